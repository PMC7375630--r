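rm_from_counts <- function(counts) {
  structure(list(counts = counts, lsoa_ids = rownames(counts),
                 gp_ids = colnames(counts), row_totals = rowSums(counts),
                 col_totals = colSums(counts), min_patients = 0,
                 dropped = data.frame(gp_id = character(),
                                      n_patients = integer())),
            class = "registration_matrix")
}

test_that("modal assignment, ties and the unassigned pool behave as documented", {
  counts <- rbind(
    L1 = c(60, 0, 40, 0),    # PCN 1: 60, PCN 2: 40 -> PCN 1, coverage 60%
    L2 = c(25, 25, 25, 25),  # tie 50/50 -> smallest PCN id (1)
    L3 = c(0, 10, 0, 90)     # unassigned practice modal -> unassigned LSOA
  )
  colnames(counts) <- c("G1", "G2", "G3", "G4")
  rm <- rm_from_counts(counts)
  membership <- c(G1 = 1L, G2 = 1L, G3 = 2L, G4 = NA)
  asg <- assign_lsoas(rm, membership)
  tab <- asg$table
  expect_equal(tab$pcn, c(1, 1, NA))
  expect_equal(tab$coverage_pct[1], 60)
  expect_equal(tab$coverage_pct[2], 50)
  expect_equal(tab$patients_to_pcn, c(60, 50, 90))
})

test_that("per-PCN coverage is the patient-weighted aggregate of its catchment", {
  # two-LSOA catchment: 60% of 100 and 90% of 300 -> 82.5%
  counts <- rbind(L1 = c(60, 40), L2 = c(270, 30))
  colnames(counts) <- c("G1", "G2")
  rm <- rm_from_counts(counts)
  membership <- c(G1 = 1L, G2 = 2L)
  asg <- assign_lsoas(rm, membership)
  cov <- coverage_statistics(asg)
  expect_equal(cov$pcn$coverage_pct[cov$pcn$pcn == 1], 82.5)

  # single-LSOA catchment fully registered within -> 100%
  counts <- rbind(L1 = c(50, 0), L2 = c(0, 50))
  colnames(counts) <- c("G1", "G2")
  asg <- assign_lsoas(rm_from_counts(counts), membership)
  cov <- coverage_statistics(asg)
  expect_equal(cov$pcn$coverage_pct, c(100, 100))
})

test_that("PCN-level market concentration reuses the HHI/EMS formulas", {
  # LSOA split 50/50 across two PCNs -> EMS = 2
  counts <- rbind(L1 = c(50, 50))
  colnames(counts) <- c("G1", "G2")
  asg <- assign_lsoas(rm_from_counts(counts), c(G1 = 1L, G2 = 2L))
  cov <- coverage_statistics(asg)
  expect_equal(cov$lsoa$pcn_ems, 2)
  expect_equal(cov$lsoa$pcn_hhi, 0.5)
})

test_that("summary quantiles match the naive sort-based oracle", {
  set.seed(301)
  x <- runif(37) * 100
  q <- pcnets:::summary_quantiles(x)
  expect_equal(q$median, median(x))
  expect_equal(q$min, min(x))
  expect_equal(q$max, max(x))
  expect_equal(q$q1, unname(quantile(x, 0.25)))
  expect_equal(q$q3, unname(quantile(x, 0.75)))
})

test_that("coverage is invariant to splitting an LSOA into duplicate rows", {
  counts <- rbind(L1 = c(60, 40), L2 = c(270, 30))
  colnames(counts) <- c("G1", "G2")
  membership <- c(G1 = 1L, G2 = 2L)
  cov1 <- coverage_statistics(assign_lsoas(rm_from_counts(counts), membership))
  split_counts <- rbind(L1a = c(30, 20), L1b = c(30, 20), L2 = c(270, 30))
  colnames(split_counts) <- c("G1", "G2")
  cov2 <- coverage_statistics(assign_lsoas(rm_from_counts(split_counts),
                                           membership))
  expect_equal(cov1$pcn$coverage_pct, cov2$pcn$coverage_pct)
})

test_that("patient conservation holds through assembly", {
  city <- generate_city(40, 12, 3, seed = 311)
  reg <- sample_registrations(city, patients_per_lsoa = 30, dup_rate = 0.2,
                              seed = 312)
  rm <- build_registration_matrix(deduplicate_patients(reg), min_patients = 10)
  membership <- pcn_membership(list(valid = split(rm$gp_ids,
                                                  rep(1:3, length.out = ncol(rm$counts)))),
                               rm$gp_ids)
  asg <- assign_lsoas(rm, membership)
  expect_equal(sum(asg$pcn_counts), sum(rm$counts))
  expect_equal(sum(asg$table$total_patients), sum(rm$counts))
})

test_that("PCN catalogue sums list sizes and counts CCG span", {
  membership <- c(G1 = 1L, G2 = 1L, G3 = 2L, G4 = NA)
  practices <- data.frame(
    gp_id = c("G1", "G2", "G3", "G4"),
    ccg_id = c("C1", "C1", "C2", "C2"),
    list_size = c(8000, 12000, 5000, 7000),
    stringsAsFactors = FALSE
  )
  cat_tab <- pcn_summaries(membership, practices)
  expect_equal(cat_tab$list_size, c(20000, 5000))
  expect_equal(cat_tab$n_ccgs, c(1, 1))
  expect_equal(attr(cat_tab, "unassigned"), "G4")

  # missing list size contributes 0 and is logged
  practices$list_size[2] <- NA
  expect_warning(cat2 <- pcn_summaries(membership, practices), "missing")
  expect_equal(cat2$list_size[1], 8000)
  expect_equal(attr(cat2, "missing_list_size"), "G2")

  # planted-CCG city with perfect recovery spans exactly one CCG per PCN
  fitbun <- small_planted_fit()
  fit <- fitbun$fit
  expect_true(all(fit$catalogue$n_ccgs == 1))
})
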