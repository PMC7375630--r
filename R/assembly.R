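#' Practice-to-PCN membership vector
#'
#' Turns the valid communities of a filtered partition into a membership
#' vector over all practices of a registration matrix. PCNs are numbered
#' 1..P in the order the valid communities appear; practices not in any
#' valid community (filtered out, or absent from the partition) form an
#' explicit unassigned pool coded `NA`.
#'
#' @param filtered a [filter_communities()] result (or a named list
#'   community -> member ids).
#' @param gp_ids all practice ids, in registration-matrix column order.
#' @return integer vector named by `gp_ids`; `NA` marks the unassigned pool.
#' @export
pcn_membership <- function(filtered, gp_ids) {
  valid <- if (is.list(filtered) && !is.null(filtered$valid)) filtered$valid else filtered
  member <- rep(NA_integer_, length(gp_ids))
  names(member) <- gp_ids
  for (p in seq_along(valid)) {
    ids <- intersect(valid[[p]], gp_ids)
    member[ids] <- p
  }
  member
}

#' Assign LSOAs to PCNs by modal registration
#'
#' Aggregates the LSOA-by-practice counts to LSOA-by-PCN (the unassigned
#' practice pool kept as one extra column) and assigns each LSOA to the PCN
#' holding the largest patient count. Ties are broken by the smallest PCN
#' id, with the unassigned pool losing ties to any real PCN. LSOAs whose
#' modal provider group is the unassigned pool are reported as unassigned
#' (`pcn = NA`).
#'
#' @param rm a `registration_matrix`.
#' @param membership a [pcn_membership()] vector over the matrix's
#'   practices.
#' @return object of class `lsoa_assignment`: list with `table` (data frame
#'   lsoa_id, pcn, patients_to_pcn, total_patients, coverage_pct) and
#'   `pcn_counts` (LSOA x PCN count matrix, last column the unassigned
#'   pool).
#' @export
assign_lsoas <- function(rm, membership) {
  stopifnot(inherits(rm, "registration_matrix"),
            length(membership) == ncol(rm$counts))
  pcns <- sort(unique(membership[!is.na(membership)]))
  group <- match(membership, pcns)           # NA -> unassigned pool
  pool <- length(pcns) + 1L
  group[is.na(group)] <- pool
  agg <- t(rowsum(t(rm$counts), group))      # LSOA x group counts
  colnames(agg) <- c(as.character(pcns), "unassigned")[sort(unique(group))]
  # ensure all groups present as columns even if empty
  full <- matrix(0, nrow(agg), pool,
                 dimnames = list(rownames(rm$counts),
                                 c(as.character(pcns), "unassigned")))
  full[, colnames(agg)] <- agg

  total <- rowSums(full)
  # modal PCN: ties to smallest id; unassigned pool loses ties (it is last)
  modal <- apply(full, 1, which.max)
  assigned <- ifelse(modal == pool, NA_integer_, pcns[modal])
  to_pcn <- full[cbind(seq_len(nrow(full)), modal)]
  tab <- data.frame(
    lsoa_id = rownames(full),
    pcn = assigned,
    patients_to_pcn = as.integer(to_pcn),
    total_patients = as.integer(total),
    coverage_pct = ifelse(total > 0, 100 * to_pcn / total, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, pcn_counts = full), class = "lsoa_assignment")
}

#' @export
print.lsoa_assignment <- function(x, ...) {
  n <- nrow(x$table)
  un <- sum(is.na(x$table$pcn))
  cat(sprintf("LSOA assignment: %d LSOAs, %d unassigned; median coverage %.1f%%\n",
              n, un, stats::median(x$table$coverage_pct, na.rm = TRUE)))
  invisible(x)
}

#' Coverage and market-concentration report
#'
#' Per-LSOA coverage (percentage of the LSOA's patients registered to its
#' modal PCN), per-PCN coverage (patients in the PCN's catchment LSOAs
#' registered to a member practice, over all patients in the catchment — the
#' patient-weighted aggregate of LSOA coverage), PCN-level market
#' concentration for each LSOA (HHI/EMS over PCN-aggregated counts, the
#' unassigned pool kept as one market unit), and summary quantiles of all
#' three.
#'
#' @param assignment an [assign_lsoas()] result.
#' @return object of class `coverage_report`: list with `lsoa` (the
#'   assignment table plus PCN-level hhi/ems), `pcn` (data frame pcn,
#'   n_lsoas, catchment_patients, coverage_pct), and `summary` (list of
#'   quantile summaries).
#' @export
coverage_statistics <- function(assignment) {
  stopifnot(inherits(assignment, "lsoa_assignment"))
  tab <- assignment$table
  counts <- assignment$pcn_counts
  pool <- ncol(counts)

  conc <- lsoa_market_concentration(counts)
  lsoa <- merge(tab, stats::setNames(conc[, c("lsoa_id", "hhi", "ems")],
                                     c("lsoa_id", "pcn_hhi", "pcn_ems")),
                by = "lsoa_id", all.x = TRUE, sort = FALSE)
  lsoa <- lsoa[match(tab$lsoa_id, lsoa$lsoa_id), , drop = FALSE]
  rownames(lsoa) <- NULL

  assigned <- !is.na(tab$pcn)
  pcn_ids <- sort(unique(tab$pcn[assigned]))
  pcn <- do.call(rbind, lapply(pcn_ids, function(p) {
    rows <- which(assigned & tab$pcn == p)
    inside <- sum(counts[rows, as.character(p)])
    total <- sum(tab$total_patients[rows])
    data.frame(pcn = p, n_lsoas = length(rows),
               catchment_patients = total,
               coverage_pct = 100 * inside / total,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pcn)) {
    pcn <- data.frame(pcn = integer(), n_lsoas = integer(),
                      catchment_patients = integer(),
                      coverage_pct = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(
    lsoa = lsoa, pcn = pcn,
    summary = list(
      lsoa_coverage = summary_quantiles(stats::na.omit(lsoa$coverage_pct[assigned])),
      pcn_coverage = if (nrow(pcn) > 0) summary_quantiles(pcn$coverage_pct) else NULL,
      pcn_ems = summary_quantiles(stats::na.omit(lsoa$pcn_ems)),
      pcn_hhi = summary_quantiles(stats::na.omit(lsoa$pcn_hhi)),
      n_lsoas_unassigned = sum(!assigned)
    )), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Coverage: median LSOA %.1f%%; median PCN %.1f%%; median PCN-level EMS %.2f\n",
              s$lsoa_coverage$median,
              if (is.null(s$pcn_coverage)) NA else s$pcn_coverage$median,
              s$pcn_ems$median))
  invisible(x)
}

#' Per-PCN catalogue: members, list size, CCG span
#'
#' Summarises each PCN from practice metadata: member count, summed list
#' size (a practice with missing list size contributes 0 and is logged in
#' the attribute `missing_list_size`), and the number of distinct CCGs
#' spanned.
#'
#' @param membership a [pcn_membership()] vector.
#' @param practices data frame with columns gp_id, ccg_id and optionally
#'   list_size.
#' @return object of class `pcn_catalogue`: data frame pcn, n_practices,
#'   list_size, n_ccgs; attribute `unassigned` holds the unassigned
#'   practice ids.
#' @export
pcn_summaries <- function(membership, practices) {
  stopifnot(all(c("gp_id", "ccg_id") %in% names(practices)))
  meta <- practices[match(names(membership), practices$gp_id), , drop = FALSE]
  ls <- if ("list_size" %in% names(practices)) meta$list_size else
    rep(NA_real_, nrow(meta))
  missing_ls <- names(membership)[is.na(ls) & !is.na(membership)]
  ls[is.na(ls)] <- 0
  pcns <- sort(unique(membership[!is.na(membership)]))
  out <- do.call(rbind, lapply(pcns, function(p) {
    ix <- which(!is.na(membership) & membership == p)
    data.frame(pcn = p, n_practices = length(ix),
               list_size = sum(ls[ix]),
               n_ccgs = length(unique(meta$ccg_id[ix])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(pcn = integer(), n_practices = integer(),
                      list_size = numeric(), n_ccgs = integer(),
                      stringsAsFactors = FALSE)
  }
  if (length(missing_ls) > 0) {
    warning(sprintf("%d practices missing list_size contribute 0", length(missing_ls)))
  }
  structure(out, class = c("pcn_catalogue", "data.frame"),
            unassigned = names(membership)[is.na(membership)],
            missing_list_size = missing_ls)
}
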