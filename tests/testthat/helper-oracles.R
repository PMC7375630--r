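# Independent oracles and fixture builders used across the suite.

# Minimax path closure on the complete graph: the largest edge on the best
# bottleneck path between every pair. Independent of any MST construction.
brute_minimax <- function(d) {
  n <- nrow(d)
  ml <- d
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      ml[i, ] <- pmin(ml[i, ], pmax(ml[i, k], ml[k, ]))
    }
  }
  diag(ml) <- 0
  ml
}

# Brute-force RMST: apply the keep rule to every pair using the minimax
# closure as mlink.
brute_rmst_keep <- function(d, gamma) {
  ml <- brute_minimax(d)
  dd <- d; diag(dd) <- Inf
  dnn <- apply(dd, 1, min)
  keep <- d <= ml + outer(dnn, dnn, "+") / gamma
  diag(keep) <- FALSE
  keep
}

# All set partitions of n items as restricted-growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum of the within-block sum of a symmetric matrix.
brute_best_partition <- function(b) {
  parts <- enumerate_partitions(nrow(b))
  scores <- vapply(parts, function(l) sum(b[outer(l, l, "==")]), 0)
  list(score = max(scores), labels = parts[[which.max(scores)]])
}

# Small graph family (adjacency matrices, unit weights).
graph_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}
graph_cycle <- function(n) {
  a <- graph_path(n); a[1, n] <- a[n, 1] <- 1; a
}
graph_clique <- function(n) {
  a <- matrix(1, n, n); diag(a) <- 0; a
}
graph_star <- function(n) {
  a <- matrix(0, n, n); a[1, 2:n] <- a[2:n, 1] <- 1; a
}
graph_barbell <- function(m) {
  # two m-cliques joined by one edge
  a <- matrix(0, 2 * m, 2 * m)
  a[1:m, 1:m] <- 1; a[(m + 1):(2 * m), (m + 1):(2 * m)] <- 1
  diag(a) <- 0
  a[m, m + 1] <- a[m + 1, m] <- 1
  a
}

# Two disconnected triangles (optionally bridged).
graph_two_triangles <- function(bridge = FALSE) {
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a[4, 5] <- a[5, 6] <- a[4, 6] <- 1
  a <- a + t(a)
  if (bridge) a[3, 4] <- a[4, 3] <- 1
  a
}

# Hand-built registration records: one row per record.
toy_records <- function(patient, lsoa, gp, date) {
  data.frame(patient_id = patient, lsoa_id = lsoa, gp_id = gp,
             record_date = as.Date(date), stringsAsFactors = FALSE)
}

# A small planted city + fit at desk scale, memoised per session so
# several tests can share one computation.
small_fit_cache <- new.env(parent = emptyenv())
small_planted_fit <- function() {
  if (!is.null(small_fit_cache$fit)) return(small_fit_cache$fit)
  city <- generate_city(90, 24, 3, seed = 401)
  reg <- sample_registrations(city, patients_per_lsoa = 40, dup_rate = 0.15,
                              seed = 402)
  fit <- pcn_fit(reg, city$gps, lsoas = city$lsoas, min_patients = 20,
                 gammas = gamma_grid(3), markov_times = markov_grid(5),
                 runs_per_model = 10, master_seed = 403)
  small_fit_cache$fit <- list(city = city, reg = reg, fit = fit)
  small_fit_cache$fit
}
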