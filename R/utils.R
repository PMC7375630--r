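#' Adjusted Rand Index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table by the usual pair-counting formula.
#' Used to compare recovered practice communities with planted labels.
#'
#' @param a,b label vectors of equal length (any atomic type; compared as
#'   factors).
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Derive a per-(gamma index, t index, run) seed from one master seed.
# Fixed mixing constants; result kept inside the positive 32-bit range so it
# is a valid argument to set.seed() everywhere.
derive_seed <- function(master, gamma_index = 0L, t_index = 0L, run = 0L) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + 104729 * as.numeric(gamma_index)) %% m
  s <- (s + 130363 * as.numeric(t_index)) %% m
  s <- (s + 15485863 * as.numeric(run)) %% m
  as.integer(s %% 2147483646) + 1L
}

# stopifnot() with a readable message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# weighted quantile-style summary used in coverage reports
summary_quantiles <- function(x) {
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
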