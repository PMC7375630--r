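#' Deduplicate patient registration records
#'
#' A patient observed at more than one (LSOA, practice) combination within
#' the study window is resolved to a single pair: the combination with the
#' highest record frequency for that patient is chosen; frequency ties are
#' broken by the combination carrying the most recent record date; the rare
#' double tie (equal frequency and equal latest date) falls back to the
#' lexicographically smallest (gp_id, lsoa_id) and is counted in the output.
#'
#' @param records either a `registration_table` or a data frame with columns
#'   patient_id, lsoa_id, gp_id, record_date (coercible via `as.Date`).
#' @return data frame with one row per patient: patient_id, lsoa_id, gp_id,
#'   plus attribute `n_double_ties` (number of patients resolved by the
#'   deterministic fallback).
#' @export
deduplicate_patients <- function(records) {
  if (inherits(records, "registration_table")) records <- records$records
  stopifnot(is.data.frame(records),
            all(c("patient_id", "lsoa_id", "gp_id", "record_date") %in%
                  names(records)))
  check_that(nrow(records) > 0L, "records must be non-empty")
  date <- as.Date(records$record_date)
  check_that(!anyNA(date), "record_date must be parseable dates")

  key <- paste(records$patient_id, records$lsoa_id, records$gp_id, sep = "\r")
  freq <- as.vector(table(key)[key])
  latest <- as.numeric(stats::ave(as.numeric(date), key, FUN = max))

  # one row per (patient, lsoa, gp) combination
  first <- !duplicated(key)
  comb <- data.frame(patient_id = records$patient_id[first],
                     lsoa_id = records$lsoa_id[first],
                     gp_id = records$gp_id[first],
                     freq = freq[first], latest = latest[first],
                     stringsAsFactors = FALSE)
  ord <- order(comb$patient_id, -comb$freq, -comb$latest, comb$gp_id,
               comb$lsoa_id)
  comb <- comb[ord, , drop = FALSE]
  pick <- !duplicated(comb$patient_id)

  # count patients whose top two combinations tie on frequency AND date
  idx <- which(pick)
  nxt <- idx + 1L
  has_runner <- nxt <= nrow(comb) & comb$patient_id[pmin(nxt, nrow(comb))] ==
    comb$patient_id[idx]
  n_double <- sum(has_runner &
                    comb$freq[idx] == comb$freq[pmin(nxt, nrow(comb))] &
                    comb$latest[idx] == comb$latest[pmin(nxt, nrow(comb))])

  out <- comb[pick, c("patient_id", "lsoa_id", "gp_id"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_double_ties") <- n_double
  out
}

#' Build the LSOA-by-practice registration matrix
#'
#' Tabulates deduplicated patients into a count matrix with LSOAs as rows and
#' practices as columns, then applies the small-practice exclusion: practices
#' contributing fewer than `min_patients` patients are dropped and their
#' patients removed with them (not reassigned). Dropping can only shrink
#' column totals of the remaining practices' rows, never a column itself, so
#' a single pass suffices.
#'
#' @param dedup a [deduplicate_patients()] result (patient_id, lsoa_id,
#'   gp_id).
#' @param min_patients minimum column total for a practice to be retained;
#'   the bound is strict, so a practice with exactly `min_patients` patients
#'   is kept.
#' @return object of class `registration_matrix`: list with integer matrix
#'   `counts` (dimnames = LSOA and practice ids), `row_totals`, `col_totals`,
#'   and `dropped` (data frame of excluded practices with their patient
#'   counts).
#' @export
build_registration_matrix <- function(dedup, min_patients = 100) {
  stopifnot(is.data.frame(dedup),
            all(c("lsoa_id", "gp_id") %in% names(dedup)))
  counts <- table(dedup$lsoa_id, dedup$gp_id)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  keep <- colSums(counts) >= min_patients
  dropped <- data.frame(gp_id = colnames(counts)[!keep],
                        n_patients = unname(colSums(counts)[!keep]),
                        stringsAsFactors = FALSE)
  counts <- counts[, keep, drop = FALSE]
  check_that(ncol(counts) > 0L && sum(counts) > 0L,
             "no practice survives the minimum-patient filter")
  structure(list(counts = counts,
                 lsoa_ids = rownames(counts), gp_ids = colnames(counts),
                 row_totals = rowSums(counts), col_totals = colSums(counts),
                 min_patients = min_patients, dropped = dropped),
            class = "registration_matrix")
}

#' @export
print.registration_matrix <- function(x, ...) {
  cat(sprintf(
    "Registration matrix: %d LSOAs x %d practices, %d patients (%d practices dropped)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts), nrow(x$dropped)))
  invisible(x)
}

#' LSOA market concentration: Herfindahl-Hirschman index and equivalent market size
#'
#' For each LSOA, the registration shares s_ij (proportion of the LSOA's
#' patients registered to each practice) give the Herfindahl-Hirschman index
#' HHI_i = sum_j s_ij^2 and the equivalent market size EMS_i = 1 / HHI_i —
#' the number of practices that would serve the LSOA if each held an equal
#' share. Zero-patient LSOAs are excluded from the summary and reported.
#'
#' @param x a `registration_matrix`, or a numeric count matrix with LSOAs as
#'   rows (units may equally be PCNs; the statistic is agnostic).
#' @return data frame with one row per LSOA with at least one patient:
#'   lsoa_id, n_patients, hhi, ems; attribute `excluded` lists zero-patient
#'   LSOA ids.
#' @export
lsoa_market_concentration <- function(x) {
  counts <- if (inherits(x, "registration_matrix")) x$counts else as.matrix(x)
  stopifnot(is.numeric(counts), all(counts >= 0))
  tot <- rowSums(counts)
  excluded <- rownames(counts)[tot == 0]
  keep <- tot > 0
  shares <- counts[keep, , drop = FALSE] / tot[keep]
  hhi <- rowSums(shares^2)
  out <- data.frame(lsoa_id = rownames(counts)[keep],
                    n_patients = unname(tot[keep]),
                    hhi = unname(hhi), ems = unname(1 / hhi),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
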