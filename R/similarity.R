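#' Practice registration profiles over LSOAs
#'
#' Each practice's profile is the proportion of its patients resident in
#' each LSOA: the registration-matrix column divided by its column total.
#' An alternative orientation normalises within LSOAs instead (the
#' probability that a patient from each LSOA registers with the practice);
#' under cosine similarity the practice-wise normalisation is equivalent to
#' using raw counts, so the choice only matters for the row-normalised
#' variant kept for sensitivity analysis.
#'
#' @param rm a `registration_matrix`.
#' @param normalise `"practice"` (default; columns sum to 1) or `"lsoa"`
#'   (each count divided by its LSOA row total before column use).
#' @return numeric matrix with LSOAs as rows and practices as columns;
#'   with `normalise = "practice"` every column sums to 1.
#' @export
gp_profiles <- function(rm, normalise = c("practice", "lsoa")) {
  stopifnot(inherits(rm, "registration_matrix"))
  normalise <- match.arg(normalise)
  counts <- rm$counts
  check_that(all(rm$col_totals > 0), "zero practice column total upstream")
  if (normalise == "practice") {
    sweep(counts, 2, rm$col_totals, "/")
  } else {
    check_that(all(rm$row_totals > 0), "zero LSOA row total upstream")
    counts / rm$row_totals
  }
}

#' Cosine similarity matrix between practices
#'
#' Pairwise cosine similarity of practice profiles over LSOAs:
#' `S_AB = sum_i A_i B_i / (sqrt(sum_i A_i^2) sqrt(sum_i B_i^2))`. The
#' profiles are non-negative, so similarities lie in `[0, 1]`; the matrix is
#' made exactly symmetric with a unit diagonal.
#'
#' @param profiles matrix with LSOAs as rows and practices as columns
#'   (profiles or raw counts; cosine is scale-invariant per column). All
#'   columns must be non-zero.
#' @return object of class `similarity_graph`: list with the symmetric
#'   matrix `s` (dimnames = practice ids) and `gp_ids`.
#' @export
cosine_similarity_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  norms <- sqrt(colSums(profiles^2))
  check_that(all(norms > 0), "every practice profile must be non-zero")
  unit <- sweep(profiles, 2, norms, "/")
  s <- crossprod(unit)
  s <- (s + t(s)) / 2            # exact symmetry
  s[s < 0] <- 0; s[s > 1] <- 1   # clamp rounding spill
  diag(s) <- 1
  check_that(all(is.finite(s)), "non-finite similarity encountered")
  structure(list(s = s, gp_ids = colnames(profiles)), class = "similarity_graph")
}

#' Practice similarity network from a registration matrix
#'
#' Convenience composition of [gp_profiles()] and
#' [cosine_similarity_matrix()].
#'
#' @inheritParams gp_profiles
#' @return a `similarity_graph`.
#' @export
practice_similarity <- function(rm, normalise = c("practice", "lsoa")) {
  cosine_similarity_matrix(gp_profiles(rm, normalise))
}

#' @export
print.similarity_graph <- function(x, ...) {
  n <- nrow(x$s)
  off <- x$s[upper.tri(x$s)]
  cat(sprintf("Similarity graph: %d practices; off-diagonal mean %.3f, %.1f%% zero\n",
              n, mean(off), 100 * mean(off == 0)))
  invisible(x)
}

#' Write a similarity graph as a weighted edge list CSV
#'
#' @param sg a `similarity_graph` or `sparse_graph`.
#' @param path output CSV path (columns gp_a, gp_b, weight).
#' @param drop_zero omit zero-similarity pairs (dense input only).
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(sg, path, drop_zero = TRUE) {
  if (inherits(sg, "sparse_graph")) {
    edges <- sg$edges
  } else {
    stopifnot(inherits(sg, "similarity_graph"))
    idx <- which(upper.tri(sg$s), arr.ind = TRUE)
    edges <- data.frame(gp_a = sg$gp_ids[idx[, 1]], gp_b = sg$gp_ids[idx[, 2]],
                        weight = sg$s[idx], stringsAsFactors = FALSE)
    if (drop_zero) edges <- edges[edges$weight > 0, , drop = FALSE]
  }
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}
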