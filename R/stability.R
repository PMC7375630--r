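#' Random-walk operators for Markov-stability community detection
#'
#' From a weighted undirected graph builds the ingredients of continuous-time
#' Markov stability: the transition matrix `M = diag(k)^-1 A` of the random
#' walk (k = node strengths) and its stationary distribution `pi = k / sum(k)`.
#' Because `diag(pi) %*% M` is symmetric, `M` shares eigenvectors with the
#' symmetrised operator `N = diag(k)^-1/2 A diag(k)^-1/2`; one symmetric
#' eigendecomposition of `N` is stored so the heat kernel
#' `exp(t (M - I))` — and hence the stability matrix at any Markov time —
#' is cheap to evaluate across a whole grid of times.
#'
#' Nodes with zero strength (isolated in the weighted sense) violate the
#' upstream contract (RMST output is connected) and raise an error. A graph
#' whose positive-weight part is disconnected is legal: the walk simply
#' never crosses between components.
#'
#' @param graph a `sparse_graph`, or a symmetric non-negative weighted
#'   adjacency matrix.
#' @return object of class `stability_model`: list with `a` (adjacency),
#'   `k`, `pi`, `m` (row-stochastic transition matrix), eigen pair
#'   (`vectors`, `values`) of the symmetrised operator, and `gp_ids`.
#' @export
random_walk_operators <- function(graph) {
  a <- if (inherits(graph, "sparse_graph")) sparse_adjacency(graph) else as.matrix(graph)
  stopifnot(isSymmetric(unname(a)), all(a >= 0))
  k <- rowSums(a)
  check_that(all(k > 0), "isolated node (zero strength): upstream contract violated")
  total <- sum(k)
  pi <- k / total
  m <- a / k
  sk <- sqrt(k)
  nsym <- a / outer(sk, sk)
  es <- eigen((nsym + t(nsym)) / 2, symmetric = TRUE)
  structure(list(a = a, k = k, total = total, pi = pi, m = m,
                 vectors = es$vectors, values = es$values,
                 gp_ids = rownames(a) %||% as.character(seq_along(k))),
            class = "stability_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.stability_model <- function(x, ...) {
  cat(sprintf("Markov-stability model: %d nodes, total strength %.4g\n",
              length(x$k), x$total))
  invisible(x)
}

#' Stability matrix at a Markov time
#'
#' Computes `R(t) = Pi exp(t (M - I)) - pi pi^T` (with `Pi = diag(pi)`), the
#' matrix whose within-community block sum is the Markov stability of a
#' partition. The full matrix exponential is evaluated through the stored
#' symmetric eigendecomposition; the linearised variant replaces the
#' exponential by its first-order expansion `Pi (I + t(M - I))`, which is
#' faster and adequate at small times.
#'
#' @param model a `stability_model`.
#' @param t non-negative Markov time.
#' @param flavour `"exponential"` (default) or `"linearised"`.
#' @return symmetric n x n matrix summing to 0.
#' @export
stability_matrix <- function(model, t, flavour = c("exponential", "linearised")) {
  flavour <- match.arg(flavour)
  stopifnot(inherits(model, "stability_model"), t >= 0)
  if (flavour == "linearised") {
    r <- diag(model$pi * (1 - t)) + t * model$a / model$total -
      outer(model$pi, model$pi)
  } else {
    u <- sqrt(model$k) * model$vectors               # row-scaled eigenvectors
    e <- exp(t * (model$values - 1))
    r <- (u %*% (e * t(u))) / model$total - outer(model$pi, model$pi)
  }
  (r + t(r)) / 2
}

#' Markov stability of a partition
#'
#' `r(t, H) = trace(H^T (Pi exp(t(M - I)) - pi pi^T) H)`: the sum of the
#' stability matrix over within-community pairs. The all-in-one partition
#' scores exactly 0 at every time; at `t = 0` the finest partition scores
#' `1 - sum(pi^2)`.
#'
#' @param model a `stability_model`.
#' @param labels community labels, one per node.
#' @param t Markov time.
#' @param r optional precomputed [stability_matrix()] (overrides `t`).
#' @inheritParams stability_matrix
#' @return the stability value, a single number.
#' @export
stability_score <- function(model, labels, t = NULL, r = NULL,
                            flavour = c("exponential", "linearised")) {
  if (is.null(r)) r <- stability_matrix(model, t, match.arg(flavour))
  stopifnot(length(labels) == nrow(r))
  sum(vapply(split(seq_along(labels), labels),
             function(ix) sum(r[ix, ix]), 0))
}

#' Canonical form of a labelling
#'
#' Renumbers communities by order of first appearance along the node order,
#' so relabelled but identical partitions compare equal.
#'
#' @param labels community labels.
#' @return integer labels in canonical form.
#' @export
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# Generalised Louvain: maximise the within-community sum of a symmetric
# matrix b (local moves + aggregation by block sums; the matrix is never
# recomputed on aggregated graphs, so the score is exact on the original).
# Sweep order randomised by the current RNG state.
louvain_matrix <- function(b, max_passes = 100L) {
  n <- nrow(b)
  groups <- seq_len(n)          # community of each original node
  bc <- b                       # aggregated matrix, one row per community
  repeat {
    nc <- nrow(bc)
    m <- seq_len(nc)            # community of each aggregated node
    moved_any <- FALSE
    for (pass in seq_len(max_passes)) {
      moved <- FALSE
      for (i in sample.int(nc)) {
        ci <- m[i]
        bi <- bc[i, ]
        s <- numeric(max(m))
        agg <- rowsum(bi, m)
        s[as.integer(rownames(agg))] <- agg
        value <- 2 * s + bc[i, i]          # joining community c (c != ci)
        value[ci] <- 2 * (s[ci] - bc[i, i]) + bc[i, i]   # staying
        alone <- bc[i, i]                  # splitting off alone
        best <- which.max(value)
        best_val <- value[best]
        if (alone > best_val + 1e-12) {
          free <- which(tabulate(m, max(m)) == 0)
          target <- if (length(free) > 0) free[1] else max(m) + 1L
          m[i] <- target
          moved <- TRUE
        } else if (best != ci && best_val > value[ci] + 1e-12) {
          m[i] <- best
          moved <- TRUE
        }
      }
      if (!moved) break
      moved_any <- TRUE
    }
    if (!moved_any) break
    m <- match(m, unique(m))
    groups <- m[groups]
    bc <- rowsum(t(rowsum(bc, m)), m)
    if (nrow(bc) == nc) break
  }
  canonical_labels(groups)
}

#' Louvain optimisation of Markov stability
#'
#' Greedy Louvain maximisation of `r(t)` treating the stability matrix as a
#' generalised modularity matrix: repeated local node moves (in an order
#' randomised by `seed`) followed by community aggregation, until no move
#' improves the score. Aggregation sums blocks of the original stability
#' matrix, so the reported score is exact.
#'
#' @param model a `stability_model`.
#' @param t Markov time.
#' @param seed integer seed for the sweep order.
#' @param r optional precomputed [stability_matrix()].
#' @inheritParams stability_matrix
#' @return object of class `partition`: list with canonical integer
#'   `labels` (named by node ids), stability `r`, Markov time `t`.
#' @export
louvain_optimise <- function(model, t = NULL, seed = 1L, r = NULL,
                             flavour = c("exponential", "linearised")) {
  if (is.null(r)) r <- stability_matrix(model, t, match.arg(flavour))
  set.seed(seed)
  labels <- louvain_matrix(r)
  names(labels) <- model$gp_ids
  structure(list(labels = labels,
                 r = stability_score(model, labels, r = r),
                 t = t, multiplicity = 1L),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities over %d nodes, stability r = %.6g",
              length(unique(x$labels)), length(x$labels), x$r))
  if (!is.null(x$multiplicity) && !is.null(x$n_runs) && x$n_runs > 1)
    cat(sprintf(" (consensus %d/%d runs)", x$multiplicity, x$n_runs))
  cat("\n")
  invisible(x)
}

#' Consensus partition over repeated Louvain runs
#'
#' Canonicalises each run's labelling and returns the most common partition.
#' Multiplicity ties are broken by higher mean stability, then by the
#' lexicographically smallest canonical labelling.
#'
#' @param runs non-empty list of `partition` objects over the same node set.
#' @return the winning `partition` with its `multiplicity` and `n_runs`
#'   recorded; `r` is the mean stability of the identical runs.
#' @export
consensus_partition <- function(runs) {
  check_that(length(runs) > 0, "runs must be non-empty")
  labs <- lapply(runs, function(p) canonical_labels(p$labels))
  nn <- lengths(labs)
  check_that(all(nn == nn[1]), "runs must cover the same node set")
  sig <- vapply(labs, paste, "", collapse = ",")
  counts <- table(sig)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    mean_r <- vapply(top, function(s) mean(vapply(runs[sig == s],
                                                  function(p) p$r, 0)), 0)
    top <- top[mean_r == max(mean_r)]
    if (length(top) > 1L) {
      mat <- do.call(rbind, lapply(top, function(s)
        as.integer(strsplit(s, ",", fixed = TRUE)[[1]])))
      top <- top[do.call(order, as.data.frame(mat))[1]]
    }
  }
  member <- which(sig == top)
  winner <- runs[[member[1]]]
  out <- winner
  out$labels <- labs[[member[1]]]
  names(out$labels) <- names(winner$labels)
  out$r <- mean(vapply(runs[member], function(p) p$r, 0))
  out$multiplicity <- length(member)
  out$n_runs <- length(runs)
  out
}
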