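#' Convert a similarity graph to a distance matrix
#'
#' Elementwise `d = 1 - s`: identical registration profiles are at distance
#' 0, practices with disjoint LSOA support at distance 1.
#'
#' @param sg a `similarity_graph` (or a symmetric similarity matrix in
#'   `[0, 1]` with unit diagonal).
#' @return symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`, dimnames preserved.
#' @export
to_distance <- function(sg) {
  s <- if (inherits(sg, "similarity_graph")) sg$s else as.matrix(sg)
  stopifnot(isSymmetric(unname(s)), all(s >= 0 & s <= 1))
  1 - s
}

#' Minimum spanning tree and maximum-link matrix
#'
#' Computes the MST of the complete weighted graph given by a distance
#' matrix, and the `mlink` matrix: `mlink[A, B]` is the largest edge weight
#' on the unique tree path between A and B (0 on the diagonal). By the
#' minimax property of MST paths, `mlink[A, B] <= d[A, B]` for every pair.
#' Distance ties are resolved by building the edge list in lexicographic
#' (i, j) order, which fixes the tree deterministically.
#'
#' @param d symmetric distance matrix with zero diagonal, finite entries.
#' @return list with `edges` (two-column index matrix of the `n - 1` tree
#'   edges, i < j), `weights` (their distances) and `mlink` (n x n matrix).
#' @export
mst_maxlink <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2, all(is.finite(d)), isSymmetric(unname(d)))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  igraph::E(g)$weight <- d[idx]
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  te <- igraph::as_edgelist(tree, names = FALSE)
  tw <- igraph::E(tree)$weight
  te <- t(apply(te, 1, sort))

  # adjacency list of the tree, then one DFS per root accumulating the
  # largest edge met along the path
  adj <- vector("list", n)
  for (e in seq_len(nrow(te))) {
    a <- te[e, 1]; b <- te[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, tw[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, tw[e]))
  }
  mlink <- matrix(0, n, n, dimnames = dimnames(d))
  for (root in seq_len(n)) {
    stack <- root
    seen <- logical(n); seen[root] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        u <- nb[r, 1]
        if (!seen[u]) {
          seen[u] <- TRUE
          mlink[root, u] <- max(mlink[root, v], nb[r, 2])
          stack <- c(stack, u)
        }
      }
    }
  }
  mlink <- pmax(mlink, t(mlink))  # exact symmetry
  list(edges = te, weights = tw, mlink = mlink)
}

#' Relaxed Minimum Spanning Tree sparsification
#'
#' Keeps an edge (A, B) of the complete distance graph iff
#' `d_AB <= mlink_AB + (dNN_A + dNN_B) / gamma`, where `dNN_X` is the
#' distance from X to its nearest neighbour and `mlink` is the largest edge
#' on the MST path between A and B. All MST edges satisfy the rule (their
#' tree path is the edge itself), so the output always contains the MST and
#' is connected. Larger `gamma` shrinks the relaxation term and prunes more;
#' as `gamma -> Inf` the output approaches the MST (plus ties), as
#' `gamma -> 0+` the complete graph. Equality is kept so both limits are
#' well defined. A multiplicative variant (`relaxation * gamma`, so larger
#' `gamma` keeps more) is available for sensitivity analysis.
#'
#' @param d symmetric distance matrix (typically [to_distance()] of a
#'   similarity graph).
#' @param gamma positive pruning parameter.
#' @param variant `"divide"` (default: relaxation `(dNN_A + dNN_B) / gamma`)
#'   or `"multiply"` (`(dNN_A + dNN_B) * gamma`).
#' @return object of class `sparse_graph`: list with `edges` (data frame
#'   gp_a, gp_b, weight — weights are similarities `1 - d`), `gp_ids`,
#'   `gamma`, `variant` and `keep` (logical n x n matrix of retained pairs).
#' @export
rmst_sparsify <- function(d, gamma, variant = c("divide", "multiply")) {
  variant <- match.arg(variant)
  d <- as.matrix(d)
  check_that(gamma > 0, "gamma must be positive")
  n <- nrow(d)
  ml <- mst_maxlink(d)
  dd <- d; diag(dd) <- Inf
  dnn <- apply(dd, 1, min)
  relax <- outer(dnn, dnn, "+")
  relax <- if (variant == "divide") relax / gamma else relax * gamma
  keep <- d <= ml$mlink + relax
  keep[cbind(ml$edges[, 1], ml$edges[, 2])] <- TRUE   # MST always in
  keep[cbind(ml$edges[, 2], ml$edges[, 1])] <- TRUE
  diag(keep) <- FALSE
  keep <- keep & t(keep)

  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  edges <- data.frame(gp_a = ids[idx[, 1]], gp_b = ids[idx[, 2]],
                      weight = 1 - d[idx], stringsAsFactors = FALSE)
  structure(list(edges = edges, edge_index = idx, gp_ids = ids,
                 gamma = gamma, variant = variant, keep = keep),
            class = "sparse_graph")
}

#' @export
print.sparse_graph <- function(x, ...) {
  n <- length(x$gp_ids)
  cat(sprintf("RMST-sparsened graph: %d practices, %d of %d edges kept (gamma = %.3g)\n",
              n, nrow(x$edges), n * (n - 1) / 2, x$gamma))
  invisible(x)
}

# weighted adjacency matrix of a sparse graph (similarity weights)
sparse_adjacency <- function(sg) {
  stopifnot(inherits(sg, "sparse_graph"))
  n <- length(sg$gp_ids)
  a <- matrix(0, n, n, dimnames = list(sg$gp_ids, sg$gp_ids))
  a[sg$edge_index] <- sg$edges$weight
  a[sg$edge_index[, c(2, 1), drop = FALSE]] <- sg$edges$weight
  a
}
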