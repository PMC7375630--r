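test_that("random-walk operators have the documented structure", {
  # single edge: stationary distribution (1/2, 1/2)
  mod <- random_walk_operators(graph_path(2))
  expect_equal(mod$pi, c(0.5, 0.5))

  # star with centre + 3 leaves: pi = degree / 2m = (1/2, 1/6, 1/6, 1/6)
  mod <- random_walk_operators(graph_star(4))
  expect_equal(mod$pi, c(1 / 2, 1 / 6, 1 / 6, 1 / 6))

  # transition matrix is row-stochastic; heat kernel preserves stochasticity
  a <- graph_barbell(3)
  mod <- random_walk_operators(a)
  expect_equal(rowSums(mod$m), rep(1, 6))
  for (t in c(0.2, 1, 3)) {
    # recover exp(t(M - I)) from the stability matrix: P = Pi^-1 (R + pi pi^T)
    r <- stability_matrix(mod, t)
    p <- (r + outer(mod$pi, mod$pi)) / mod$pi
    expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-12)
    expect_true(all(p >= -1e-12))
  }

  expect_error(random_walk_operators(matrix(0, 2, 2)), "isolated")
})

test_that("stability scores match closed forms", {
  mod <- random_walk_operators(graph_path(2))
  # two nodes, finest partition: r(t) = exp(-2t)/2
  for (t in c(0, 0.1, 0.5, 1)) {
    expect_equal(stability_score(mod, 1:2, t = t), exp(-2 * t) / 2,
                 tolerance = 1e-12)
  }
  expect_equal(stability_score(mod, 1:2, t = 0.5), 0.18394, tolerance = 1e-4)

  # all-in-one partition scores exactly 0 at every time, any graph
  for (a in list(graph_path(5), graph_cycle(6), graph_star(5))) {
    mod <- random_walk_operators(a)
    for (t in c(0, 0.3, 1)) {
      expect_equal(stability_score(mod, rep(1, nrow(a)), t = t), 0,
                   tolerance = 1e-12)
    }
  }

  # finest partition at t = 0 scores 1 - sum(pi^2)
  mod <- random_walk_operators(graph_cycle(7))
  expect_equal(stability_score(mod, 1:7, t = 0), 1 - sum(mod$pi^2),
               tolerance = 1e-12)
})

test_that("Louvain recovers enumerated optima on two-triangle graphs", {
  # brute force over all 203 partitions of 6 nodes; with the bridge the
  # triangles only dominate at a larger Markov time
  for (bridge in c(FALSE, TRUE)) {
    t <- if (bridge) 1 else 0.5
    mod <- random_walk_operators(graph_two_triangles(bridge))
    r <- stability_matrix(mod, t)
    oracle <- brute_best_partition(r)
    best <- NULL
    for (s in 1:20) {
      p <- louvain_optimise(mod, t, seed = s)
      if (is.null(best) || p$r > best$r) best <- p
    }
    expect_equal(best$r, oracle$score, tolerance = 1e-10)
    expect_equal(unname(best$labels), canonical_labels(oracle$labels))
    expect_equal(unname(best$labels), c(1, 1, 1, 2, 2, 2))
  }
})

test_that("t = 0 yields the finest partition", {
  mod <- random_walk_operators(graph_clique(6))
  p <- louvain_optimise(mod, t = 0, seed = 1)
  expect_equal(unname(p$labels), 1:6)
})

test_that("optimal stability is at least the finest partition's and non-negative", {
  set.seed(131)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(10, 0.5)
    if (!igraph::is_connected(g)) next
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    mod <- random_walk_operators(a)
    for (t in c(0.05, 0.5, 1)) {
      finest <- stability_score(mod, 1:10, t = t)
      p <- louvain_optimise(mod, t, seed = rep)
      expect_gte(p$r, finest - 1e-12)
      expect_gte(p$r, -1e-12)
    }
  }
})

test_that("canonical form is invariant under relabelling and automorphism", {
  expect_equal(canonical_labels(c(7, 7, 2, 2, 9)), c(1, 1, 2, 2, 3))
  expect_equal(canonical_labels(c("b", "b", "a")), c(1, 1, 2))

  # relabelling nodes of a graph relabels the canonical partition identically
  a <- graph_two_triangles(TRUE)
  mod <- random_walk_operators(a)
  p <- louvain_optimise(mod, 0.1, seed = 3)
  perm <- c(4, 5, 6, 1, 2, 3)
  mod2 <- random_walk_operators(a[perm, perm])
  p2 <- louvain_optimise(mod2, 0.1, seed = 3)
  expect_equal(unname(p2$labels), canonical_labels(unname(p$labels)[perm]))
})

test_that("consensus selects the modal partition with the documented tie-breaks", {
  mk <- function(labels, r) structure(list(labels = labels, r = r, t = 0.1),
                                      class = "partition")
  p1 <- mk(c(a = 1, b = 1, c = 2), 0.4)
  p2 <- mk(c(a = 2, b = 2, c = 1), 0.35)   # same partition as p1, relabelled
  p3 <- mk(c(a = 1, b = 2, c = 2), 0.9)
  cons <- consensus_partition(list(p1, p2, p3))
  expect_equal(unname(cons$labels), c(1, 1, 2))
  expect_equal(cons$multiplicity, 2L)
  expect_equal(cons$n_runs, 3L)

  # multiplicity tie -> higher mean r
  cons <- consensus_partition(list(p1, p3))
  expect_equal(unname(cons$labels), c(1, 2, 2))

  # full tie -> lexicographically smallest canonical labelling
  q1 <- mk(c(a = 1, b = 1, c = 2), 0.5)
  q2 <- mk(c(a = 1, b = 2, c = 2), 0.5)
  cons <- consensus_partition(list(q1, q2))
  expect_equal(unname(cons$labels), c(1, 1, 2))
})

test_that("linearised stability approximates the exponential at small times", {
  mod <- random_walk_operators(graph_barbell(4))
  r_full <- stability_matrix(mod, 0.01)
  r_lin <- stability_matrix(mod, 0.01, flavour = "linearised")
  expect_equal(r_full, r_lin, tolerance = 1e-3)
})
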