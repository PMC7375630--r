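unit_cluster_layout <- function() {
  # 9 practices in a unit cluster + 1 at distance ~140
  set.seed(201)
  xy <- cbind(runif(9), runif(9))
  xy <- rbind(xy, c(100, 100))
  spatial_layout(xy, ids = sprintf("G%02d", 1:10))
}

test_that("the remote practice in the 9+1 construction is the only outlier", {
  layout <- unit_cluster_layout()
  out <- spatial_outliers(sprintf("G%02d", 1:10), layout)
  expect_equal(out, "G10")

  # community-wide median is computed once, from original membership
  d <- layout$dist[1:10, 1:10]
  med_all <- median(d[upper.tri(d)])
  expect_lt(med_all, 2)                      # dominated by the unit cluster
  expect_gt(median(d[10, -10]), 4 * med_all) # the distant practice exceeds it

  # regular polygon: symmetry gives no outliers
  ang <- 2 * pi * (0:7) / 8
  reg <- spatial_layout(cbind(cos(ang), sin(ang)), ids = letters[1:8])
  expect_length(spatial_outliers(letters[1:8], reg), 0)

  expect_error(spatial_outliers(letters[1:2], reg), "size filter")
})

square_layout <- function(extra) {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), extra)
  spatial_layout(pts, ids = sprintf("G%d", seq_len(nrow(pts))))
}

test_that("hull containment matches hand-computed fractions", {
  # 4 members on a square, one foreign practice at the centre -> 1/5
  layout <- square_layout(c(0.5, 0.5))
  res <- hull_containment(sprintf("G%d", 1:4), layout)
  expect_equal(res$fraction, 1 / 5)
  expect_equal(res$foreign, "G5")

  # two foreign practices inside -> 2/6
  layout <- square_layout(rbind(c(0.5, 0.5), c(0.25, 0.75)))
  res <- hull_containment(sprintf("G%d", 1:4), layout)
  expect_equal(res$fraction, 2 / 6)

  # no foreign practice inside -> 0
  layout <- square_layout(c(5, 5))
  res <- hull_containment(sprintf("G%d", 1:4), layout)
  expect_equal(res$fraction, 0)

  # boundary points count as inside
  layout <- square_layout(c(0.5, 0))
  res <- hull_containment(sprintf("G%d", 1:4), layout)
  expect_equal(res$fraction, 1 / 5)

  # collinear members: degenerate hull, computed on the segment
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0), c(1.5, 0), c(5, 5))
  layout <- spatial_layout(pts, ids = sprintf("G%d", 1:5))
  res <- hull_containment(sprintf("G%d", 1:3), layout)
  expect_true(res$degenerate)
  expect_equal(res$foreign, "G4")
  expect_equal(res$fraction, 1 / 4)
})

test_that("size bounds behave as specified at the boundaries", {
  set.seed(202)
  mk_partition <- function(sizes) {
    labels <- rep(seq_along(sizes), sizes)
    n <- sum(sizes)
    # compact, well-separated clusters so only size can exclude
    xy <- cbind(labels * 100 + rnorm(n, sd = 0.5), rnorm(n, sd = 0.5))
    ids <- sprintf("G%03d", seq_len(n))
    names(labels) <- ids
    list(labels = labels, layout = spatial_layout(xy, ids = ids))
  }
  p <- mk_partition(c(2, 3, 20, 21, 8))
  f <- filter_communities(p$labels, p$layout)
  sizes_valid <- sort(lengths(f$valid))
  expect_equal(unname(sizes_valid), c(3, 8, 20))      # 2 and 21 excluded
  expect_setequal(unique(f$exclusions$reason),
                  c("small_community", "large_community"))
  # conservation: valid + excluded = all practices
  expect_equal(f$score + nrow(f$exclusions), length(p$labels))
})

test_that("containment-mixed communities are excluded", {
  # two interleaved communities occupying the same footprint
  set.seed(203)
  xy <- rbind(cbind(rnorm(6), rnorm(6)), cbind(rnorm(6), rnorm(6)))
  ids <- sprintf("G%02d", 1:12)
  labels <- rep(1:2, each = 6)
  names(labels) <- ids
  layout <- spatial_layout(xy, ids = ids)
  f <- filter_communities(labels, layout)
  expect_true("containment" %in% f$exclusions$reason)
})

test_that("an injected remote practice is flagged, and only it", {
  set.seed(204)
  xy <- cbind(rnorm(9), rnorm(9))
  xy <- rbind(xy, c(500, 0))
  ids <- sprintf("G%02d", 1:10)
  labels <- rep(1, 10)
  names(labels) <- ids
  layout <- spatial_layout(xy, ids = ids)
  f <- filter_communities(labels, layout)
  flagged <- f$exclusions$gp_id[f$exclusions$reason == "outlier"]
  expect_equal(flagged, "G10")
  expect_equal(unname(lengths(f$valid)), 9)
})

test_that("score accounting is exact arithmetic", {
  filtered <- list(valid = list("1" = letters[1:8], "2" = letters[9:13],
                                "3" = letters[14:25]))
  expect_equal(score_partition(filtered), 25)
  expect_equal(score_partition(list(valid = list())), 0)
})
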