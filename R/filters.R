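#' Pairwise straight-line distances between practices
#'
#' @param coords data frame or matrix with columns x, y (rows named or
#'   ordered by practice); a matrix of planar projected coordinates.
#' @param ids optional practice ids (defaults to rownames / gp_id column).
#' @return object of class `spatial_layout`: list with `coords` (n x 2
#'   matrix) and `dist` (symmetric Euclidean distance matrix).
#' @export
spatial_layout <- function(coords, ids = NULL) {
  if (is.data.frame(coords)) {
    if (is.null(ids) && "gp_id" %in% names(coords)) ids <- coords$gp_id
    coords <- as.matrix(coords[, c("x", "y")])
  }
  stopifnot(is.numeric(coords), ncol(coords) == 2, all(is.finite(coords)))
  if (!is.null(ids)) rownames(coords) <- ids
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(rownames(coords), rownames(coords))
  structure(list(coords = coords, dist = d), class = "spatial_layout")
}

#' Spatial outliers within a community
#'
#' Flags members of a practice community that are geographically remote from
#' it: a practice is an outlier when its median distance to the other
#' members exceeds `factor` times the community-wide median pairwise
#' distance. Both medians are computed once from the original membership
#' (a single pass; no recomputation after removals).
#'
#' @param members practice ids (or indices) of the community; at least 3.
#' @param layout a [spatial_layout()].
#' @param factor multiple of the community median that defines remoteness.
#' @return character/integer vector of the members flagged as outliers
#'   (possibly empty).
#' @export
spatial_outliers <- function(members, layout, factor = 4) {
  stopifnot(inherits(layout, "spatial_layout"))
  check_that(length(members) >= 3,
             "community smaller than 3: route to the size filter")
  d <- layout$dist[members, members, drop = FALSE]
  med_all <- stats::median(d[upper.tri(d)])
  # median distance of each member to its co-members (self excluded)
  med_i <- vapply(seq_along(members), function(i) stats::median(d[i, -i]), 0)
  members[med_i > factor * med_all]
}

# Point-in-polygon, boundary inclusive. Vertices as an n x 2 matrix (open
# ring). Degenerate polygons (all vertices collinear) reduce to on-segment
# tests against the hull's extreme points.
point_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  poly <- matrix(as.numeric(poly), ncol = 2)
  nv <- nrow(poly)
  on_segment <- function(p, a, b) {
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > tol * max(1, sum(abs(b - a)))) return(FALSE)
    dot <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
    len2 <- sum((b - a)^2)
    dot >= -tol && dot <= len2 + tol
  }
  apply(pts, 1, function(p) {
    # boundary first
    for (v in seq_len(nv)) {
      a <- poly[v, ]; b <- poly[if (v == nv) 1L else v + 1L, ]
      if (on_segment(p, a, b)) return(TRUE)
    }
    if (nv < 3L) return(FALSE)
    # ray casting
    inside <- FALSE
    j <- nv
    for (v in seq_len(nv)) {
      yi <- poly[v, 2]; yj <- poly[j, 2]
      if ((yi > p[2]) != (yj > p[2])) {
        xint <- poly[v, 1] + (p[2] - yi) / (yj - yi) * (poly[j, 1] - poly[v, 1])
        if (p[1] < xint) inside <- !inside
      }
      j <- v
    }
    inside
  })
}

#' Foreign-practice containment of a community's convex hull
#'
#' Builds the convex hull of the member practices and measures how mixed the
#' community's footprint is: the fraction of all practices lying inside the
#' hull (members plus non-members; boundary points count as inside) that are
#' not members. Collinear memberships give a degenerate segment hull;
#' containment is then computed on the segment.
#'
#' @param members member practice ids (or indices); at least 3 after outlier
#'   removal.
#' @param layout a [spatial_layout()] over all practices.
#' @return list with `fraction` (foreign / all inside), `foreign` (ids of
#'   contained non-members), `degenerate` (TRUE for a zero-area hull).
#' @export
hull_containment <- function(members, layout) {
  stopifnot(inherits(layout, "spatial_layout"))
  all_ids <- rownames(layout$coords)
  if (is.null(all_ids)) all_ids <- seq_len(nrow(layout$coords))
  mc <- layout$coords[members, , drop = FALSE]
  hull <- grDevices::chull(mc[, 1], mc[, 2])
  poly <- mc[hull, , drop = FALSE]
  degenerate <- nrow(poly) < 3
  foreign_ids <- setdiff(all_ids, members)
  if (length(foreign_ids) == 0L) {
    return(list(fraction = 0, foreign = foreign_ids[0], degenerate = degenerate))
  }
  fc <- layout$coords[foreign_ids, , drop = FALSE]
  inside <- point_in_polygon(fc, poly)
  foreign <- foreign_ids[inside]
  # members are inside their own hull by construction
  fraction <- length(foreign) / (length(members) + length(foreign))
  list(fraction = fraction, foreign = foreign, degenerate = degenerate)
}

#' Geographic validity filter for candidate PCN communities
#'
#' Applies the validity pipeline to each community of a partition: remove
#' spatial outliers (communities of size >= 3 only), require the surviving
#' size to lie in `[min_size, max_size]`, and require the foreign-practice
#' containment of the convex hull to be at most `max_containment`.
#' Communities failing any check are excluded whole; every excluded practice
#' is logged with the first reason that removed it.
#'
#' @param partition a `partition` (or a named label vector).
#' @param layout a [spatial_layout()] over the partition's practices.
#' @param min_size,max_size inclusive bounds on community size.
#' @param max_containment maximum tolerated foreign-containment fraction
#'   (exceeding it — strictly — excludes the community).
#' @param outlier_factor passed to [spatial_outliers()].
#' @return list with `valid` (named list: community label -> member ids),
#'   `exclusions` (data frame gp_id, reason in
#'   outlier/small_community/large_community/containment), `score` (number
#'   of practices in valid communities).
#' @export
filter_communities <- function(partition, layout, min_size = 3, max_size = 20,
                               max_containment = 0.25, outlier_factor = 4) {
  labels <- if (inherits(partition, "partition")) partition$labels else partition
  ids <- names(labels)
  check_that(!is.null(ids), "partition labels must be named by practice id")
  comms <- split(ids, labels)
  valid <- list()
  excl <- list()
  note <- function(gp, reason) data.frame(gp_id = gp, reason = reason,
                                          stringsAsFactors = FALSE)
  for (lab in names(comms)) {
    members <- comms[[lab]]
    if (length(members) >= 3) {
      out <- spatial_outliers(members, layout, factor = outlier_factor)
      if (length(out) > 0) {
        excl[[length(excl) + 1L]] <- note(out, "outlier")
        members <- setdiff(members, out)
      }
    }
    if (length(members) < min_size) {
      excl[[length(excl) + 1L]] <- note(members, "small_community")
      next
    }
    if (length(members) > max_size) {
      excl[[length(excl) + 1L]] <- note(members, "large_community")
      next
    }
    cont <- hull_containment(members, layout)
    if (cont$fraction > max_containment) {
      excl[[length(excl) + 1L]] <- note(members, "containment")
      next
    }
    valid[[lab]] <- members
  }
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(gp_id = character(), reason = character(), stringsAsFactors = FALSE)
  list(valid = valid, exclusions = exclusions,
       score = sum(lengths(valid)))
}

#' Number of practices in valid communities
#'
#' @param filtered a [filter_communities()] result.
#' @return the partition score: total member count of valid communities.
#' @export
score_partition <- function(filtered) {
  sum(lengths(filtered$valid))
}
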