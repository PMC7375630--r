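#' Generate a synthetic city with planted practice communities
#'
#' Builds a planar city of LSOA centroids and general-practice locations with
#' a planted community structure: `k` spatial cluster centres are placed
#' evenly on a circle (one at the origin for `k = 1`) and each LSOA and
#' practice is scattered around the centre of its planted community. The
#' first `k` LSOAs and the first `k` practices are allocated to communities
#' 1..k round-robin so every planted community is non-empty by construction;
#' the remainder are filled at random. Each practice belongs to a CCG that
#' coincides with its planted community, giving a known administrative truth
#' for span statistics.
#'
#' Distances are planar Euclidean in arbitrary units; there is no geodesy.
#'
#' @param n_lsoa number of LSOAs (small-area geographies of residence).
#' @param n_gp number of general practices.
#' @param k number of planted communities; must satisfy `k <= n_gp` and
#'   `k <= n_lsoa`.
#' @param lambda decay length of the registration kernel `exp(-d/lambda)`,
#'   in the same arbitrary units as the coordinates.
#' @param epsilon leakage probability multiplier in `[0, 1)` applied to
#'   registrations that cross planted-community boundaries; `0` forbids them.
#' @param seed integer seed; the city is fully reproducible from it.
#' @param centre_spacing approximate distance between neighbouring community
#'   centres.
#' @param cluster_sd standard deviation of the Gaussian scatter of LSOAs and
#'   practices around their community centre.
#' @return an object of class `synthetic_city`: a list with data frames
#'   `lsoas` (lsoa_id, x, y, population, planted), `gps`
#'   (gp_id, x, y, ccg_id, planted) and the generating `params`.
#' @seealso [sample_registrations()]
#' @export
generate_city <- function(n_lsoa, n_gp, k, lambda = 15, epsilon = 0.05,
                          seed = 1L, centre_spacing = 40, cluster_sd = 6) {
  check_that(k >= 1 && n_gp >= k && n_lsoa >= k,
             "invalid configuration: need n_gp >= k >= 1 and n_lsoa >= k")
  check_that(lambda > 0, "lambda must be positive")
  check_that(epsilon >= 0 && epsilon < 1, "epsilon must lie in [0, 1)")
  set.seed(seed)

  if (k == 1L) {
    centres <- matrix(0, nrow = 1, ncol = 2)
  } else {
    radius <- centre_spacing / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1) / k
    centres <- cbind(radius * cos(ang), radius * sin(ang))
  }

  alloc <- function(n) {
    if (n == k) seq_len(k) else c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  }
  lsoa_comm <- alloc(n_lsoa)
  gp_comm <- alloc(n_gp)

  lsoas <- data.frame(
    lsoa_id = sprintf("L%04d", seq_len(n_lsoa)),
    x = centres[lsoa_comm, 1] + stats::rnorm(n_lsoa, sd = cluster_sd),
    y = centres[lsoa_comm, 2] + stats::rnorm(n_lsoa, sd = cluster_sd),
    population = sample(1200:2500, n_lsoa, replace = TRUE),
    planted = lsoa_comm,
    stringsAsFactors = FALSE
  )
  gps <- data.frame(
    gp_id = sprintf("G%03d", seq_len(n_gp)),
    x = centres[gp_comm, 1] + stats::rnorm(n_gp, sd = cluster_sd),
    y = centres[gp_comm, 2] + stats::rnorm(n_gp, sd = cluster_sd),
    ccg_id = sprintf("CCG%02d", gp_comm),
    planted = gp_comm,
    stringsAsFactors = FALSE
  )

  structure(
    list(lsoas = lsoas, gps = gps,
         params = list(n_lsoa = n_lsoa, n_gp = n_gp, k = k, lambda = lambda,
                       epsilon = epsilon, seed = seed,
                       centre_spacing = centre_spacing, cluster_sd = cluster_sd)),
    class = "synthetic_city"
  )
}

#' @export
print.synthetic_city <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic city: %d LSOAs, %d practices, %d planted communities\n",
    p$n_lsoa, p$n_gp, p$k))
  cat(sprintf("  decay length %.3g, leakage %.3g, seed %d\n",
              p$lambda, p$epsilon, p$seed))
  invisible(x)
}

#' Sample a patient registration table from a synthetic city
#'
#' Draws patients resident in each LSOA and registers each with one practice:
#' a patient in LSOA i picks practice j with probability proportional to
#' `exp(-d_ij / lambda)` times 1 inside the planted community and `epsilon`
#' across communities. Every patient receives one record for their true
#' (LSOA, practice) pair; with probability `dup_rate` a patient additionally
#' gains conflicting records for a different pair, constructed so that the
#' true pair always wins deduplication — either by strictly higher record
#' frequency or, on a frequency tie, by carrying the strictly latest record
#' date. Ground truth is therefore exactly recoverable.
#'
#' @param city a [generate_city()] result.
#' @param patients_per_lsoa number of patients drawn in each LSOA.
#' @param dup_rate probability in `[0, 1)` that a patient carries conflicting
#'   duplicate records.
#' @param seed integer seed; the table is reproducible from it.
#' @param date_window two dates (coercible via `as.Date`) bounding all record
#'   dates.
#' @return a list of class `registration_table` with elements `records`
#'   (data frame: patient_id, lsoa_id, gp_id, record_date) and `truth`
#'   (data frame: patient_id, lsoa_id, gp_id — the planted registration).
#' @export
sample_registrations <- function(city, patients_per_lsoa = 50, dup_rate = 0.1,
                                 seed = 1L,
                                 date_window = c("2017-04-01", "2018-03-31")) {
  stopifnot(inherits(city, "synthetic_city"))
  check_that(dup_rate >= 0 && dup_rate < 1, "dup_rate must lie in [0, 1)")
  set.seed(seed)
  window <- as.Date(date_window)
  n_days <- as.integer(window[2] - window[1]) + 1L
  check_that(n_days > 2L, "date window too narrow")

  lam <- city$params$lambda
  eps <- city$params$epsilon
  gx <- city$gps$x; gy <- city$gps$y
  n_gp <- nrow(city$gps); n_lsoa <- nrow(city$lsoas)

  # true (lsoa, gp) pair per patient
  pat_lsoa <- rep(seq_len(n_lsoa), each = patients_per_lsoa)
  pat_gp <- integer(length(pat_lsoa))
  for (i in seq_len(n_lsoa)) {
    d <- sqrt((gx - city$lsoas$x[i])^2 + (gy - city$lsoas$y[i])^2)
    w <- exp(-d / lam) *
      ifelse(city$gps$planted == city$lsoas$planted[i], 1, eps)
    if (all(w <= 0)) {
      stop(sprintf("invalid configuration: LSOA %s has no admissible practice",
                   city$lsoas$lsoa_id[i]), call. = FALSE)
    }
    idx <- which(pat_lsoa == i)
    pat_gp[idx] <- sample.int(n_gp, length(idx), replace = TRUE, prob = w)
  }

  n_pat <- length(pat_lsoa)
  patient_id <- sprintf("P%06d", seq_len(n_pat))
  # true dates kept in the later half of the window so duplicates can always
  # be placed strictly earlier
  true_day <- sample.int(n_days %/% 2, n_pat, replace = TRUE) + n_days %/% 2

  records <- data.frame(
    patient_id = patient_id,
    lsoa_id = city$lsoas$lsoa_id[pat_lsoa],
    gp_id = city$gps$gp_id[pat_gp],
    record_date = window[1] + (true_day - 1L),
    stringsAsFactors = FALSE
  )

  dup <- which(stats::runif(n_pat) < dup_rate)
  if (length(dup) > 0L) {
    # conflicting pair: a different practice (or, failing that, a different
    # LSOA), dated strictly before every true record of the patient
    alt_gp <- vapply(dup, function(p) {
      if (n_gp > 1L) sample(setdiff(seq_len(n_gp), pat_gp[p]), 1L) else pat_gp[p]
    }, integer(1))
    alt_lsoa <- pat_lsoa[dup]
    same_pair <- alt_gp == pat_gp[dup]
    if (any(same_pair)) {
      check_that(n_lsoa > 1L, "cannot build conflicting duplicates: one LSOA and one practice")
      alt_lsoa[same_pair] <- vapply(dup[same_pair], function(p) {
        sample(setdiff(seq_len(n_lsoa), pat_lsoa[p]), 1L)
      }, integer(1))
    }
    dup_day <- vapply(true_day[dup], function(d) sample.int(d - 1L, 1L), integer(1))
    dup_records <- data.frame(
      patient_id = patient_id[dup],
      lsoa_id = city$lsoas$lsoa_id[alt_lsoa],
      gp_id = city$gps$gp_id[alt_gp],
      record_date = window[1] + (dup_day - 1L),
      stringsAsFactors = FALSE
    )
    # half the duplicated patients get an extra true record so the true pair
    # wins on frequency; the other half tie on frequency and win on recency
    extra <- dup[stats::runif(length(dup)) < 0.5]
    if (length(extra) > 0L) {
      extra_records <- records[extra, , drop = FALSE]
      extra_records$record_date <- extra_records$record_date - 1L
      dup_records <- rbind(dup_records, extra_records)
    }
    records <- rbind(records, dup_records)
  }
  records <- records[order(records$patient_id, records$record_date,
                           records$lsoa_id, records$gp_id), , drop = FALSE]
  rownames(records) <- NULL

  truth <- data.frame(
    patient_id = patient_id,
    lsoa_id = city$lsoas$lsoa_id[pat_lsoa],
    gp_id = city$gps$gp_id[pat_gp],
    stringsAsFactors = FALSE
  )

  structure(list(records = records, truth = truth,
                 params = list(patients_per_lsoa = patients_per_lsoa,
                               dup_rate = dup_rate, seed = seed,
                               date_window = window)),
            class = "registration_table")
}

#' @export
print.registration_table <- function(x, ...) {
  cat(sprintf("Registration table: %d records for %d patients\n",
              nrow(x$records), nrow(x$truth)))
  invisible(x)
}

#' Write city metadata and a registration table as CSV
#'
#' Emits `lsoas.csv` (id,x,y,population,planted), `gps.csv`
#' (id,x,y,ccg,planted) and `registrations.csv`
#' (patient_id,lsoa_id,gp_id,record_date ISO-8601) under `dir`.
#'
#' @param city a [generate_city()] result.
#' @param registrations a [sample_registrations()] result (optional).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_city <- function(city, registrations = NULL, dir) {
  stopifnot(inherits(city, "synthetic_city"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(lsoas = file.path(dir, "lsoas.csv"),
             gps = file.path(dir, "gps.csv"))
  utils::write.csv(city$lsoas, paths[["lsoas"]], row.names = FALSE)
  utils::write.csv(city$gps, paths[["gps"]], row.names = FALSE)
  if (!is.null(registrations)) {
    stopifnot(inherits(registrations, "registration_table"))
    paths <- c(paths, registrations = file.path(dir, "registrations.csv"))
    rec <- registrations$records
    rec$record_date <- format(rec$record_date, "%Y-%m-%d")
    utils::write.csv(rec, paths[["registrations"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Square LSOA tile polygons as GeoJSON
#'
#' Writes one axis-aligned square tile per LSOA centroid (a lightweight
#' stand-in for census boundary polygons) as a GeoJSON FeatureCollection with
#' the LSOA attributes, plus any extra per-LSOA properties supplied.
#'
#' @param city a [generate_city()] result.
#' @param path output file path.
#' @param size tile side length; defaults to the generator's cluster scale.
#' @param properties optional data frame of extra properties with one row per
#'   LSOA, in city order.
#' @return invisibly, `path`.
#' @export
lsoa_tiles_geojson <- function(city, path, size = city$params$cluster_sd,
                               properties = NULL) {
  stopifnot(inherits(city, "synthetic_city"))
  h <- size / 2
  feats <- lapply(seq_len(nrow(city$lsoas)), function(i) {
    r <- city$lsoas[i, ]
    ring <- list(c(r$x - h, r$y - h), c(r$x + h, r$y - h),
                 c(r$x + h, r$y + h), c(r$x - h, r$y + h), c(r$x - h, r$y - h))
    props <- list(lsoa_id = r$lsoa_id, population = r$population,
                  planted = r$planted)
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
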