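#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]. All
#' grid constants default to the study-scale settings: 40 pruning
#' parameters in `[2.1, 6.0]`, 400 log-spaced Markov times in `[0.01, 1]`,
#' 500 Louvain runs per model. Configurations round-trip losslessly through
#' YAML via [read_config()] / [write_config()].
#'
#' @param registrations,practices,lsoas input CSV paths (`lsoas` optional).
#' @param out_dir output directory for all artifacts.
#' @param gamma_min,gamma_max,gamma_n RMST pruning-parameter grid.
#' @param t_min,t_max,t_n,t_spacing Markov-time grid (`"log"` or
#'   `"linear"`).
#' @param runs_per_model Louvain repeats per grid point.
#' @param min_patients small-practice exclusion threshold.
#' @param outlier_factor,min_size,max_size,max_containment geographic
#'   validity controls.
#' @param rmst_variant `"divide"` or `"multiply"`, see [rmst_sparsify()].
#' @param flavour stability flavour, see [stability_matrix()].
#' @param normalise profile orientation, see [gp_profiles()].
#' @param master_seed integer master seed for the whole grid.
#' @param geojson also write PCN catchment/tile GeoJSON when LSOA metadata
#'   is available.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(registrations, practices, lsoas = NULL,
                            out_dir = "pcn-out",
                            gamma_min = 2.1, gamma_max = 6.0, gamma_n = 40,
                            t_min = 0.01, t_max = 1, t_n = 400,
                            t_spacing = c("log", "linear"),
                            runs_per_model = 500, min_patients = 100,
                            outlier_factor = 4, min_size = 3, max_size = 20,
                            max_containment = 0.25,
                            rmst_variant = c("divide", "multiply"),
                            flavour = c("exponential", "linearised"),
                            normalise = c("practice", "lsoa"),
                            master_seed = 1L, geojson = TRUE) {
  cfg <- list(registrations = registrations, practices = practices,
              lsoas = lsoas, out_dir = out_dir,
              gamma_min = gamma_min, gamma_max = gamma_max,
              gamma_n = as.integer(gamma_n),
              t_min = t_min, t_max = t_max, t_n = as.integer(t_n),
              t_spacing = match.arg(t_spacing),
              runs_per_model = as.integer(runs_per_model),
              min_patients = min_patients,
              outlier_factor = outlier_factor,
              min_size = min_size, max_size = max_size,
              max_containment = max_containment,
              rmst_variant = match.arg(rmst_variant),
              flavour = match.arg(flavour),
              normalise = match.arg(normalise),
              master_seed = as.integer(master_seed), geojson = geojson)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  check_that(cfg$gamma_n >= 1 && cfg$t_n >= 1, "grids must be non-empty")
  check_that(cfg$gamma_min > 0 && cfg$t_min > 0, "grid minima must be positive")
  check_that(cfg$runs_per_model >= 1, "runs_per_model must be positive")
  check_that(cfg$min_patients >= 0 && cfg$outlier_factor > 0 &&
               cfg$min_size >= 1 && cfg$max_size >= cfg$min_size &&
               cfg$max_containment >= 0, "thresholds out of range")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` invisibly returns `path`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[!vapply(cfg, is.null, TRUE)])
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_grids <- function(cfg) {
  times <- if (cfg$t_spacing == "log") {
    markov_grid(cfg$t_n, cfg$t_min, cfg$t_max)
  } else {
    seq(cfg$t_min, cfg$t_max, length.out = cfg$t_n)
  }
  list(gammas = gamma_grid(cfg$gamma_n, cfg$gamma_min, cfg$gamma_max),
       markov_times = times)
}

#' Run the full PCN discovery pipeline from files
#'
#' Reads the registration table and metadata CSVs named in the
#' configuration, fits the model with [pcn_fit()], and writes every
#' intermediate and final artifact under `out_dir`: the sparse registration
#' matrix (triplet CSV), LSOA market concentration, similarity and
#' sparsened edge lists, the full grid as JSON lines, the exclusion log,
#' PCN membership / LSOA assignment / PCN summary CSVs, `metrics.json`
#' (all summary quantiles), a provenance `manifest.json` (config, its hash,
#' seed, package and R versions), and — when LSOA metadata is present and
#' `geojson` is enabled — PCN catchment tiles as GeoJSON. Reruns with the
#' same configuration and seed reproduce `metrics.json` byte-identically.
#'
#' @param cfg a `pipeline_config` (or path to its YAML file).
#' @return invisibly, a list with the fitted `pcn_fit` and the named vector
#'   of `paths` written.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  records <- stage("read_registrations", {
    check_that(file.exists(cfg$registrations),
               paste("missing input:", cfg$registrations))
    utils::read.csv(cfg$registrations, stringsAsFactors = FALSE)
  })
  practices <- stage("read_practices", {
    df <- utils::read.csv(cfg$practices, stringsAsFactors = FALSE)
    names(df)[names(df) == "id"] <- "gp_id"
    names(df)[names(df) == "ccg"] <- "ccg_id"
    df
  })
  lsoas <- NULL
  if (!is.null(cfg$lsoas) && nzchar(cfg$lsoas)) {
    lsoas <- stage("read_lsoas", {
      df <- utils::read.csv(cfg$lsoas, stringsAsFactors = FALSE)
      names(df)[names(df) == "id"] <- "lsoa_id"
      df
    })
  }

  grids <- config_grids(cfg)
  fit <- stage("fit", pcn_fit(
    records, practices, lsoas = lsoas, min_patients = cfg$min_patients,
    gammas = grids$gammas, markov_times = grids$markov_times,
    runs_per_model = cfg$runs_per_model, master_seed = cfg$master_seed,
    flavour = cfg$flavour, rmst_variant = cfg$rmst_variant,
    min_size = cfg$min_size, max_size = cfg$max_size,
    max_containment = cfg$max_containment,
    outlier_factor = cfg$outlier_factor, normalise = cfg$normalise))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  paths <- c()

  stage("write_artifacts", {
    # registration matrix as sparse triplets
    idx <- which(fit$matrix$counts > 0, arr.ind = TRUE)
    trip <- data.frame(lsoa_id = rownames(fit$matrix$counts)[idx[, 1]],
                       gp_id = colnames(fit$matrix$counts)[idx[, 2]],
                       count = fit$matrix$counts[idx], stringsAsFactors = FALSE)
    trip <- trip[order(trip$lsoa_id, trip$gp_id), , drop = FALSE]
    utils::write.csv(trip, p("registration_matrix.csv"), row.names = FALSE)
    utils::write.csv(fit$market[, c("lsoa_id", "hhi", "ems")],
                     p("lsoa_market.csv"), row.names = FALSE)
    write_edge_list(fit$similarity, p("similarity_edges.csv"))
    write_edge_list(fit$grid$best$sparse_graph, p("rmst_edges.csv"))
    write_grid_jsonl(fit$grid, p("grid.jsonl"))
    utils::write.csv(fit$grid$best$filtered$exclusions, p("exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(gp_id = names(fit$membership),
                                pcn_id = fit$membership),
                     p("pcn_membership.csv"), row.names = FALSE)
    utils::write.csv(fit$assignment$table[, c("lsoa_id", "pcn", "coverage_pct")],
                     p("lsoa_assignment.csv"), row.names = FALSE)
    pc <- merge(as.data.frame(fit$catalogue), fit$coverage$pcn, by = "pcn")
    utils::write.csv(pc[, c("pcn", "n_practices", "list_size", "n_ccgs",
                            "coverage_pct")],
                     p("pcn_summary.csv"), row.names = FALSE)
    paths <- c(registration_matrix = p("registration_matrix.csv"),
                lsoa_market = p("lsoa_market.csv"),
                similarity_edges = p("similarity_edges.csv"),
                rmst_edges = p("rmst_edges.csv"),
                grid = p("grid.jsonl"), exclusions = p("exclusions.csv"),
                pcn_membership = p("pcn_membership.csv"),
                lsoa_assignment = p("lsoa_assignment.csv"),
                pcn_summary = p("pcn_summary.csv"))
  })

  stage("write_metrics", {
    s <- summary(fit)
    metrics <- list(optimum = s$optimum,
                    n_pcns = s$n_pcns, n_practices = s$n_practices,
                    n_grouped = s$n_grouped,
                    pcn_size = s$pcn_size, list_size = s$list_size,
                    ccg_span = as.list(stats::setNames(as.integer(s$ccg_span),
                                                       names(s$ccg_span))),
                    lsoa_ems = s$lsoa_ems, coverage = s$coverage,
                    exclusions = as.list(stats::setNames(as.integer(s$exclusions),
                                                         names(s$exclusions))))
    jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, metrics = p("metrics.json"))
  })

  stage("write_manifest", {
    cfg_path <- p("config.yaml")
    write_config(cfg, cfg_path)
    manifest <- list(config = unclass(cfg),
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     master_seed = cfg$master_seed,
                     package = "pcnets",
                     package_version = as.character(utils::packageVersion("pcnets")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, config = cfg_path, manifest = p("manifest.json"))
  })

  if (isTRUE(cfg$geojson) && !is.null(lsoas)) {
    stage("write_geojson", {
      paths <- c(paths, catchments = write_catchments_geojson(
        fit, lsoas, p("pcn_catchments.geojson")))
    })
  }

  invisible(list(fit = fit, paths = paths))
}

#' Export PCN catchments as GeoJSON
#'
#' Writes one square tile per LSOA (centred on its centroid) with its
#' assigned PCN and coverage attached, plus one convex-hull polygon per PCN
#' over its member practices with the PCN summary attached — a plain
#' choropleth-ready export.
#'
#' @param fit a `pcn_fit`.
#' @param lsoas LSOA metadata (lsoa_id, x, y, population).
#' @param path output GeoJSON path.
#' @param tile_size square tile side length; default the median
#'   nearest-neighbour spacing of the LSOA centroids.
#' @return `path`, invisibly.
#' @export
write_catchments_geojson <- function(fit, lsoas, path, tile_size = NULL) {
  stopifnot(inherits(fit, "pcn_fit"),
            all(c("lsoa_id", "x", "y") %in% names(lsoas)))
  if (is.null(tile_size)) {
    d <- as.matrix(stats::dist(cbind(lsoas$x, lsoas$y)))
    diag(d) <- Inf
    tile_size <- stats::median(apply(d, 1, min))
  }
  h <- tile_size / 2
  atab <- fit$assignment$table
  ix <- match(lsoas$lsoa_id, atab$lsoa_id)
  square <- function(x, y) list(c(x - h, y - h), c(x + h, y - h),
                                c(x + h, y + h), c(x - h, y + h),
                                c(x - h, y - h))
  tiles <- lapply(seq_len(nrow(lsoas)), function(i) {
    list(type = "Feature",
         properties = list(kind = "lsoa_tile",
                           lsoa_id = lsoas$lsoa_id[i],
                           pcn = if (is.na(ix[i])) NULL else atab$pcn[ix[i]],
                           coverage_pct = if (is.na(ix[i])) NULL else
                             atab$coverage_pct[ix[i]]),
         geometry = list(type = "Polygon",
                         coordinates = list(square(lsoas$x[i], lsoas$y[i]))))
  })
  coords <- fit$layout$coords
  hulls <- lapply(seq_len(nrow(fit$catalogue)), function(pi) {
    prow <- fit$catalogue[pi, ]
    mc <- coords[!is.na(fit$membership) & fit$membership == prow$pcn, ,
                 drop = FALSE]
    hch <- grDevices::chull(mc[, 1], mc[, 2])
    ring <- lapply(c(hch, hch[1]), function(j) c(mc[j, 1], mc[j, 2]))
    list(type = "Feature",
         properties = list(kind = "pcn_hull", pcn = prow$pcn,
                           n_practices = prow$n_practices,
                           list_size = prow$list_size, n_ccgs = prow$n_ccgs),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = c(tiles, hulls))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
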