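#' Fit Primary Care Networks from patient registration records
#'
#' The one-stop model fit. From a patient-level registration table and
#' practice metadata it runs the full discovery pipeline: deduplicate
#' patients, build the LSOA-by-practice registration matrix with the
#' small-practice exclusion, compute LSOA market concentration (HHI and
#' equivalent market size), build the practice cosine-similarity network,
#' and search the (RMST pruning parameter, Markov time) grid — sparsifying,
#' running repeated Louvain optimisation of Markov stability, taking
#' consensus partitions, and applying the geographic validity filters. The
#' partition with the most practices in valid communities is selected;
#' LSOAs are then assigned to PCNs by modal registration and catchment
#' coverage and PCN-level concentration are reported.
#'
#' @param records registration records: a `registration_table` from
#'   [sample_registrations()], or a data frame with columns patient_id,
#'   lsoa_id, gp_id, record_date.
#' @param practices practice metadata: data frame with columns gp_id, x, y,
#'   ccg_id and optionally list_size. When list_size is absent the observed
#'   deduplicated patient count per practice is used in its place.
#' @param lsoas optional LSOA metadata (data frame with lsoa_id, x, y,
#'   population), carried through to the fitted object for reporting and
#'   plotting.
#' @param min_patients small-practice exclusion threshold (strict lower
#'   bound on patients contributed).
#' @param gammas,markov_times,runs_per_model,master_seed,flavour,rmst_variant
#'   grid-search controls, see [grid_search()].
#' @param min_size,max_size,max_containment,outlier_factor geographic
#'   validity controls, see [filter_communities()].
#' @param normalise profile orientation, see [gp_profiles()].
#' @return an object of class `pcn_fit`; see Details for components.
#'   Components: `matrix` (`registration_matrix`), `market` (LSOA HHI/EMS),
#'   `similarity`, `layout`, `grid` (`grid_result`), `membership`,
#'   `assignment`, `coverage` (`coverage_report`), `catalogue`
#'   (`pcn_catalogue`), `dedup_info`, `practices`, `lsoas`, `call`.
#' @seealso [summary.pcn_fit()], [plot.pcn_fit()], [run_pipeline()]
#' @export
pcn_fit <- function(records, practices, lsoas = NULL, min_patients = 100,
                    gammas = gamma_grid(40), markov_times = markov_grid(400),
                    runs_per_model = 500, master_seed = 1L,
                    flavour = c("exponential", "linearised"),
                    rmst_variant = c("divide", "multiply"),
                    min_size = 3, max_size = 20, max_containment = 0.25,
                    outlier_factor = 4,
                    normalise = c("practice", "lsoa")) {
  cl <- match.call()
  stopifnot(all(c("gp_id", "x", "y", "ccg_id") %in% names(practices)))

  dedup <- deduplicate_patients(records)
  rm <- build_registration_matrix(dedup, min_patients = min_patients)
  missing_meta <- setdiff(rm$gp_ids, practices$gp_id)
  check_that(length(missing_meta) == 0,
             paste("practices missing metadata:", paste(missing_meta, collapse = ", ")))
  market <- lsoa_market_concentration(rm)
  sim <- practice_similarity(rm, normalise = match.arg(normalise))

  meta <- practices[match(rm$gp_ids, practices$gp_id), , drop = FALSE]
  if (!"list_size" %in% names(meta)) {
    meta$list_size <- unname(rm$col_totals)
  }
  layout <- spatial_layout(meta)

  grid <- grid_search(sim, layout, gammas = gammas,
                      markov_times = markov_times,
                      runs_per_model = runs_per_model,
                      master_seed = master_seed,
                      flavour = match.arg(flavour),
                      rmst_variant = match.arg(rmst_variant),
                      min_size = min_size, max_size = max_size,
                      max_containment = max_containment,
                      outlier_factor = outlier_factor)

  membership <- pcn_membership(grid$best$filtered, rm$gp_ids)
  assignment <- assign_lsoas(rm, membership)
  coverage <- coverage_statistics(assignment)
  catalogue <- pcn_summaries(membership, meta)

  structure(list(matrix = rm, market = market, similarity = sim,
                 layout = layout, grid = grid, membership = membership,
                 assignment = assignment, coverage = coverage,
                 catalogue = catalogue,
                 dedup_info = list(n_patients = nrow(dedup),
                                   n_double_ties = attr(dedup, "n_double_ties")),
                 practices = meta, lsoas = lsoas, call = cl),
            class = "pcn_fit")
}

#' @export
print.pcn_fit <- function(x, ...) {
  b <- x$grid$best
  n_gp <- length(x$membership)
  n_in <- sum(!is.na(x$membership))
  cat("Primary Care Network fit\n")
  cat(sprintf("  %d practices, %d LSOAs, %d patients\n",
              n_gp, nrow(x$matrix$counts), sum(x$matrix$counts)))
  cat(sprintf("  optimum at gamma = %.4g, Markov time = %.4g (grid of %d points)\n",
              b$gamma, b$t, nrow(x$grid$table)))
  cat(sprintf("  %d PCNs grouping %d practices (%.1f%%); %d unassigned\n",
              nrow(x$catalogue), n_in, 100 * n_in / n_gp, n_gp - n_in))
  invisible(x)
}

#' Summarise a PCN fit
#'
#' Headline descriptive statistics of the selected optimal partition: PCN
#' counts and sizes, list-size quartiles, CCG span distribution, LSOA and
#' PCN catchment coverage, and market concentration at practice and PCN
#' level.
#'
#' @param object a `pcn_fit`.
#' @param ... unused.
#' @return a list of class `summary.pcn_fit`.
#' @export
summary.pcn_fit <- function(object, ...) {
  x <- object
  cat_tab <- x$catalogue
  n_gp <- length(x$membership)
  spans <- if (nrow(cat_tab) > 0) table(cat_tab$n_ccgs) else table(integer())
  out <- list(
    n_practices = n_gp,
    n_grouped = sum(!is.na(x$membership)),
    n_pcns = nrow(cat_tab),
    optimum = list(gamma = x$grid$best$gamma, t = x$grid$best$t,
                   score = x$grid$best$score),
    pcn_size = if (nrow(cat_tab) > 0) summary_quantiles(cat_tab$n_practices) else NULL,
    list_size = if (nrow(cat_tab) > 0) summary_quantiles(cat_tab$list_size) else NULL,
    ccg_span = spans,
    lsoa_ems = summary_quantiles(x$market$ems),
    coverage = x$coverage$summary,
    exclusions = table(x$grid$best$filtered$exclusions$reason),
    n_double_ties = x$dedup_info$n_double_ties
  )
  class(out) <- "summary.pcn_fit"
  out
}

#' @export
print.summary.pcn_fit <- function(x, ...) {
  cat("Primary Care Network fit - summary\n")
  cat(sprintf("  optimum: gamma = %.4g, Markov time = %.4g\n",
              x$optimum$gamma, x$optimum$t))
  cat(sprintf("  %d PCNs; %d of %d practices grouped (%.1f%%)\n",
              x$n_pcns, x$n_grouped, x$n_practices,
              100 * x$n_grouped / x$n_practices))
  if (!is.null(x$pcn_size))
    cat(sprintf("  PCN size: median %d practices (range %d-%d)\n",
                as.integer(x$pcn_size$median), as.integer(x$pcn_size$min),
                as.integer(x$pcn_size$max)))
  if (!is.null(x$list_size))
    cat(sprintf("  PCN list size: median %.0f (IQR %.0f-%.0f)\n",
                x$list_size$median, x$list_size$q1, x$list_size$q3))
  if (length(x$ccg_span) > 0) {
    pct <- round(100 * as.numeric(x$ccg_span) / sum(x$ccg_span), 1)
    cat("  CCG span: ", paste0(names(x$ccg_span), " CCG(s): ", pct, "%",
                               collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  LSOA equivalent market size (practices): median %.2f (range %.2f-%.2f)\n",
              x$lsoa_ems$median, x$lsoa_ems$min, x$lsoa_ems$max))
  cs <- x$coverage
  cat(sprintf("  LSOA coverage: median %.1f%% (range %.1f-%.1f%%)\n",
              cs$lsoa_coverage$median, cs$lsoa_coverage$min, cs$lsoa_coverage$max))
  if (!is.null(cs$pcn_coverage))
    cat(sprintf("  PCN coverage: median %.1f%% (range %.1f-%.1f%%)\n",
                cs$pcn_coverage$median, cs$pcn_coverage$min, cs$pcn_coverage$max))
  cat(sprintf("  PCN-level EMS per LSOA: median %.2f\n", cs$pcn_ems$median))
  if (length(x$exclusions) > 0)
    cat("  excluded practices: ",
        paste0(names(x$exclusions), " = ", as.integer(x$exclusions),
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Plot a PCN fit
#'
#' Base-graphics map of the fitted configuration: practices coloured by
#' assigned PCN with convex-hull outlines per PCN; unassigned practices as
#' open circles; LSOA centroids (when available) as light grey points.
#'
#' @param x a `pcn_fit`.
#' @param show_lsoas draw LSOA centroids underneath.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.pcn_fit <- function(x, show_lsoas = TRUE, ...) {
  coords <- x$layout$coords
  memb <- x$membership
  pal <- grDevices::hcl.colors(max(1, nrow(x$catalogue)), "Dark 3")
  col <- ifelse(is.na(memb), NA, pal[memb])
  xlim <- range(coords[, 1]); ylim <- range(coords[, 2])
  if (show_lsoas && !is.null(x$lsoas)) {
    xlim <- range(xlim, x$lsoas$x); ylim <- range(ylim, x$lsoas$y)
  }
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = "x", ylab = "y",
                 main = "Primary Care Networks", ...)
  if (show_lsoas && !is.null(x$lsoas)) {
    graphics::points(x$lsoas$x, x$lsoas$y, pch = ".", col = "grey70")
  }
  for (p in unique(stats::na.omit(memb))) {
    mc <- coords[names(memb)[!is.na(memb) & memb == p], , drop = FALSE]
    if (nrow(mc) >= 3) {
      h <- grDevices::chull(mc[, 1], mc[, 2])
      graphics::polygon(mc[h, 1], mc[h, 2], border = pal[p], lty = 2)
    }
  }
  graphics::points(coords[, 1], coords[, 2], pch = ifelse(is.na(memb), 1, 19),
                   col = ifelse(is.na(memb), "grey40", col), cex = 0.9)
  invisible(x)
}
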