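#' Grid search over RMST pruning parameters and Markov times
#'
#' For every (gamma, t) pair: sparsify the similarity network with the RMST
#' at `gamma`, run Louvain optimisation of Markov stability at time `t`
#' `runs_per_model` times with derived seeds, take the consensus (most
#' common) partition, apply the geographic validity filter, and score the
#' partition by the number of practices in valid communities. The optimum is
#' the grid point with the highest score; ties go to smaller gamma, then
#' smaller t. The random-walk operators are diagonalised once per gamma and
#' reused across all Markov times.
#'
#' The study-scale default grid is 40 evenly spaced pruning parameters in
#' `[2.1, 6.0]` by 400 log-spaced Markov times in `[0.01, 1]` with 500 runs
#' per model; [markov_grid()] and [gamma_grid()] build grids of any size
#' with those endpoints.
#'
#' @param similarity a `similarity_graph`.
#' @param layout a [spatial_layout()] over the same practices.
#' @param gammas,markov_times numeric vectors of pruning parameters and
#'   Markov times.
#' @param runs_per_model Louvain repeats per grid point.
#' @param master_seed integer; per-(gamma, t, run) seeds are derived from it
#'   by a fixed counter scheme, so the whole grid is reproducible.
#' @param flavour stability flavour, see [stability_matrix()].
#' @param rmst_variant passed to [rmst_sparsify()].
#' @param min_size,max_size,max_containment,outlier_factor passed to
#'   [filter_communities()].
#' @return object of class `grid_result`: list with `table` (one row per
#'   grid point: gamma, t, n_communities, n_valid, score, n_excluded, r,
#'   multiplicity, error), `best` (list: gamma, t, partition, filtered), and the call
#'   parameters.
#' @export
grid_search <- function(similarity, layout, gammas = gamma_grid(40),
                        markov_times = markov_grid(400), runs_per_model = 500,
                        master_seed = 1L,
                        flavour = c("exponential", "linearised"),
                        rmst_variant = c("divide", "multiply"),
                        min_size = 3, max_size = 20, max_containment = 0.25,
                        outlier_factor = 4) {
  stopifnot(inherits(similarity, "similarity_graph"),
            inherits(layout, "spatial_layout"))
  check_that(length(gammas) > 0 && length(markov_times) > 0,
             "grids must be non-empty")
  flavour <- match.arg(flavour)
  rmst_variant <- match.arg(rmst_variant)
  d <- to_distance(similarity)

  rows <- list()
  best <- NULL
  for (gi in seq_along(gammas)) {
    gamma <- gammas[gi]
    model <- NULL
    sparse <- NULL
    stage_err <- tryCatch({
      sparse <- rmst_sparsify(d, gamma, variant = rmst_variant)
      model <- random_walk_operators(sparse)
      NA_character_
    }, error = function(e) conditionMessage(e))
    for (ti in seq_along(markov_times)) {
      t <- markov_times[ti]
      rec <- list(gamma = gamma, t = t, n_communities = NA_integer_,
                  n_valid = NA_integer_, score = 0L,
                  n_excluded = NA_integer_, r = NA_real_,
                  multiplicity = NA_integer_, error = stage_err)
      if (is.na(stage_err)) {
        res <- tryCatch({
          r <- stability_matrix(model, t, flavour)
          runs <- lapply(seq_len(runs_per_model), function(run) {
            louvain_optimise(model, t, r = r,
                             seed = derive_seed(master_seed, gi, ti, run))
          })
          cons <- consensus_partition(runs)
          filt <- filter_communities(cons, layout, min_size = min_size,
                                     max_size = max_size,
                                     max_containment = max_containment,
                                     outlier_factor = outlier_factor)
          list(cons = cons, filt = filt)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          rec$error <- conditionMessage(res)
        } else {
          rec$n_communities <- length(unique(res$cons$labels))
          rec$n_valid <- length(res$filt$valid)
          rec$score <- res$filt$score
          rec$n_excluded <- nrow(res$filt$exclusions)
          rec$r <- res$cons$r
          rec$multiplicity <- res$cons$multiplicity
          if (is.null(best) || rec$score > best$score) {
            best <- list(gamma = gamma, t = t, gamma_index = gi, t_index = ti,
                         score = rec$score, partition = res$cons,
                         filtered = res$filt, sparse_graph = sparse)
          }
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  check_that(!is.null(best), "every grid point failed")
  structure(list(table = tab, best = best,
                 params = list(gammas = gammas, markov_times = markov_times,
                               runs_per_model = runs_per_model,
                               master_seed = master_seed, flavour = flavour,
                               rmst_variant = rmst_variant,
                               min_size = min_size, max_size = max_size,
                               max_containment = max_containment,
                               outlier_factor = outlier_factor)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("Grid search: %d points; optimum gamma = %.4g, t = %.4g, score = %d practices in %d communities\n",
              nrow(x$table), b$gamma, b$t, b$score, length(b$filtered$valid)))
  invisible(x)
}

#' Log-spaced Markov-time grid
#'
#' @param n number of Markov times.
#' @param from,to endpoints (defaults 0.01 and 1).
#' @return numeric vector of `n` log-spaced times.
#' @export
markov_grid <- function(n = 400, from = 0.01, to = 1) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Evenly spaced RMST pruning-parameter grid
#'
#' @param n number of pruning parameters.
#' @param from,to endpoints (defaults 2.1 and 6.0).
#' @return numeric vector of `n` evenly spaced parameters.
#' @export
gamma_grid <- function(n = 40, from = 2.1, to = 6.0) {
  seq(from, to, length.out = n)
}

#' Write grid-search records as JSON lines
#'
#' One JSON object per (gamma, t) grid point.
#'
#' @param grid a `grid_result`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_grid_jsonl <- function(grid, path) {
  stopifnot(inherits(grid, "grid_result"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(grid$table))) {
    writeLines(jsonlite::toJSON(as.list(grid$table[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}
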