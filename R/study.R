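#' Replicated forest study for one scenario and one mtry
#'
#' Draws `replicates` independent datasets from the generating model, grows
#' one forest per replicate, and collects permutation importances and
#' split-selection tallies from the same forests. This is the inner engine
#' behind [vim_study()] and [run_study()]; exposing it lets callers reuse
#' one set of forests for both importance and selection-frequency
#' summaries.
#'
#' Conditional importances may be computed on reduced data: when
#' `conditional_n_obs`/`conditional_ntree` are smaller than the main
#' settings, a separate forest on a random subset of rows is grown per
#' replicate for the conditional measure (the within-strata permutation is
#' substantially more expensive than the unconditional one).
#'
#' @param model A [generating_model()].
#' @param n_obs Observations per replicate.
#' @param replicates Number of replicates.
#' @param ntree Trees per forest.
#' @param mtry Candidate predictors per node.
#' @param min_node_size,subsample_fraction Forest settings (see
#'   [grow_forest()]).
#' @param vim_types Subset of `c("unconditional", "conditional")`.
#' @param scheme [conditioning_scheme()] for the conditional measure.
#' @param conditional_n_obs,conditional_ntree Reduced settings for the
#'   conditional measure; default the main settings.
#' @param tally Also tally split-variable selection frequencies over the
#'   main forests? Skipping it saves time when only importances are needed.
#' @param seed Integer seed; per-replicate data, forest and permutation
#'   seeds are drawn from it up front and reported in the result.
#'
#' @return A list: `vims` (tibble `replicate`, `predictor`, `type`,
#'   `importance`, `scaled`, `mtry`, `scenario`), `selection` (a
#'   [tally_selection()] tibble over all replicates' main forests, with
#'   `mtry` and `scenario`; `NULL` when `tally = FALSE`), `seeds`
#'   (per-replicate seed table), `n_redrawn` (count of failed replicates
#'   re-drawn under the next derived seed).
#' @export
run_replicates <- function(model, n_obs, replicates, ntree, mtry,
                           min_node_size = 20, subsample_fraction = 0.632,
                           vim_types = "unconditional",
                           scheme = conditioning_scheme(),
                           conditional_n_obs = n_obs,
                           conditional_ntree = ntree,
                           tally = TRUE,
                           seed = NULL) {
  stopifnot(inherits(model, "generating_model"), replicates >= 1,
            all(vim_types %in% c("unconditional", "conditional")))
  if (!is.null(seed)) set.seed(seed)
  seeds <- tibble::tibble(
    replicate = seq_len(replicates),
    data_seed = sample.int(.Machine$integer.max - 1L, replicates),
    forest_seed = sample.int(.Machine$integer.max - 1L, replicates),
    perm_seed = sample.int(.Machine$integer.max - 1L, replicates)
  )
  vims <- vector("list", replicates)
  first_counts <- all_counts <- rep(0L, model$p)
  n_trees_total <- 0L
  n_redrawn <- 0L

  run_one <- function(data_seed, forest_seed, perm_seed) {
    d <- simulate_dataset(model, n_obs, seed = data_seed)
    f <- grow_forest(d, ntree = ntree, mtry = mtry,
                     min_node_size = min_node_size,
                     subsample_fraction = subsample_fraction,
                     seed = forest_seed)
    out <- list()
    if (tally) out$tally <- tally_selection(f)
    res <- list()
    if ("unconditional" %in% vim_types) {
      res$unconditional <- vim_unconditional(f, perm_seed = perm_seed)
    }
    if ("conditional" %in% vim_types) {
      fc <- f
      if (conditional_n_obs < n_obs || conditional_ntree < ntree) {
        set.seed(perm_seed)
        rows <- sort(sample.int(n_obs, min(conditional_n_obs, n_obs)))
        fc <- grow_forest(d[rows, ], ntree = conditional_ntree, mtry = mtry,
                          min_node_size = min_node_size,
                          subsample_fraction = subsample_fraction,
                          seed = forest_seed + 1L)
      }
      res$conditional <- vim_conditional(fc, scheme,
                                         perm_seed = perm_seed + 1L)
    }
    out$vims <- purrr::map_dfr(res, ~ tibble::as_tibble(.x))
    out
  }

  for (r in seq_len(replicates)) {
    attempt <- 0L
    repeat {
      # a failed replicate is re-drawn under the next derived seed
      shift <- attempt * 1000003L
      one <- tryCatch(
        run_one(seeds$data_seed[r] %% (.Machine$integer.max - shift) + shift,
                seeds$forest_seed[r], seeds$perm_seed[r]),
        error = identity)
      if (!inherits(one, "condition")) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (attempt > 5L) {
        stop("replicate ", r, " failed repeatedly: ",
             conditionMessage(one), call. = FALSE)
      }
      message("replicate ", r, " failed (", conditionMessage(one),
              "); re-drawing with the next derived seed")
    }
    if (tally) {
      first_counts <- first_counts + one$tally$first_split_count
      all_counts <- all_counts + one$tally$all_split_count
      n_trees_total <- n_trees_total + one$tally$n_trees_total[1]
    }
    vims[[r]] <- dplyr::mutate(one$vims, replicate = r)
  }
  vims <- dplyr::bind_rows(vims) |>
    dplyr::mutate(mtry = mtry, scenario = model$scenario) |>
    dplyr::select("replicate", "predictor", "type", "importance", "scaled",
                  "mtry", "scenario")
  class(vims) <- c("vim_study", class(vims))
  selection <- NULL
  if (tally) {
    selection <- tibble::tibble(
      predictor = predictor_names(model$p),
      first_split_count = first_counts,
      all_split_count = all_counts,
      first_split_share = first_counts / max(sum(first_counts), 1L),
      all_split_share = all_counts / max(sum(all_counts), 1L),
      n_trees_total = n_trees_total,
      mtry = mtry, scenario = model$scenario
    )
    class(selection) <- c("selection_freq", class(selection))
  }
  list(vims = vims, selection = selection, seeds = seeds,
       n_redrawn = n_redrawn)
}

#' Replicated permutation-importance study
#'
#' Convenience wrapper over [run_replicates()] returning only the
#' per-replicate importance table.
#'
#' @inheritParams run_replicates
#' @return A `vim_study` tibble: one row per replicate x predictor x
#'   importance type.
#' @examples
#' s <- vim_study(generating_model("H0"), n_obs = 200, replicates = 3,
#'                ntree = 20, mtry = 3, seed = 10)
#' vim_summary(s)
#' @export
vim_study <- function(model, n_obs, replicates, ntree, mtry, ...,
                      seed = NULL) {
  run_replicates(model, n_obs, replicates, ntree, mtry, ...,
                 tally = FALSE, seed = seed)$vims
}

#' Distribution summary of a replicated importance study
#'
#' Per predictor (and importance type / mtry / scenario where present):
#' median and quartiles of the replicate importances — the numbers behind
#' the usual per-predictor boxplot panels.
#'
#' @param study A `vim_study` tibble (or any tibble with `predictor` and
#'   `importance`, optionally `type`, `mtry`, `scenario`).
#' @param value Column to summarise: `"importance"` or `"scaled"`.
#' @return A tibble with `median`, `q1`, `q3`, `n` per group.
#' @export
vim_summary <- function(study, value = "importance") {
  stopifnot(value %in% names(study))
  keys <- intersect(c("scenario", "type", "mtry", "predictor"), names(study))
  study |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      median = median(.data[[value]]),
      q1 = quantile(.data[[value]], 0.25, names = FALSE),
      q3 = quantile(.data[[value]], 0.75, names = FALSE),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Correlated-versus-uncorrelated median importance gap
#'
#' The study's null-calibration statistic: the median importance over all
#' (replicate, predictor) values in the correlated group minus the median
#' over the uncorrelated group.
#'
#' @param study A `vim_study` tibble.
#' @param correlated Character vector naming the correlated predictors.
#' @param value Column to compare (default `"importance"`).
#' @return A tibble with one row per (scenario, type, mtry) group present,
#'   and a `median_gap` column.
#' @export
vim_group_gap <- function(study, correlated = paste0("x", 1:4),
                          value = "importance") {
  keys <- intersect(c("scenario", "type", "mtry"), names(study))
  study |>
    dplyr::mutate(group = ifelse(.data$predictor %in% correlated,
                                 "correlated", "uncorrelated")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "group")))) |>
    dplyr::summarise(median = median(.data[[value]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "median") |>
    dplyr::mutate(median_gap = .data$correlated - .data$uncorrelated)
}

#' @export
autoplot.vim_study <- function(object, ...) {
  lev <- unique(object$predictor)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$predictor, levels = lev),
                               y = .data$importance)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_grid(ggplot2::vars(.data$type),
                        ggplot2::vars(.data$mtry),
                        labeller = ggplot2::label_both, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "permutation importance (OOB MSE increase)")
}
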