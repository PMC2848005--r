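#' Split-variable selection frequencies
#'
#' Counts, over every tree in one or several forests, how often each
#' predictor is chosen at the first (depth-0) split and across all internal
#' nodes. Competition between correlated predictors shows up here: under a
#' signal-bearing block the correlated predictors dominate the first split,
#' while across all splits the uncorrelated signal predictors catch up.
#'
#' @param forests A `cart_forest` or a list of them (sharing predictors).
#' @return A `selection_freq` tibble: `predictor`, `first_split_count`,
#'   `all_split_count`, `first_split_share` (of trees with at least one
#'   split), `all_split_share` (of all internal nodes), `n_trees_total`.
#' @examples
#' d <- simulate_dataset(generating_model("HA"), n = 300, seed = 8)
#' tally_selection(grow_forest(d, ntree = 30, mtry = 3, seed = 9))
#' @export
tally_selection <- function(forests) {
  if (inherits(forests, "cart_forest")) forests <- list(forests)
  stopifnot(length(forests) >= 1,
            all(purrr::map_lgl(forests, inherits, "cart_forest")))
  pred <- forests[[1]]$predictors
  stopifnot(all(purrr::map_lgl(forests, ~ identical(.x$predictors, pred))))
  recs <- purrr::map_dfr(forests, split_records)
  n_trees_total <- sum(purrr::map_int(forests, ~ .x$config$ntree))
  counts <- function(r) {
    tab <- table(factor(r$predictor, levels = pred))
    as.integer(tab)
  }
  first <- counts(dplyr::filter(recs, .data$is_first_split))
  all_s <- counts(recs)
  out <- tibble::tibble(
    predictor = pred,
    first_split_count = first,
    all_split_count = all_s,
    first_split_share = if (sum(first) > 0) first / sum(first) else 0 * first,
    all_split_share = if (sum(all_s) > 0) all_s / sum(all_s) else 0 * all_s,
    n_trees_total = n_trees_total
  )
  class(out) <- c("selection_freq", class(out))
  out
}

#' @export
autoplot.selection_freq <- function(object, ...) {
  long <- object |>
    dplyr::select("predictor", `first split` = "first_split_share",
                  `all splits` = "all_split_share") |>
    tidyr::pivot_longer(-"predictor", names_to = "which",
                        values_to = "share") |>
    dplyr::mutate(predictor = factor(.data$predictor,
                                     levels = object$predictor))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predictor, y = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~which) +
    ggplot2::labs(x = NULL, y = "selection share")
}
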