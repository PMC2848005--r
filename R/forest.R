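#' Grow an instrumented CART-style regression forest
#'
#' Fits an ensemble of variance-reduction regression trees with per-node
#' random candidate-feature draws (`mtry`), each tree trained on a
#' subsample drawn *without replacement* (default 63.2% of the rows, so the
#' out-of-bag complement is exactly 36.8%). Unlike off-the-shelf forests,
#' every split record (feature, threshold, depth) and every tree's
#' in-bag/out-of-bag index sets are retained, which is what the permutation
#' importance and selection-frequency machinery reads.
#'
#' A node is never split when it holds fewer than `min_node_size` in-bag
#' rows or when no candidate split strictly reduces the pooled sum of
#' squared deviations; children may be smaller than `min_node_size`.
#' Candidate thresholds are midpoints between consecutive distinct in-bag
#' values; criterion ties are broken towards the lowest feature index and
#' then the smallest threshold, so runs are reproducible.
#'
#' @param data Data frame with the response and predictor columns.
#' @param response Name of the response column; all other columns are
#'   predictors.
#' @param ntree Number of trees.
#' @param mtry Number of candidate predictors drawn (uniformly, without
#'   replacement, fresh per node) at each split.
#' @param min_node_size Minimum in-bag size of a splittable node.
#' @param subsample_fraction Fraction of rows subsampled per tree.
#' @param seed Optional integer seed for the growing RNG stream.
#'
#' @return An object of class `cart_forest`: trees (node matrices), in-bag
#'   and OOB index sets, the training data, and the configuration.
#' @examples
#' d <- simulate_dataset(generating_model("HA"), n = 300, seed = 3)
#' f <- grow_forest(d, ntree = 25, mtry = 3, seed = 4)
#' glance(f)
#' @export
grow_forest <- function(data, response = "y", ntree = 500, mtry = 3,
                        min_node_size = 20, subsample_fraction = 0.632,
                        seed = NULL) {
  xy <- dataset_xy(data, response)
  p <- ncol(xy$X)
  n <- nrow(xy$X)
  stopifnot(ntree >= 1, min_node_size >= 1)
  if (mtry < 1 || mtry > p) {
    stop("`mtry` must be between 1 and the number of predictors",
         call. = FALSE)
  }
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("`subsample_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_grow_forest(xy$X, xy$y, as.integer(ntree), as.integer(mtry),
                         as.integer(min_node_size), subsample_fraction)
  structure(
    list(trees = raw$trees, inbag = raw$inbag, oob = raw$oob,
         X = xy$X, y = xy$y, predictors = xy$predictors,
         config = list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                       min_node_size = as.integer(min_node_size),
                       subsample_fraction = subsample_fraction,
                       seed = seed),
         p = p, n = n),
    class = "cart_forest"
  )
}

#' @export
print.cart_forest <- function(x, ...) {
  cat(sprintf(
    "<cart_forest> %d trees, mtry = %d, min node size = %d, n = %d, p = %d\n",
    x$config$ntree, x$config$mtry, x$config$min_node_size, x$n, x$p))
  cat(sprintf("OOB MSE: %.4g\n", oob_mse(x)))
  invisible(x)
}

#' Split records of every tree in a forest
#'
#' One row per internal node: which predictor was split, where, and at what
#' depth. Depth-0 records are the first split of their tree.
#'
#' @param forest A [grow_forest()] fit.
#' @return Tibble with columns `tree`, `node`, `depth`, `feature`,
#'   `predictor`, `threshold`, `is_first_split`.
#' @export
split_records <- function(forest) {
  stopifnot(inherits(forest, "cart_forest"))
  blocks <- lapply(seq_along(forest$trees), function(t) {
    tr <- forest$trees[[t]]
    internal <- which(tr[, "feature"] > 0)
    if (length(internal) == 0) return(NULL)
    cbind(tree = t, node = internal, depth = tr[internal, "depth"],
          feature = tr[internal, "feature"],
          threshold = tr[internal, "threshold"])
  })
  m <- do.call(rbind, blocks)
  if (is.null(m)) {
    return(tibble::tibble(tree = integer(), node = integer(),
                          depth = integer(), feature = integer(),
                          predictor = character(), threshold = double(),
                          is_first_split = logical()))
  }
  tibble::tibble(
    tree = as.integer(m[, "tree"]),
    node = as.integer(m[, "node"]),
    depth = as.integer(m[, "depth"]),
    feature = as.integer(m[, "feature"]),
    predictor = forest$predictors[m[, "feature"]],
    threshold = m[, "threshold"],
    is_first_split = m[, "depth"] == 0
  )
}

#' @describeIn split_records `tidy()` method: alias for the split-record
#'   table.
#' @param x A `cart_forest`.
#' @param ... Unused.
#' @export
tidy.cart_forest <- function(x, ...) split_records(x)

#' @export
glance.cart_forest <- function(x, ...) {
  tibble::tibble(
    ntree = x$config$ntree, mtry = x$config$mtry,
    min_node_size = x$config$min_node_size,
    subsample_fraction = x$config$subsample_fraction,
    nobs = x$n, p = x$p,
    n_internal_nodes = sum(purrr::map_int(
      x$trees, ~ sum(.x[, "feature"] > 0))),
    oob_mse = oob_mse(x)
  )
}

#' @export
predict.cart_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$predictors])
  rows <- seq_len(nrow(X))
  preds <- purrr::map(object$trees, cpp_predict_tree, X = X, rows = rows)
  Reduce(`+`, preds) / length(preds)
}

#' Out-of-bag predictions from an instrumented forest
#'
#' Each tree predicts exactly the rows it did not train on. The
#' forest-level OOB prediction for a row averages over the trees holding
#' that row out of bag.
#'
#' @param forest A [grow_forest()] fit.
#' @param per_tree If `TRUE`, return one row per (tree, OOB row); otherwise
#'   the forest-level aggregate per training row.
#' @return A tibble: `tree`, `row`, `.pred` (per-tree), or `row`, `.pred`,
#'   `n_trees` (aggregate). Rows that are OOB in no tree are dropped from
#'   the aggregate (possible only for tiny `ntree`).
#' @export
predict_oob <- function(forest, per_tree = FALSE) {
  stopifnot(inherits(forest, "cart_forest"))
  tab <- purrr::map_dfr(seq_along(forest$trees), function(t) {
    rows <- forest$oob[[t]]
    tibble::tibble(
      tree = t, row = as.integer(rows),
      .pred = cpp_predict_tree(forest$trees[[t]], forest$X, rows))
  })
  if (per_tree) return(tab)
  dplyr::group_by(tab, .data$row) |>
    dplyr::summarise(.pred = mean(.data$.pred), n_trees = dplyr::n(),
                     .groups = "drop")
}

#' Forest-level out-of-bag mean squared error
#'
#' @param forest A [grow_forest()] fit.
#' @return A scalar MSE of the aggregated OOB predictions.
#' @export
oob_mse <- function(forest) {
  agg <- predict_oob(forest)
  mean((forest$y[agg$row] - agg$.pred)^2)
}
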