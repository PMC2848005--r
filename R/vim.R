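#' Conditioning scheme for the conditional permutation importance
#'
#' A predictor's conditioning set is every other predictor whose absolute
#' sample correlation with it is at least `threshold`. Within-stratum
#' permutation then preserves the conditioning structure while breaking the
#' predictor's marginal association with the outcome. Strata are, by
#' default, the cells of the partition a tree's own split points induce on
#' the conditioning predictors (`"tree_splits"`); `"quantile_bins"`
#' cross-classifies global `n_bins`-quantile bins instead.
#'
#' @param threshold Absolute-correlation cutoff in `[0, 1]` defining the
#'   conditioning sets. With a design whose correlations are either 0.9 or
#'   0, any cutoff strictly between them selects the same sets.
#' @param strata_source `"tree_splits"` or `"quantile_bins"`.
#' @param n_bins Number of quantile bins for `"quantile_bins"`.
#' @return A `conditioning_scheme` list.
#' @export
conditioning_scheme <- function(threshold = 0.2,
                                strata_source = c("tree_splits",
                                                  "quantile_bins"),
                                n_bins = 5) {
  strata_source <- match.arg(strata_source)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1, n_bins >= 2)
  structure(list(threshold = threshold, strata_source = strata_source,
                 n_bins = as.integer(n_bins)),
            class = "conditioning_scheme")
}

vim_result <- function(forest, per_tree, type, scheme = NULL) {
  ntree <- nrow(per_tree)
  importance <- colMeans(per_tree)
  if (ntree >= 2) {
    se <- apply(per_tree, 2, sd) / sqrt(ntree)
    scaled <- ifelse(se > 0, importance / se, ifelse(importance == 0, 0, Inf))
  } else {
    warning("scaled importance is undefined for a single tree",
            call. = FALSE)
    scaled <- rep(NA_real_, ncol(per_tree))
  }
  out <- tibble::tibble(predictor = forest$predictors,
                        importance = unname(importance),
                        scaled = unname(scaled), type = type)
  attr(out, "per_tree") <- per_tree
  attr(out, "scheme") <- scheme
  class(out) <- c("vim_result", class(out))
  out
}

#' Unconditional permutation variable importance
#'
#' For each tree and each predictor the tree actually uses: compute the
#' tree's out-of-bag MSE, permute that predictor's values uniformly among
#' the tree's OOB rows, recompute the OOB MSE, and record the difference
#' (permuted minus original; positive means important). The unconditional
#' importance averages these differences over trees; the scaled importance
#' divides by the Monte-Carlo standard error over trees,
#' `sd(differences) / sqrt(ntree)`, and therefore grows with forest size.
#' Predictors never split on by a tree contribute an exact 0 for that tree.
#'
#' @param forest A [grow_forest()] fit.
#' @param perm_seed Optional seed for the permutation stream (independent
#'   of the forest-growing stream).
#' @param nperm Permutations averaged per tree-predictor pair (default 1,
#'   matching common practice).
#' @return A `vim_result` tibble (`predictor`, `importance`, `scaled`,
#'   `type`) carrying the `ntree x p` matrix of raw per-tree differences in
#'   `attr(, "per_tree")`.
#' @examples
#' d <- simulate_dataset(generating_model("HA"), n = 300, seed = 5)
#' f <- grow_forest(d, ntree = 40, mtry = 3, seed = 6)
#' vim_unconditional(f, perm_seed = 7)
#' @export
vim_unconditional <- function(forest, perm_seed = NULL, nperm = 1) {
  stopifnot(inherits(forest, "cart_forest"), nperm >= 1)
  if (!is.null(perm_seed)) set.seed(perm_seed)
  empty <- lapply(seq_len(forest$p), function(i) integer(0))
  per_tree <- cpp_vim(forest$trees, forest$oob, forest$X, forest$y,
                      empty, 0L, NULL, as.integer(nperm))
  colnames(per_tree) <- forest$predictors
  vim_result(forest, per_tree, "unconditional")
}

#' Conditional permutation variable importance
#'
#' As [vim_unconditional()], but each predictor is permuted only within
#' strata defined by the predictors correlated with it (its conditioning
#' set under the scheme's threshold), so the permutation preserves the
#' joint distribution with the correlated companions and measures the
#' predictor's contribution beyond them. Predictors with empty
#' conditioning sets reduce exactly to the unconditional computation (and
#' consume the identical permutation stream).
#'
#' @inheritParams vim_unconditional
#' @param scheme A [conditioning_scheme()].
#' @return A `vim_result` tibble with `type = "conditional"`.
#' @export
vim_conditional <- function(forest, scheme = conditioning_scheme(),
                            perm_seed = NULL, nperm = 1) {
  stopifnot(inherits(forest, "cart_forest"),
            inherits(scheme, "conditioning_scheme"), nperm >= 1)
  if (!is.null(perm_seed)) set.seed(perm_seed)
  R <- cor(forest$X)
  cond_sets <- lapply(seq_len(forest$p), function(i) {
    j <- which(abs(R[i, ]) >= scheme$threshold)
    as.integer(setdiff(j, i))
  })
  qbins <- NULL
  mode <- 0L
  if (scheme$strata_source == "quantile_bins") {
    mode <- 1L
    qbins <- apply(forest$X, 2, function(x) {
      br <- unique(quantile(x, probs = seq(0, 1, length.out =
                                             scheme$n_bins + 1)))
      as.integer(cut(x, breaks = br, include.lowest = TRUE))
    })
    storage.mode(qbins) <- "integer"
  }
  per_tree <- cpp_vim(forest$trees, forest$oob, forest$X, forest$y,
                      cond_sets, mode, qbins, as.integer(nperm))
  colnames(per_tree) <- forest$predictors
  vim_result(forest, per_tree, "conditional", scheme)
}

#' @export
autoplot.vim_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$predictor,
                                          levels = .data$predictor),
                               y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "permutation importance (OOB MSE increase)",
                  title = paste(object$type[1], "permutation importance"))
}
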