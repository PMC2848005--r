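#' Population standard deviation of the response
#'
#' For the linear generating model `y = X b + eps` with predictor
#' correlation matrix `V` (unit variances) this is
#' `sigma_y = sqrt(b' V b + sigma_eps^2)`.
#'
#' @param model A [generating_model()].
#' @return A positive scalar.
#' @examples
#' response_sd(generating_model("H0")) # just the noise SD
#' @export
response_sd <- function(model) {
  stopifnot(inherits(model, "generating_model"))
  b <- model$coefficients
  sqrt(drop(t(b) %*% model$correlation %*% b) + model$sigma_eps^2)
}

#' True single-predictor (bivariate) regression slopes
#'
#' The population slope of `y` regressed on each predictor alone is
#' `(V b)[i] / V[i, i]`; with unit predictor variances this is simply
#' `(V b)[i]`. Correlated proxies of influential predictors therefore pick
#' up large bivariate slopes even when their own generating coefficient is
#' zero — the spurious-correlation mechanism the study quantifies.
#'
#' @param model A [generating_model()].
#' @return Numeric vector of length `p`.
#' @examples
#' true_bivariate_beta(generating_model("HA"))[4] # proxy slope of x4
#' @export
true_bivariate_beta <- function(model) {
  stopifnot(inherits(model, "generating_model"))
  drop(model$correlation %*% model$coefficients) / diag(model$correlation)
}

#' True marginal predictor-outcome correlations
#'
#' `cor(x_i, y) = (V b)[i] / sigma_y` with
#' `sigma_y = sqrt(b' V b + sigma_eps^2)`.
#'
#' @param model A [generating_model()].
#' @return Numeric vector of length `p`, each entry in `[-1, 1]`.
#' @examples
#' round(true_marginal_correlation(generating_model("HA")), 2)
#' @export
true_marginal_correlation <- function(model) {
  stopifnot(inherits(model, "generating_model"))
  drop(model$correlation %*% model$coefficients) / response_sd(model)
}

#' Closed-form truth table for a generating model
#'
#' One row per predictor: generating coefficient, correlated-block
#' membership, the true bivariate slope, and the true marginal correlation
#' with the outcome.
#'
#' @param model A [generating_model()].
#' @return A tibble with columns `predictor`, `coefficient`, `correlated`,
#'   `bivariate_beta`, `marginal_r`.
#' @examples
#' truth_table(generating_model("HA"))
#' @export
truth_table <- function(model) {
  dplyr::mutate(tidy(model),
                bivariate_beta = true_bivariate_beta(model),
                marginal_r = true_marginal_correlation(model))
}
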