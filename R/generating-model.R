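#' Block-equicorrelated predictor correlation matrix
#'
#' Builds a `p x p` correlation matrix whose leading `block_size` predictors
#' are equi-correlated at `rho` and whose remaining predictors are mutually
#' uncorrelated. This is the design used throughout the package: a tight
#' block of proxies (think markers in strong linkage disequilibrium)
#' embedded among independent noise predictors.
#'
#' @param p Number of predictors.
#' @param block_size Number of predictors in the correlated leading block.
#' @param rho Common within-block correlation, in `[0, 1)`.
#'
#' @return A `p x p` numeric correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite: its eigenvalues are `1 + (block_size - 1) * rho`,
#'   `1 - rho` repeated, and 1).
#' @examples
#' block_correlation_matrix(5, 3, 0.5)
#' @export
block_correlation_matrix <- function(p, block_size, rho) {
  stopifnot(is.numeric(p), length(p) == 1, p >= 1,
            is.numeric(block_size), length(block_size) == 1, block_size >= 1)
  if (block_size > p) {
    stop("`block_size` must be at most `p`", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1) {
    stop("`rho` must be a single value in [0, 1)", call. = FALSE)
  }
  V <- diag(p)
  if (block_size > 1) {
    V[seq_len(block_size), seq_len(block_size)] <- rho
    diag(V) <- 1
  }
  V
}

#' Linear generating model with a correlated predictor block
#'
#' The data-generating process for the whole simulation study:
#' standard-normal predictors `x1..xp` with the leading `block_size`
#' predictors equi-correlated at `rho`, and an intercept-free linear
#' response `y = X b + eps`, `eps ~ N(0, sigma_eps^2)`.
#'
#' Under the default 12-predictor design the alternative-hypothesis
#' coefficients are `(5, 5, 2, 0, -5, -5, -2, 0, 0, 0, 0, 0)`: three of the
#' four correlated predictors and three uncorrelated predictors carry
#' signal, while `x4` is a pure proxy (zero coefficient, correlated 0.9
#' with `x1..x3`). The null scenario keeps the correlation structure and
#' sets every coefficient to zero.
#'
#' @param scenario `"HA"` (alternative) or `"H0"` (global null).
#' @param p Number of predictors.
#' @param block_size Size of the leading correlated block.
#' @param rho Within-block correlation.
#' @param coefficients Optional coefficient vector of length `p`; defaults
#'   to the canonical 12-predictor coefficients under `"HA"` (only available
#'   for `p = 12`) and to zeros under `"H0"`.
#' @param sigma_eps Standard deviation of the additive Gaussian noise.
#'
#' @return An object of class `generating_model`: a list with elements
#'   `coefficients`, `correlation`, `sigma_eps`, `scenario`, `p`.
#' @examples
#' m <- generating_model("HA")
#' m$coefficients
#' tidy(m)
#' @export
generating_model <- function(scenario = c("HA", "H0"), p = 12, block_size = 4,
                             rho = 0.9, coefficients = NULL,
                             sigma_eps = 0.5) {
  scenario <- match.arg(scenario)
  V <- block_correlation_matrix(p, block_size, rho)
  if (scenario == "H0") {
    coefficients <- rep(0, p)
  } else if (is.null(coefficients)) {
    if (p != 12) {
      stop("default HA coefficients are defined for p = 12; ",
           "supply `coefficients` for other p", call. = FALSE)
    }
    coefficients <- c(5, 5, 2, 0, -5, -5, -2, rep(0, 5))
  }
  stopifnot(length(coefficients) == p, is.numeric(coefficients))
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1 || sigma_eps <= 0) {
    stop("`sigma_eps` must be a single positive number", call. = FALSE)
  }
  structure(
    list(coefficients = as.numeric(coefficients), correlation = V,
         sigma_eps = sigma_eps, scenario = scenario, p = as.integer(p),
         block_size = as.integer(block_size), rho = rho),
    class = "generating_model"
  )
}

#' @export
print.generating_model <- function(x, ...) {
  cat("<generating_model> scenario", x$scenario,
      sprintf("| p = %d, block of %d at rho = %g, sigma_eps = %g\n",
              x$p, x$block_size, x$rho, x$sigma_eps))
  cat("coefficients:", paste(x$coefficients, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn generating_model One row per predictor: coefficient and
#'   whether it belongs to the correlated block.
#' @param x A `generating_model`.
#' @param ... Unused.
#' @export
tidy.generating_model <- function(x, ...) {
  tibble::tibble(
    predictor = predictor_names(x$p),
    coefficient = x$coefficients,
    correlated = seq_len(x$p) <= x$block_size & x$block_size > 1
  )
}

predictor_names <- function(p) paste0("x", seq_len(p))

#' Draw one replicate from a generating model
#'
#' Simulates `n` i.i.d. rows of the multivariate-normal design (unit
#' variances, correlation matrix from the model) and the intercept-free
#' response `y = X b + eps`. Identical `(model, n, seed)` give
#' bit-identical output.
#'
#' @param model A [generating_model()].
#' @param n Number of observations.
#' @param seed Optional integer seed (`set.seed()` is called when supplied).
#'
#' @return A tibble with columns `x1..xp` and `y`, carrying the attributes
#'   `seed` and `scenario`.
#' @examples
#' d <- simulate_dataset(generating_model("HA"), n = 200, seed = 1)
#' round(cor(d$x1, d$x2), 1)
#' @export
simulate_dataset <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "generating_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ev <- eigen(model$correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("model correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  X <- MASS::mvrnorm(n, mu = rep(0, model$p), Sigma = model$correlation)
  if (n == 1) X <- matrix(X, nrow = 1)
  y <- drop(X %*% model$coefficients) + rnorm(n, 0, model$sigma_eps)
  out <- tibble::as_tibble(as.data.frame(X, col.names = predictor_names(model$p)))
  names(out) <- predictor_names(model$p)
  out$y <- y
  attr(out, "seed") <- seed
  attr(out, "scenario") <- model$scenario
  out
}

# numeric design matrix + response from a simulated tibble
dataset_xy <- function(data, response = "y") {
  stopifnot(response %in% names(data))
  pred <- setdiff(names(data), response)
  list(X = as.matrix(data[pred]), y = data[[response]], predictors = pred)
}
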