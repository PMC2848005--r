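#' Configuration for a full simulation study
#'
#' Bundles every knob of the study grid: scenarios (alternative and/or
#' null), the mtry grid, forest and OLS settings, and the master seed. The
#' `"paper"` scale runs the full-scale study design (2,000 observations, 500
#' replicates, 5,000 trees; conditional importance on 500 observations and
#' 500 trees); the `"desk"` scale (default) keeps `n_obs = 2000` but drops
#' to 50 replicates and 250 trees so the ordinal findings are decidable in
#' minutes on one core.
#'
#' @param scale `"desk"` or `"paper"`; sets defaults for the size knobs.
#' @param n_obs,n_replicates,ntree Main study sizes (override the scale
#'   preset).
#' @param conditional_n_obs,conditional_ntree Reduced sizes for the
#'   conditional importance.
#' @param mtry_grid Integer vector of mtry values.
#' @param scenarios Subset of `c("HA", "H0")`.
#' @param vim_types Subset of `c("unconditional", "conditional")`.
#' @param master_seed Integer master seed; all per-replicate seeds derive
#'   from it.
#' @param output_dir Directory for the CSV outputs and manifest.
#' @return A `study_config` list.
#' @export
study_config <- function(scale = c("desk", "paper"),
                         n_obs = NULL, n_replicates = NULL, ntree = NULL,
                         conditional_n_obs = 500, conditional_ntree = NULL,
                         mtry_grid = c(1, 3, 8),
                         scenarios = c("HA", "H0"),
                         vim_types = c("unconditional", "conditional"),
                         master_seed = 20100227,
                         output_dir = "corrvim-study") {
  scale <- match.arg(scale)
  preset <- if (scale == "paper") {
    list(n_obs = 2000, n_replicates = 500, ntree = 5000,
         conditional_ntree = 500)
  } else {
    list(n_obs = 2000, n_replicates = 50, ntree = 250,
         conditional_ntree = 250)
  }
  cfg <- list(
    scale = scale,
    n_obs = n_obs %||% preset$n_obs,
    n_replicates = n_replicates %||% preset$n_replicates,
    ntree = ntree %||% preset$ntree,
    conditional_n_obs = conditional_n_obs,
    conditional_ntree = conditional_ntree %||% preset$conditional_ntree,
    mtry_grid = as.integer(mtry_grid),
    scenarios = match.arg(scenarios, c("HA", "H0"), several.ok = TRUE),
    vim_types = match.arg(vim_types, c("unconditional", "conditional"),
                          several.ok = TRUE),
    master_seed = as.integer(master_seed),
    output_dir = output_dir
  )
  if (cfg$n_obs < 200) {
    stop("`n_obs` below 200 leaves too few out-of-bag rows per tree",
         call. = FALSE)
  }
  structure(cfg, class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulation study and write its report bundle
#'
#' Orchestrates the whole grid — scenarios x mtry x importance types — and
#' writes, under `config$output_dir`:
#' \itemize{
#'   \item `truth.csv`: the closed-form truth table (bivariate slopes and
#'     marginal correlations) per scenario;
#'   \item `bias_coverage.csv`: full-model and single-predictor OLS bias
#'     and 95% coverage, both with and without an intercept, per scenario;
#'   \item `vim_replicates.csv` and `vim_summary.csv`: per-replicate
#'     importances and their median/quartile summaries;
#'   \item `selection_frequencies.csv`: first-split and all-split tallies;
#'   \item `manifest.json`: the full configuration and every derived seed,
#'     sufficient to reproduce any single replicate.
#' }
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with all of the above as tibbles plus the
#'   manifest.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$master_seed)
  arm_seed_pool <- sample.int(.Machine$integer.max - 1L,
                              2L * length(config$scenarios) *
                                (1L + length(config$mtry_grid)))
  next_seed <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      arm_seed_pool[i]
    }
  })

  truth <- purrr::map_dfr(config$scenarios, function(sc) {
    dplyr::mutate(truth_table(generating_model(sc)), scenario = sc)
  })

  bias_cov <- purrr::map_dfr(config$scenarios, function(sc) {
    m <- generating_model(sc)
    s <- next_seed()
    purrr::map_dfr(c(TRUE, FALSE), function(ic) {
      dplyr::mutate(
        bias_coverage_table(m, n = config$n_obs,
                            replicates = config$n_replicates,
                            intercept = ic, seed = s),
        scenario = sc)
    })
  })

  vims <- list()
  sel <- list()
  seeds <- list()
  redrawn <- list()
  for (sc in config$scenarios) {
    m <- generating_model(sc)
    for (mt in config$mtry_grid) {
      arm <- run_replicates(
        m, n_obs = config$n_obs, replicates = config$n_replicates,
        ntree = config$ntree, mtry = mt, vim_types = config$vim_types,
        conditional_n_obs = config$conditional_n_obs,
        conditional_ntree = config$conditional_ntree,
        seed = next_seed())
      key <- paste(sc, mt, sep = "_mtry")
      vims[[key]] <- arm$vims
      sel[[key]] <- arm$selection
      seeds[[key]] <- dplyr::mutate(arm$seeds, scenario = sc, mtry = mt)
      redrawn[[key]] <- arm$n_redrawn
    }
  }
  vims <- dplyr::bind_rows(vims)
  sel <- dplyr::bind_rows(sel)
  summary <- vim_summary(vims)

  manifest <- list(
    package_version = as.character(utils::packageVersion("corrvim")),
    config = unclass(config),
    replicate_seeds = dplyr::bind_rows(seeds),
    replicates_redrawn = redrawn,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )

  paths <- file.path(config$output_dir,
                     c("truth.csv", "bias_coverage.csv",
                       "vim_replicates.csv", "vim_summary.csv",
                       "selection_frequencies.csv", "manifest.json"))
  utils::write.csv(truth, paths[1], row.names = FALSE)
  utils::write.csv(bias_cov, paths[2], row.names = FALSE)
  utils::write.csv(vims, paths[3], row.names = FALSE)
  utils::write.csv(summary, paths[4], row.names = FALSE)
  utils::write.csv(sel, paths[5], row.names = FALSE)
  jsonlite::write_json(manifest, paths[6], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  invisible(list(truth = truth, bias_coverage = bias_cov,
                 vim_replicates = vims, vim_summary = summary,
                 selection = sel, manifest = manifest))
}
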