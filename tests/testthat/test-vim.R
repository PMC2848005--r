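vim_fixture <- function(n = 200, scenario = "HA", ntree = 30, mtry = 3,
                        seed = 91, min_node_size = 20) {
  d <- simulate_dataset(generating_model(scenario), n, seed = seed)
  grow_forest(d, ntree = ntree, mtry = mtry, min_node_size = min_node_size,
              seed = seed + 1)
}

test_that("stored importances equal the per-tree difference means", {
  f <- vim_fixture()
  v <- vim_unconditional(f, perm_seed = 1)
  pt <- attr(v, "per_tree")
  expect_equal(dim(pt), c(30, 12))
  expect_equal(v$importance, unname(colMeans(pt)))
  expect_equal(v$scaled,
               unname(colMeans(pt) / (apply(pt, 2, sd) / sqrt(30))))
})

test_that("a predictor no tree uses has per-tree differences exactly 0", {
  d <- simulate_dataset(generating_model("HA"), 150, seed = 101)
  d$x13 <- 1 # constant column: no split can use it
  f <- grow_forest(d, ntree = 20, mtry = 13, min_node_size = 20, seed = 102)
  expect_false(any(split_records(f)$feature == 13))
  v <- vim_unconditional(f, perm_seed = 103)
  expect_identical(unname(attr(v, "per_tree")[, 13]), rep(0, 20))
})

test_that("pure-noise predictors centre on zero importance under H0", {
  f <- vim_fixture(n = 400, scenario = "H0", ntree = 60, seed = 111)
  v <- vim_unconditional(f, perm_seed = 112)
  pt <- attr(v, "per_tree")
  se <- apply(pt, 2, sd) / sqrt(nrow(pt))
  # uncorrelated noise predictors: mean difference within 3 MC SEs of 0
  expect_true(all(abs(v$importance[5:12]) < pmax(3 * se[5:12], 1e-8)))
})

test_that("a single tree's mean importance matches full enumeration", {
  # 1 tree, 3 OOB rows: average the two-MSE subtraction over all 3! = 6
  # permutations by hand and compare with the Monte-Carlo mean over seeds
  set.seed(121)
  d <- tibble::tibble(x1 = rnorm(8), x2 = rnorm(8))
  d$y <- 3 * d$x1 + rnorm(8, 0, 0.2)
  f <- grow_forest(d, ntree = 1, mtry = 2, min_node_size = 3, seed = 122)
  oob <- f$oob[[1]]
  expect_equal(length(oob), 8 - round(0.632 * 8))
  X <- as.matrix(d[c("x1", "x2")])
  tr <- f$trees[[1]]

  base <- sapply(oob, function(r) predict_tree_oracle(tr, X[r, ]))
  mse0 <- mean((d$y[oob] - base)^2)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  enum_mean <- function(j) {
    vals <- X[oob, j]
    mean(apply(perms, 1, function(pm) {
      pred <- sapply(seq_along(oob), function(i) {
        predict_tree_oracle(tr, X[oob[i], ], sub_feature = j,
                            sub_value = vals[pm[i]])
      })
      mean((d$y[oob] - pred)^2) - mse0
    }))
  }
  used <- sort(unique(split_records(f)$feature))
  mc <- replicate(600, {
    suppressWarnings(vim_unconditional(f)$importance)
  })
  for (j in used) {
    expect_equal(mean(mc[j, ]), enum_mean(j),
                 tolerance = 4 * sd(mc[j, ]) / sqrt(600) + 1e-10)
  }
})

test_that("empty conditioning sets reproduce the unconditional stream", {
  # independent predictors: threshold above every sample correlation makes
  # every conditioning set empty, so the permutation stream is shared
  set.seed(131)
  d <- tibble::tibble(x1 = rnorm(150), x2 = rnorm(150), x3 = rnorm(150))
  d$y <- 2 * d$x1 - d$x2 + rnorm(150, 0, 0.5)
  f <- grow_forest(d, ntree = 15, mtry = 2, min_node_size = 15, seed = 132)
  vu <- vim_unconditional(f, perm_seed = 133)
  vc <- vim_conditional(f, conditioning_scheme(threshold = 0.99),
                        perm_seed = 133)
  expect_identical(attr(vu, "per_tree"), attr(vc, "per_tree"))
  expect_equal(vu$importance, vc$importance)
})

test_that("within-stratum permutation cannot break a deterministic proxy", {
  # x2 drives y; x3 is an exact copy. Conditioning x2's permutation on
  # quantile bins of x3 makes every stratum constant in x2, so the
  # conditional importance collapses to 0 while the unconditional is large.
  set.seed(141)
  x2 <- rep(c(0, 1), each = 40)
  d <- tibble::tibble(x1 = rnorm(80), x2 = x2, x3 = x2)
  d$y <- 5 * d$x2 + rnorm(80, 0, 0.3)
  f <- grow_forest(d, ntree = 10, mtry = 3, min_node_size = 10, seed = 142)
  vu <- vim_unconditional(f, perm_seed = 143)
  vc <- vim_conditional(
    f, conditioning_scheme(threshold = 0.5, strata_source = "quantile_bins",
                           n_bins = 4),
    perm_seed = 143)
  i2 <- which(vc$predictor == "x2")
  expect_gt(vu$importance[i2], 1)
  expect_equal(vc$importance[i2], 0)
})

test_that("tree-split strata confine permutation to the threshold sides", {
  # x1 is binary with a continuous 0.9-correlated companion x2. The trees
  # split densely on x2, so x1's conditional permutation is confined to
  # the cells x2's split points induce — cells that are almost pure in
  # sign(x1). Shuffling x1 inside them can barely move it across any x2
  # threshold, so the conditional importance of x1 must collapse relative
  # to the unconditional one, which freely swaps the two x1 levels.
  set.seed(151)
  x1 <- sample(c(-1, 1), 200, replace = TRUE)
  d <- tibble::tibble(x1 = x1,
                      x2 = 0.9 * x1 + sqrt(1 - 0.81) * rnorm(200))
  d$y <- 4 * d$x1 + 2 * d$x2 + rnorm(200, 0, 0.3)
  f <- grow_forest(d, ntree = 20, mtry = 2, min_node_size = 20, seed = 152)
  recs <- split_records(f)
  # any recorded x1 threshold is the midpoint of {-1, 1}
  expect_true(all(recs$threshold[recs$feature == 1] == 0))
  expect_gt(sum(recs$feature == 2), 0) # conditioning splits exist
  vu <- vim_unconditional(f, perm_seed = 153)
  vc <- vim_conditional(f, conditioning_scheme(threshold = 0.5),
                        perm_seed = 153)
  i1 <- which(vc$predictor == "x1")
  expect_gt(vu$importance[i1], 10)
  expect_lt(vc$importance[i1], 0.25 * vu$importance[i1])
})

test_that("scaled importance grows with forest size, raw importance not", {
  d <- simulate_dataset(generating_model("HA"), 400, seed = 161)
  f1 <- grow_forest(d, ntree = 100, mtry = 3, seed = 162)
  f4 <- grow_forest(d, ntree = 400, mtry = 3, seed = 163)
  v1 <- vim_unconditional(f1, perm_seed = 164)
  v4 <- vim_unconditional(f4, perm_seed = 165)
  i1 <- which(v1$predictor == "x1")
  # quadrupling ntree should roughly double the scaled value of a strong
  # predictor while the raw importance stays put
  expect_gt(v4$scaled[i1] / v1$scaled[i1], 1.4)
  expect_lt(v4$scaled[i1] / v1$scaled[i1], 2.8)
  expect_equal(v4$importance[i1], v1$importance[i1], tolerance = 0.35)
})

test_that("single-tree forests return importance but no scaled value", {
  f <- vim_fixture(ntree = 1, n = 100, min_node_size = 10)
  expect_warning(v <- vim_unconditional(f, perm_seed = 171), "single tree")
  expect_true(all(is.na(v$scaled)))
  expect_true(is.numeric(v$importance))
})

test_that("study summaries report medians, quartiles and the group gap", {
  s <- vim_study(generating_model("H0"), n_obs = 150, replicates = 3,
                 ntree = 10, mtry = 2, min_node_size = 20, seed = 181)
  expect_equal(nrow(s), 3 * 12)
  sm <- vim_summary(s)
  expect_equal(nrow(sm), 12)
  expect_true(all(sm$q1 <= sm$median & sm$median <= sm$q3))

  # identical replicates collapse the IQR to zero
  one <- dplyr::filter(s, .data$replicate == 1)
  tri <- dplyr::bind_rows(one, one, one)
  sm0 <- vim_summary(tri)
  expect_equal(sm0$q1, sm0$q3)

  gap <- vim_group_gap(s)
  expect_equal(
    gap$median_gap,
    median(s$importance[s$predictor %in% paste0("x", 1:4)]) -
      median(s$importance[!s$predictor %in% paste0("x", 1:4)]))
})
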