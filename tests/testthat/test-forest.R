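small_dataset <- function(n = 60, seed = 21) {
  simulate_dataset(generating_model("HA"), n, seed = seed)
}

test_that("a constant response yields single-leaf trees", {
  d <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30), y = 2)
  f <- grow_forest(d, ntree = 5, mtry = 2, min_node_size = 5, seed = 1)
  expect_true(all(purrr::map_int(f$trees, nrow) == 1))
  expect_equal(nrow(split_records(f)), 0)
  expect_equal(unname(predict(f, d)), rep(2, 30))
})

test_that("the enumerable 1-D step function splits between 2 and 3", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4), y = c(0, 0, 10, 10))
  f <- grow_forest(d, ntree = 1, mtry = 1, min_node_size = 2,
                   subsample_fraction = 1, seed = 2)
  rec <- split_records(f)
  expect_equal(rec$feature[rec$depth == 0], 1)
  first_thr <- rec$threshold[rec$depth == 0]
  expect_gt(first_thr, 2)
  expect_lt(first_thr, 3)
  expect_equal(unname(predict(f, d)), c(0, 0, 10, 10))
})

test_that("in-bag and OOB sets partition the rows at 63.2%", {
  d <- small_dataset(n = 2000 %/% 10) # n = 200 keeps the test quick
  f <- grow_forest(d, ntree = 10, mtry = 3, seed = 3)
  for (t in 1:10) {
    ib <- f$inbag[[t]]; ob <- f$oob[[t]]
    expect_equal(length(ib), round(0.632 * 200))
    expect_equal(length(intersect(ib, ob)), 0)
    expect_equal(sort(c(ib, ob)), 1:200)
  }
})

test_that("growth is deterministic under a fixed seed", {
  d <- small_dataset()
  f1 <- grow_forest(d, ntree = 8, mtry = 3, min_node_size = 10, seed = 11)
  f2 <- grow_forest(d, ntree = 8, mtry = 3, min_node_size = 10, seed = 11)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$inbag, f2$inbag)
  f3 <- grow_forest(d, ntree = 8, mtry = 3, min_node_size = 10, seed = 12)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("with mtry = p a single tree equals the greedy CART oracle", {
  for (seed in c(31, 32, 33)) {
    d <- small_dataset(n = 40, seed = seed)
    f <- grow_forest(d, ntree = 1, mtry = 12, min_node_size = 8,
                     subsample_fraction = 1, seed = seed)
    X <- as.matrix(d[paste0("x", 1:12)])
    oracle <- cart_oracle(X, d$y, 1:40, min_node_size = 8)
    got <- split_records(f)[, c("depth", "feature", "threshold")]
    want <- oracle_splits(oracle)
    # same multiset of (depth, feature, threshold) records
    expect_equal(nrow(got), nrow(want))
    ord <- function(z) z[order(z$depth, z$feature, z$threshold), ]
    expect_equal(ord(as.data.frame(got))$feature, ord(want)$feature)
    expect_equal(ord(as.data.frame(got))$threshold, ord(want)$threshold,
                 tolerance = 1e-12)
  }
})

test_that("every recorded split strictly reduces the node SSE", {
  d <- small_dataset(n = 120, seed = 41)
  f <- grow_forest(d, ntree = 6, mtry = 3, min_node_size = 15, seed = 42)
  X <- as.matrix(d[paste0("x", 1:12)])
  for (t in 1:6) {
    red <- node_sse_reductions(f$trees[[t]], X, d$y, f$inbag[[t]])
    expect_true(all(red > 0))
  }
})

test_that("no node smaller than min_node_size is split", {
  d <- small_dataset(n = 150, seed = 51)
  f <- grow_forest(d, ntree = 10, mtry = 3, min_node_size = 20, seed = 52)
  for (t in 1:10) {
    tr <- f$trees[[t]]
    internal <- tr[, "feature"] > 0
    expect_true(all(tr[internal, "n_node"] >= 20))
    expect_true(all(tr[!internal, "n_node"] >= 1))
  }
})

test_that("per-tree OOB predictions match an R tree-walk oracle", {
  d <- small_dataset(n = 12, seed = 61)
  f <- grow_forest(d, ntree = 3, mtry = 4, min_node_size = 3, seed = 62)
  X <- as.matrix(d[paste0("x", 1:12)])
  tab <- predict_oob(f, per_tree = TRUE)
  expect_equal(nrow(tab), sum(lengths(f$oob)))
  for (i in seq_len(nrow(tab))) {
    tr <- f$trees[[tab$tree[i]]]
    expect_equal(tab$.pred[i], predict_tree_oracle(tr, X[tab$row[i], ]))
  }
  # single-tree OOB table covers exactly the OOB complement
  f1 <- grow_forest(d, ntree = 1, mtry = 3, seed = 63)
  expect_equal(predict_oob(f1, per_tree = TRUE)$row, f1$oob[[1]])
  expect_equal(length(f1$oob[[1]]), 12 - round(0.632 * 12))
})

test_that("a forest drives OOB error far below the response variance", {
  # strong one-predictor signal, tiny noise
  set.seed(71)
  d <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300))
  d$y <- 10 * d$x1 + rnorm(300, 0, 0.1)
  f <- grow_forest(d, ntree = 60, mtry = 2, min_node_size = 10, seed = 72)
  expect_lt(oob_mse(f), var(d$y) / 4)
})

test_that("invalid configurations are rejected", {
  d <- small_dataset(n = 30)
  expect_error(grow_forest(d, mtry = 13), "mtry")
  expect_error(grow_forest(d, subsample_fraction = 0), "subsample_fraction")
  expect_error(grow_forest(d[1, ]), "observations")
})
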