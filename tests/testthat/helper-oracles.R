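# Independent reference implementations used only by the tests.

# OLS via the normal equations, with t-based confidence intervals.
ols_oracle <- function(X, y, intercept = TRUE, conf_level = 0.95) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tq <- qt(1 - (1 - conf_level) / 2, df)
  list(estimate = drop(beta), se = se,
       lower = drop(beta) - tq * se, upper = drop(beta) + tq * se)
}

# Exhaustive greedy CART regression tree (all features considered at every
# node, i.e. the mtry = p case). Returns a nested list; used to check the
# C++ grower on small instances.
cart_oracle <- function(X, y, rows, min_node_size, depth = 0) {
  m <- length(rows)
  mean_y <- mean(y[rows])
  sse <- sum((y[rows] - mean_y)^2)
  node <- list(value = mean_y, n = m, depth = depth, feature = NA,
               threshold = NA, left = NULL, right = NULL)
  if (m < min_node_size || sse <= 1e-12) return(node)
  best <- list(feature = NA, threshold = NA, reduction = 0)
  for (f in seq_len(ncol(X))) {
    xv <- X[rows, f]
    ux <- sort(unique(xv))
    if (length(ux) < 2) next
    for (i in seq_len(length(ux) - 1)) {
      thr <- (ux[i] + ux[i + 1]) / 2
      l <- rows[xv <= thr]
      r <- rows[xv > thr]
      red <- sse - sum((y[l] - mean(y[l]))^2) - sum((y[r] - mean(y[r]))^2)
      if (red > best$reduction + 1e-12) {
        best <- list(feature = f, threshold = thr, reduction = red)
      }
    }
  }
  if (is.na(best$feature)) return(node)
  node$feature <- best$feature
  node$threshold <- best$threshold
  xv <- X[rows, best$feature]
  node$left <- cart_oracle(X, y, rows[xv <= best$threshold], min_node_size,
                           depth + 1)
  node$right <- cart_oracle(X, y, rows[xv > best$threshold], min_node_size,
                            depth + 1)
  node
}

# Walk a fitted tree's node matrix in plain R (independent of the C++
# prediction path). `sub` optionally substitutes one feature's value.
predict_tree_oracle <- function(tree, x, sub_feature = NA, sub_value = NA) {
  node <- 1
  repeat {
    f <- tree[node, "feature"]
    if (f == 0) return(unname(tree[node, "value"]))
    v <- if (!is.na(sub_feature) && f == sub_feature) sub_value else x[f]
    node <- if (v <= tree[node, "threshold"]) tree[node, "left"]
            else tree[node, "right"]
  }
}

# Flatten the nested oracle tree into (depth, feature, threshold) records
# for comparison with split_records().
oracle_splits <- function(node) {
  if (is.na(node$feature)) return(NULL)
  rbind(
    data.frame(depth = node$depth, feature = node$feature,
               threshold = node$threshold),
    oracle_splits(node$left),
    oracle_splits(node$right)
  )
}

# In-node SSE at every internal node of a fitted tree, recomputed from the
# raw data, to verify recorded splits strictly reduce the criterion.
node_sse_reductions <- function(tree, X, y, inbag) {
  rows_of <- vector("list", nrow(tree))
  rows_of[[1]] <- inbag
  out <- numeric(0)
  for (i in seq_len(nrow(tree))) {
    if (tree[i, "feature"] == 0) next
    rows <- rows_of[[i]]
    f <- tree[i, "feature"]; thr <- tree[i, "threshold"]
    l <- rows[X[rows, f] <= thr]
    r <- rows[X[rows, f] > thr]
    rows_of[[tree[i, "left"]]] <- l
    rows_of[[tree[i, "right"]]] <- r
    sse <- function(ix) sum((y[ix] - mean(y[ix]))^2)
    out <- c(out, sse(rows) - sse(l) - sse(r))
  }
  out
}

default_ha_model <- function() generating_model("HA")
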