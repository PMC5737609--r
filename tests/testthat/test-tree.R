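# Redundancy-sized regression tree: splitting, growing, pruning,
# routing.

toy_design <- function(X, y) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(x = X, y = y,
                 tfbs_columns = colnames(X), condition_columns = character(),
                 construct = rownames(X) %||% as.character(seq_len(nrow(X))),
                 condition = rep("none", nrow(X)),
                 row_id = as.character(seq_len(nrow(X)))),
            class = "design_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("best_split maximizes SSE reduction under the minbucket constraint", {
  set.seed(1)
  n <- 1000
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- as.numeric(X[, "x1"] > 0.5)
  s <- best_split(X, y, minbucket = 50)
  expect_equal(s$column, "x1")
  # threshold adjacent to the true step
  xs <- sort(X[, "x1"])
  gap <- max(diff(xs))
  expect_lt(abs(s$threshold - 0.5), gap + max(diff(sort(X[, 1]))))
  expect_lt(abs(s$threshold - 0.5), 0.02)
  # constant response: nothing to gain
  expect_null(best_split(X, rep(1, n), minbucket = 10))
  # not enough rows for two legal children
  expect_null(best_split(X, y, rows = 1:80, minbucket = 50))
})

test_that("best_split equals the exhaustive enumeration oracle", {
  for (k in 1:12) {
    set.seed(400 + k)
    n <- sample(30:200, 1)
    p <- sample(2:4, 1)
    X <- matrix(sample(seq(0, 1, by = 0.05), n * p, replace = TRUE), n, p)
    colnames(X) <- paste0("x", 1:p)
    y <- rnorm(n) + X[, 1] * sample(0:2, 1)
    mb <- sample(c(1, 5, 10), 1)
    got <- best_split(X, y, minbucket = mb)
    want <- oracle_best_split(X, y, mb)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$col_index, want$col)
      expect_equal(got$threshold, want$threshold, tolerance = 1e-9)
      expect_equal(got$gain, want$gain, tolerance = 1e-9)
    }
  }
})

test_that("grow respects minbucket, recovers planted clusters, degenerates to a root", {
  set.seed(2)
  n <- 1200
  X <- cbind(M1 = rpois(n, 2), M2 = runif(n), M3 = runif(n))
  y <- ifelse(X[, "M1"] >= 2, 3, 0) + rnorm(n, 0, 0.4)
  d <- toy_design(X, y)
  tr <- grow_tree(d, minbucket = 100, cp = 0.01)
  expect_gte(tr$n_leaves, 2L)
  expect_equal(tr$nodes[["1"]]$column, "M1")
  # every leaf >= ceiling(minbucket); proportions sum to 1
  leaves <- Filter(function(nd) nd$leaf, tr$nodes)
  expect_true(all(vapply(leaves, `[[`, numeric(1), "n") >= 100))
  expect_equal(sum(vapply(leaves, `[[`, numeric(1), "proportion")), 1)
  # child SSE sums never exceed the parent's
  for (nd in tr$nodes) {
    if (!nd$leaf) {
      l <- tr$nodes[[as.character(2 * nd$id)]]
      r <- tr$nodes[[as.character(2 * nd$id + 1)]]
      expect_lte(l$sse + r$sse, nd$sse + 1e-9)
    }
  }
  # minbucket beyond n: single root, no clustering
  tr1 <- grow_tree(d, minbucket = n + 1, cp = 0.01)
  expect_equal(tr1$n_leaves, 1L)
  # constant response: single root
  tr2 <- grow_tree(toy_design(X, rep(2, n)), minbucket = 10)
  expect_equal(tr2$n_leaves, 1L)
  expect_error(grow_tree(toy_design(X[0, , drop = FALSE], numeric(0)), 10),
               "empty")
})

test_that("routing follows the split rules with ties going right", {
  set.seed(3)
  X <- cbind(a = runif(500), b = runif(500))
  y <- as.numeric(X[, "a"] > 0.4) + rnorm(500, 0, 0.1)
  d <- toy_design(X, y)
  tr <- grow_tree(d, minbucket = 50)
  thr <- tr$nodes[["1"]]$threshold
  right <- assign_cluster(tr, c(a = thr, b = 0.5))
  left <- assign_cluster(tr, c(a = thr - 1e-9, b = 0.5))
  expect_false(right == left)
  # routing training rows reproduces stored leaf counts
  cl <- assign_cluster(tr, X)
  counts <- table(cl)
  for (nd in Filter(function(nd) nd$leaf, tr$nodes))
    expect_equal(unname(counts[as.character(nd$cluster)]), nd$n,
                 ignore_attr = TRUE)
  # single-node tree routes everything to its only cluster
  tr1 <- grow_tree(d, minbucket = 1000)
  expect_true(all(assign_cluster(tr1, X) == 1L))
  expect_error(assign_cluster(tr, c(b = 0.5)), "split columns")
})

test_that("cost-complexity pruning keeps real structure and discards noise", {
  set.seed(4)
  n <- 400
  X <- cbind(u = runif(n), v = runif(n), w = runif(n))
  # pure-noise response: prunes back to the root in nearly every run
  to_root <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xs <- cbind(u = runif(n), v = runif(n), w = runif(n))
    ys <- rnorm(n)
    d <- toy_design(Xs, ys)
    tr <- grow_tree(d, minbucket = 20, cp = 0.005)
    if (tr$n_leaves == 1) return(TRUE)   # nothing grown, trivially a root
    cv_prune(tr, d, n_folds = 10, seed = s)$n_leaves == 1
  }, logical(1))
  expect_gte(sum(to_root), 18)
  # strong two-cluster signal survives pruning
  y <- ifelse(X[, "u"] >= 0.5, 2, 0) + rnorm(n, 0, 0.3)
  d <- toy_design(X, y)
  tr <- grow_tree(d, minbucket = 40, cp = 0.01)
  pr <- cv_prune(tr, d, n_folds = 10, seed = 1)
  expect_gte(pr$n_leaves, 2L)
  expect_equal(pr$nodes[["1"]]$column, "u")
  # single-node tree is returned unchanged
  tr1 <- grow_tree(d, minbucket = n + 5)
  expect_identical(cv_prune(tr1, d, seed = 1)$n_leaves, 1L)
  # pruning is deterministic given the seed
  pa <- cv_prune(tr, d, n_folds = 10, seed = 99)
  pb <- cv_prune(tr, d, n_folds = 10, seed = 99)
  expect_identical(tree_to_dot(pa), tree_to_dot(pb))
  # a pruned tree is a subtree: its node ids are a subset, SSE not lower
  sse_of <- function(t) sum(vapply(Filter(function(nd) nd$leaf, t$nodes),
                                   `[[`, numeric(1), "sse"))
  expect_true(all(names(pr$nodes) %in% names(tr$nodes)))
  expect_gte(sse_of(pr) + 1e-9, sse_of(tr))
})

test_that("the grown tree matches rpart's anova fit on the same data", {
  skip_if_not_installed("rpart")
  set.seed(6)
  n <- 800
  X <- cbind(M1 = rpois(n, 1.5) + runif(n, 0, 0.2), M2 = runif(n, 0, 4))
  y <- 1.5 * pmax(0, X[, "M1"] - 1) + ifelse(X[, "M2"] > 2, 1, 0) +
    rnorm(n, 0, 0.3)
  d <- toy_design(X, y)
  mb <- 80
  ours <- grow_tree(d, minbucket = mb, cp = 0.01)
  rp <- rpart::rpart(y ~ ., data = data.frame(X, y = y), method = "anova",
                     minbucket = mb, minsplit = 2 * mb, cp = 0.01,
                     xval = 0, maxsurrogate = 0, maxcompete = 0)
  # same root split variable and a threshold in the same inter-datum gap
  expect_equal(ours$nodes[["1"]]$column,
               as.character(rp$frame$var[1]))
  rp_thr <- rp$splits[1, "index"]
  col <- ours$nodes[["1"]]$column
  between <- function(t1, t2, xs) sum(xs > min(t1, t2) & xs < max(t1, t2))
  expect_equal(between(ours$nodes[["1"]]$threshold, rp_thr, X[, col]), 0)
  expect_equal(ours$n_leaves, sum(rp$frame$var == "<leaf>"))
})
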