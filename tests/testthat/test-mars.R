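# MARS: GCV arithmetic, forward hinge construction, backward pruning,
# prediction.

test_that("gcv matches its closed form and behaves monotonically", {
  expect_equal(gcv(100, 100, 1, 3), 1 / 0.99^2, tolerance = 1e-12)
  expect_equal(gcv(50, 100, 3, 3), 0.5 / 0.94^2, tolerance = 1e-12)
  expect_gt(gcv(60, 100, 3, 3), gcv(50, 100, 3, 3))
  expect_identical(gcv(10, 5, 4, 3), Inf)   # M_eff >= n is inadmissible
})

test_that("forward pass recovers a single hinge exactly", {
  set.seed(10)
  n <- 500
  X <- cbind(x1 = runif(n), x2 = runif(n))
  y <- pmax(0, X[, "x1"] - 0.5)
  m <- mars_fit(X, y, thresh = 1e-6)
  # grid-search oracle over all (column, knot) pairs for one hinge
  best <- list(rss = Inf)
  for (j in 1:2) for (c in sort(unique(X[, j]))) {
    for (h in list(pmax(0, X[, j] - c), pmax(0, c - X[, j]))) {
      r <- sum(lm.fit(cbind(1, h), y)$residuals^2)
      if (r < best$rss) best <- list(rss = r, col = j, knot = c)
    }
  }
  expect_equal(best$col, 1)
  knots <- unlist(lapply(m$terms, function(tm)
    vapply(tm$factors, function(f)
      if (f$col == "x1" && f$dir > 0) f$knot else NA_real_, numeric(1))))
  knots <- knots[!is.na(knots)]
  expect_gte(length(knots), 1)
  gap <- max(diff(sort(unique(X[, "x1"]))))
  expect_lt(min(abs(knots - 0.5)), gap + 1e-12)
  expect_lt(m$rss, 1e-4)   # exact up to the ridge stabilizer
  # the fitted coefficient of the matching hinge is about 1
  pred_hi <- predict(m, c(x1 = 0.9, x2 = 0.5))
  pred_lo <- predict(m, c(x1 = 0.5, x2 = 0.5))
  expect_equal(pred_hi - pred_lo, 0.4, tolerance = 0.01)
})

test_that("constant responses give an intercept-only model with zero RSS", {
  X <- cbind(x1 = runif(50))
  m <- mars_fit(X, rep(3, 50))
  expect_length(m$terms, 0)
  expect_equal(unname(m$coef[1]), 3)
  expect_lt(m$rss, 1e-9)
  expect_equal(unname(predict(m, c(x1 = 0.2))), 3)
})

test_that("an interaction surface yields a degree-2 product term", {
  set.seed(11)
  n <- 800
  X <- cbind(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 2 * pmax(0, X[, "x1"] - 0.4) * pmax(0, 0.7 - X[, "x2"]) +
    rnorm(n, 0, 0.05)
  m <- mars_fit(X, y)
  degs <- vapply(m$terms, function(tm) length(tm$factors), integer(1))
  expect_true(any(degs == 2))
  pair_cols <- lapply(m$terms[degs == 2], function(tm)
    sort(vapply(tm$factors, `[[`, character(1), "col")))
  expect_true(list(c("x1", "x2")) %in% pair_cols)
  # degree is capped at 2
  expect_true(all(degs <= 2))
  # max_degree 1 suppresses products
  m1 <- mars_fit(X, y, max_degree = 1)
  expect_true(all(vapply(m1$terms, function(tm)
    length(tm$factors), integer(1)) == 1))
})

test_that("backward pass deletes noise terms and never raises GCV above the forward model", {
  set.seed(12)
  n <- 300
  X <- cbind(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 3 * pmax(0, X[, "x1"] - 0.5) + rnorm(n, 0, 0.1)
  fwd <- mars_forward(X, y, max_terms = 11)
  prn <- mars_backward(fwd, X, y)
  expect_lte(prn$gcv, gcv(fwd$rss, n, length(fwd$terms) + 1, 3) + 1e-12)
  used <- unique(unlist(lapply(prn$terms, function(tm)
    vapply(tm$factors, `[[`, character(1), "col"))))
  expect_true("x1" %in% used)
  # intercept-only input is unchanged
  X0 <- cbind(x1 = runif(30))
  f0 <- mars_forward(X0, rep(1, 30))
  expect_length(mars_backward(f0, X0, rep(1, 30))$terms, 0)
})

test_that("backward pass equals the exhaustive GCV subset oracle on small models", {
  for (k in 1:8) {
    set.seed(500 + k)
    n <- 60
    p <- sample(2:3, 1)
    X <- matrix(runif(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- 2 * pmax(0, X[, 1] - 0.5) - 1.5 * pmax(0, 0.4 - X[, 2]) +
      rnorm(n, 0, 0.2)
    fwd <- mars_forward(X, y, max_terms = 9, thresh = 1e-6)
    if (length(fwd$terms) > 8 || length(fwd$terms) == 0) next
    got <- mars_backward(fwd, X, y, penalty = 3)
    want <- oracle_best_subset(fwd$terms, X, y, penalty = 3)
    expect_equal(got$gcv, want$gcv, tolerance = 1e-6)
  }
})

test_that("prediction is linear in the basis and consistent row-by-row", {
  m <- structure(list(
    terms = list(list(factors = list(list(col = "x", knot = 1, dir = 1)))),
    coef = c(0.5, 2), columns = "x"), class = "mars_model")
  expect_equal(unname(predict(m, c(x = 3))), 0.5 + 2 * 2)
  expect_equal(unname(predict(m, c(x = 0))), 0.5)
  set.seed(13)
  X <- cbind(x = rnorm(20))
  batch <- predict(m, X)
  single <- vapply(seq_len(20), function(i) predict(m, X[i, , drop = FALSE]),
                   numeric(1))
  expect_equal(batch, single)
  expect_error(predict(m, c(z = 1)), "missing column")
})

test_that("collinear predictors do not break the forward pass", {
  set.seed(14)
  n <- 200
  x <- runif(n)
  X <- cbind(x1 = x, x2 = x, x3 = runif(n))   # duplicated column
  y <- pmax(0, x - 0.3) + rnorm(n, 0, 0.05)
  m <- mars_fit(X, y)
  expect_gt(length(m$terms), 0)
  expect_true(is.finite(m$gcv))
  r2 <- 1 - m$rss / sum((y - mean(y))^2)
  expect_gt(r2, 0.9)
})

test_that("knot recovery holds across seeded replicates", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    n <- 2000
    X <- cbind(x1 = runif(n), x2 = runif(n))
    y <- 2 * pmax(0, X[, "x1"] - 0.4) - 3 * pmax(0, 0.6 - X[, "x2"]) +
      rnorm(n, 0, 0.1)
    m <- mars_fit(X, y)
    knots_on <- function(col) {
      k <- unlist(lapply(m$terms, function(tm)
        lapply(tm$factors, function(f) if (f$col == col) f$knot else NULL)))
      if (is.null(k)) numeric(0) else k
    }
    k1 <- knots_on("x1"); k2 <- knots_on("x2")
    ok <- length(k1) > 0 && length(k2) > 0 &&
      min(abs(k1 - 0.4)) < 0.05 && min(abs(k2 - 0.6)) < 0.05
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})
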