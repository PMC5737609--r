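# Multivariate adaptive regression splines: forward hinge-pair
# construction, GCV, backward pruning, prediction.

# A term is list(factors = list(list(col, knot, dir))), dir = +1 for
# max(0, x - c), -1 for max(0, c - x).  The intercept is implicit.

hinge_eval <- function(x, knot, dir) {
  if (dir > 0) pmax(0, x - knot) else pmax(0, knot - x)
}

# basis matrix of a term list (n x length(terms)); no intercept column
mars_basis <- function(terms, X) {
  if (length(terms) == 0L)
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0L))
  B <- vapply(terms, function(tm) {
    b <- rep(1, nrow(X))
    for (f in tm$factors) {
      if (!f$col %in% colnames(X))
        stop("missing column in data: ", f$col)
      b <- b * hinge_eval(X[, f$col], f$knot, f$dir)
    }
    b
  }, numeric(nrow(X)))
  matrix(B, nrow = nrow(X))
}

term_label <- function(tm) {
  paste(vapply(tm$factors, function(f) {
    if (f$dir > 0) sprintf("h(%s-%.4g)", f$col, f$knot)
    else sprintf("h(%.4g-%s)", f$knot, f$col)
  }, character(1L)), collapse = "*")
}

# ridge-stabilized least squares on [1 | B]
mars_lsfit <- function(B, y, ridge = 1e-8) {
  A <- cbind(1, B)
  G <- crossprod(A)
  diag(G) <- diag(G) + ridge * max(diag(G), 1)
  coef <- solve(G, crossprod(A, y))
  fitted <- drop(A %*% coef)
  list(coef = drop(coef), rss = sum((y - fitted)^2), fitted = fitted)
}

#' Generalized cross-validation score
#'
#' \deqn{GCV = \frac{RSS/n}{(1 - M_{eff}/n)^2}, \quad
#'       M_{eff} = M + penalty \cdot (M - 1)/2}
#' where `M` is the number of basis functions including the intercept.
#' The smoothing penalty charges each knot `penalty / 2` extra effective
#' parameters.  `M_eff >= n` returns `Inf` (model inadmissible).
#'
#' @param rss residual sum of squares.
#' @param n number of training observations.
#' @param n_terms number of basis functions including the intercept.
#' @param penalty GCV knot penalty (Friedman recommends 2-3).
#' @return Numeric scalar.
#' @export
gcv <- function(rss, n, n_terms, penalty = 3) {
  m_eff <- n_terms + penalty * (n_terms - 1) / 2
  if (m_eff >= n) return(Inf)
  (rss / n) / (1 - m_eff / n)^2
}

# candidate knot bookkeeping for one predictor matrix
knot_candidates <- function(X, knot_max) {
  ords <- matrix(0L, nrow(X), ncol(X))
  kpos <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    ords[, j] <- o
    xs <- X[o, j]
    last <- which(c(xs[-1L] != xs[-length(xs)], TRUE))  # last occurrence
    if (length(last) > knot_max)
      last <- last[unique(round(seq(1L, length(last), length.out = knot_max)))]
    kpos[[j]] <- as.integer(last)
  }
  list(ords = ords, kpos = kpos)
}

#' MARS forward pass
#'
#' Starting from the intercept, repeatedly adds the reflected hinge pair
#' `parent * max(0, x - c)` and `parent * max(0, c - x)` -- over all
#' current terms as parents, all columns not already in the parent, and
#' all candidate knots at observed values -- that yields the largest
#' decrease in the residual sum of squares with all coefficients refitted
#' by least squares.  Stops at `max_terms` basis functions or when the
#' best decrease falls below `thresh` of the total (centered) sum of
#' squares.  Basis columns that become numerically collinear are dropped
#' and counted in the `n_dropped` field.
#'
#' @param X numeric predictor matrix with column names.
#' @param y numeric response.
#' @param max_terms maximum number of basis functions including the
#'   intercept (odd, >= 3); default 61.
#' @param max_degree 1 for additive models, 2 to allow two-hinge products
#'   (the response-function form used here).
#' @param thresh forward stop: minimum RSS decrease as a fraction of the
#'   total sum of squares.
#' @param knot_max per-column cap on candidate knots (deterministic
#'   stride subsample of the distinct observed values).
#' @return An (unpruned) object of class `mars_model`; see [mars_fit()].
#' @export
mars_forward <- function(X, y, max_terms = 61, max_degree = 2,
                         thresh = 1e-4, knot_max = 500) {
  stopifnot(max_degree %in% c(1, 2), max_terms >= 3)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  ss_total <- sum((y - mean(y))^2)
  kc <- knot_candidates(X, knot_max)

  terms <- list()
  B <- matrix(1, n, 1L)            # raw basis, column 1 = intercept
  term_of_col <- 0L                # B column -> term index (0 = intercept)
  Q <- matrix(1 / sqrt(n), n, 1L)  # orthonormal basis of span(B)
  r <- y - mean(y)
  n_dropped <- 0L

  term_cols <- function(idx) {
    if (idx == 0L) character() else
      vapply(terms[[idx]]$factors, `[[`, character(1L), "col")
  }
  term_degree <- function(idx) {
    if (idx == 0L) 0L else length(terms[[idx]]$factors)
  }

  while (ncol(B) + 2L <= max_terms && ss_total > 0) {
    allowed <- matrix(FALSE, ncol(B), ncol(X))
    for (a in seq_len(ncol(B))) {
      idx <- term_of_col[a]
      if (term_degree(idx) >= max_degree) next
      allowed[a, !colnames(X) %in% term_cols(idx)] <- TRUE
    }
    if (!any(allowed)) break
    cand <- mars_best_candidate_cpp(Q, r, B, X, kc$ords, kc$kpos,
                                    allowed * 1L)
    if (cand$parent < 0 || cand$decrease / ss_total < thresh) break
    parent_idx <- term_of_col[cand$parent]
    parent_factors <- if (parent_idx == 0L) list() else
      terms[[parent_idx]]$factors
    col <- colnames(X)[cand$col]
    b_par <- B[, cand$parent]
    added <- FALSE
    for (dir in c(1, -1)) {
      newcol <- b_par * hinge_eval(X[, col], cand$knot, dir)
      q <- newcol
      for (pass in 1:2) q <- q - Q %*% crossprod(Q, q)
      nq <- sqrt(sum(q^2))
      if (nq^2 <= 1e-10 * max(1, sum(newcol^2))) {
        n_dropped <- n_dropped + 1L
        next
      }
      q <- q / nq
      terms[[length(terms) + 1L]] <- list(
        factors = c(parent_factors,
                    list(list(col = col, knot = cand$knot, dir = dir))))
      B <- cbind(B, newcol)
      Q <- cbind(Q, q)
      term_of_col <- c(term_of_col, length(terms))
      r <- r - q * sum(q * r)
      added <- TRUE
    }
    if (!added) break
  }

  fit <- mars_lsfit(B[, -1L, drop = FALSE], y)
  structure(list(
    terms = terms, coef = fit$coef, rss = fit$rss, n_train = n,
    gcv = NA_real_, columns = colnames(X), n_dropped = n_dropped,
    max_terms = max_terms, max_degree = max_degree,
    thresh = thresh, knot_max = knot_max), class = "mars_model")
}

#' MARS backward pass
#'
#' Selects the subset of forward-pass terms minimizing the GCV, with
#' coefficients refitted by least squares for every candidate subset.
#' Models with at most `exhaustive_limit` terms are searched exhaustively
#' (the GCV optimum is then exact); larger models use the classical
#' greedy deletion path -- repeatedly removing the term whose deletion
#' gives the lowest GCV and keeping the best model seen along the path.
#' GCV ties prefer the smaller model.
#'
#' @param model a `mars_model` from [mars_forward()].
#' @param X,y the training data.
#' @param penalty GCV knot penalty; default 3 when `max_degree > 1`, else 2.
#' @param exhaustive_limit largest term count for exact subset search.
#' @return A pruned `mars_model` with its `gcv` filled in.
#' @export
mars_backward <- function(model, X, y, penalty = NULL,
                          exhaustive_limit = 12) {
  penalty <- penalty %||% (if ((model$max_degree %||% 2) > 1) 3 else 2)
  X <- as.matrix(X)
  n <- length(y)
  B <- mars_basis(model$terms, X)
  A <- cbind(1, B)
  G <- crossprod(A)
  h <- crossprod(A, y)
  yy <- sum(y * y)
  ridge <- 1e-8 * max(diag(G), 1)
  rss_of <- function(keep) {
    Gs <- G[keep, keep, drop = FALSE]
    diag(Gs) <- diag(Gs) + ridge
    cf <- solve(Gs, h[keep])
    list(rss = max(0, yy - 2 * sum(cf * h[keep]) +
                     drop(crossprod(cf, G[keep, keep, drop = FALSE] %*% cf))),
         coef = drop(cf))
  }

  current <- seq_len(ncol(A))          # 1 = intercept
  full <- rss_of(current)
  best <- list(keep = current, coef = full$coef,
               gcv = gcv(full$rss, n, length(current), penalty))
  m_terms <- ncol(A) - 1L
  if (m_terms <= exhaustive_limit) {
    for (mask in seq_len(2^m_terms) - 1L) {
      keep <- c(1L, which(bitwAnd(mask, 2^(seq_len(m_terms) - 1L)) > 0) + 1L)
      cand <- rss_of(keep)
      g <- gcv(cand$rss, n, length(keep), penalty)
      if (g < best$gcv - 1e-12 ||
          (g <= best$gcv + 1e-12 && length(keep) < length(best$keep)))
        best <- list(keep = keep, coef = cand$coef, gcv = g)
    }
  } else {
    while (length(current) > 1L) {
      step_best <- NULL
      for (drop_i in current[-1L]) {
        keep <- setdiff(current, drop_i)
        cand <- rss_of(keep)
        g <- gcv(cand$rss, n, length(keep), penalty)
        if (is.null(step_best) || g < step_best$gcv) {
          step_best <- list(keep = keep, coef = cand$coef, gcv = g)
        }
      }
      current <- step_best$keep
      if (step_best$gcv <= best$gcv) best <- step_best
    }
  }

  keep_terms <- best$keep[-1L] - 1L    # indices into model$terms
  structure(list(
    terms = model$terms[keep_terms], coef = best$coef,
    rss = rss_of(best$keep)$rss, n_train = n, gcv = best$gcv,
    penalty = penalty, columns = model$columns,
    n_dropped = model$n_dropped, max_terms = model$max_terms,
    max_degree = model$max_degree, thresh = model$thresh,
    knot_max = model$knot_max), class = "mars_model")
}

#' Fit a MARS response function
#'
#' [mars_forward()] followed by [mars_backward()].  The fitted response
#' function has the form
#' \deqn{y = c + \sum c'' h(x_{i} - k) + \sum c' h(\cdot) h(\cdot)}
#' with hinge functions `h` at knots chosen from the observed values.
#'
#' @inheritParams mars_forward
#' @inheritParams mars_backward
#' @return A `mars_model`: `terms` (each a product of 1-2 hinge factors),
#'   `coef` (intercept first), `rss`, `gcv`, `n_train`.
#' @export
mars_fit <- function(X, y, max_terms = 61, max_degree = 2, penalty = NULL,
                     thresh = 1e-4, knot_max = 500) {
  fwd <- mars_forward(X, y, max_terms = max_terms, max_degree = max_degree,
                      thresh = thresh, knot_max = knot_max)
  mars_backward(fwd, X, y, penalty = penalty)
}

#' Predict from a MARS model
#' @param object a `mars_model`.
#' @param newdata numeric matrix (or single named row) containing every
#'   column the model uses.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mars_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  B <- mars_basis(object$terms, as.matrix(newdata))
  drop(cbind(1, B) %*% object$coef)
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("MARS model: %d term(s) + intercept, n = %d, RSS = %.4g, GCV = %.4g\n",
              length(x$terms), x$n_train, x$rss, x$gcv))
  cat(format_mars_formula(x), "\n")
  invisible(x)
}

#' Human-readable response function
#' @param model a `mars_model`.
#' @param response left-hand-side label.
#' @return Character scalar like
#'   `"activity = 0.5 + 2.1*h(V.M1-1.2) - 0.7*h(2-V.M2)*h(V.M3-1)"`.
#' @export
format_mars_formula <- function(model, response = "activity") {
  rhs <- format(model$coef[1L], digits = 4)
  if (length(model$terms) > 0L) {
    for (i in seq_along(model$terms)) {
      cf <- model$coef[i + 1L]
      rhs <- paste0(rhs, if (cf >= 0) " + " else " - ",
                    format(abs(cf), digits = 4), "*",
                    term_label(model$terms[[i]]))
    }
  }
  paste(response, "=", rhs)
}

mars_to_list <- function(model) {
  list(terms = lapply(model$terms, function(tm)
         list(factors = lapply(tm$factors, function(f)
           list(col = f$col, knot = f$knot, dir = f$dir)))),
       coef = as.numeric(model$coef), rss = model$rss, gcv = model$gcv,
       n_train = model$n_train, penalty = model$penalty %||% NA,
       columns = model$columns)
}

mars_from_list <- function(lst) {
  structure(list(
    terms = lapply(lst$terms, function(tm)
      list(factors = lapply(tm$factors, function(f)
        list(col = f$col, knot = as.numeric(f$knot), dir = as.numeric(f$dir))))),
    coef = as.numeric(lst$coef), rss = lst$rss, gcv = lst$gcv,
    n_train = as.integer(lst$n_train), penalty = lst$penalty,
    columns = unlist(lst$columns)), class = "mars_model")
}
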