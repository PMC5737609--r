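# Independent brute-force oracles.  These deliberately re-derive every
# quantity with naive loops, separate from the package's code paths.

BASES <- c("A", "C", "G", "T")

# naive information-weighted similarity score of one window
oracle_match <- function(pw, window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  s <- mn <- mx <- 0
  for (i in seq_len(pw$length)) {
    wrow <- pw$info[i] * pw$freqs[i, ]
    f <- if (chars[i] %in% BASES) wrow[[chars[i]]] else mean(wrow)
    s <- s + f
    mn <- mn + min(wrow)
    mx <- mx + max(wrow)
  }
  if (mx - mn <= 0) return(1)
  (s - mn) / (mx - mn)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# all-offsets, both-strands window enumeration
oracle_scan <- function(pw, sequence, cutoff) {
  L <- pw$length
  n <- nchar(sequence)
  hits <- list()
  for (start in seq_len(max(0, n - L + 1)) - 1L) {
    win <- substr(sequence, start + 1, start + L)
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else oracle_revcomp(win)
      sc <- oracle_match(pw, w)
      if (sc >= cutoff)
        hits[[length(hits) + 1]] <- data.frame(
          start = start, strand = strand, score = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive best split: every column, every midpoint threshold
oracle_best_split <- function(X, y, minbucket) {
  mb <- ceiling(minbucket)
  n <- nrow(X)
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  parent <- sse(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (t in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- X[, j] < t
      if (sum(left) < mb || sum(!left) < mb) next
      gain <- parent - sse(y[left]) - sse(y[!left])
      if (is.null(best) || gain > best$gain + 1e-12 * max(1, best$gain))
        best <- list(col = j, threshold = t, gain = gain)
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# exhaustive GCV-best subset of MARS terms (intercept always kept).
# Coefficients use the same ridge-stabilized least-squares convention as
# the fitting contract; the subset search itself is an independent
# enumeration.
oracle_best_subset <- function(terms, X, y, penalty) {
  basis <- function(sel) {
    if (length(sel) == 0) return(matrix(1, length(y), 1))
    cols <- vapply(terms[sel], function(tm) {
      b <- rep(1, nrow(X))
      for (f in tm$factors) {
        h <- if (f$dir > 0) pmax(0, X[, f$col] - f$knot)
             else pmax(0, f$knot - X[, f$col])
        b <- b * h
      }
      b
    }, numeric(nrow(X)))
    cbind(1, cols)
  }
  n <- length(y)
  best <- NULL
  for (size in 0:length(terms)) {
    for (sel in if (size == 0) list(integer(0)) else
         asplit(utils::combn(length(terms), size), 2)) {
      A <- basis(as.integer(sel))
      G <- crossprod(A)
      diag(G) <- diag(G) + 1e-8 * max(diag(G), 1)
      cf <- solve(G, crossprod(A, y))
      rss <- sum((y - A %*% cf)^2)
      m <- ncol(A)
      meff <- m + penalty * (m - 1) / 2
      g <- if (meff >= n) Inf else (rss / n) / (1 - meff / n)^2
      if (is.null(best) || g < best$gcv - 1e-10)
        best <- list(sel = sort(as.integer(sel)), gcv = g)
    }
  }
  best
}

# a quick random informative PWM for scan tests
random_pwm <- function(id, L, seed, concentration = 4) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, {
    f <- matrix(rgamma(4 * L, shape = 1), L, 4)
    f[cbind(seq_len(L), sample.int(4, L, replace = TRUE))] <-
      rgamma(L, shape = concentration) + concentration
    pwm(id, f / rowSums(f))
  })
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# small scenario used by unit tests (kept light; the reference scenario
# is exercised in the acceptance tests)
small_scenario <- function(seed = 1, ...) {
  args <- list(n_motifs = 6, motif_length = 8, n_sequences = 300,
               sequence_length = 120,
               planting_rates = c(1.5, 1.2, 1.2, 0.5, 0.5, 0.5),
               hinge_terms = list(
                 list(cluster = 1, motif = 2, knot = 1, dir = 1, coef = 1.5),
                 list(cluster = 2, motif = 3, knot = 1, dir = 1, coef = 2.0)),
               n_barcodes = 5, n_replicates = 3, depth = 200,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(mpra_scenario, args)
}
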