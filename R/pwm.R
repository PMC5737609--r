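# Position weight matrices, normalized similarity scoring and TFBS
# enrichment scores.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A `pwm` holds one motif's per-position base frequencies, the derived
#' per-position information weights, and an optional similarity-score
#' cutoff used when scanning sequences.
#'
#' The information weight at position i is
#' \deqn{I_i = \sum_b f_{ib} \ln(4 f_{ib})}
#' with the convention \eqn{0 \ln 0 = 0}.  It is zero for a flat position
#' and \eqn{\ln 4} for a fully determined one, so informative positions
#' dominate the similarity score.
#'
#' @param id matrix identifier, e.g. `"V.CREB1_Q6"`.
#' @param freqs numeric matrix, positions x 4 (A, C, G, T).  Rows are
#'   normalized to probabilities; supply counts together with
#'   `pseudocount` to smooth them.
#' @param cutoff similarity-score threshold in `[0, 1]`, or `NA` if not
#'   yet set (see [calibrate_minfn_cutoff()]).
#' @param pseudocount value added to every cell before row normalization.
#' @return An object of class `pwm` with elements `id`, `length`, `freqs`,
#'   `info` and `cutoff`.
#' @seealso [parse_motifs()], [match_score()], [scan_hits()]
#' @export
pwm <- function(id, freqs, cutoff = NA_real_, pseudocount = 0) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4L)
    stop("'freqs' must have 4 columns (A, C, G, T)")
  if (nrow(freqs) < 1L) stop("'freqs' must have at least one position")
  if (any(!is.finite(freqs)) || any(freqs < 0))
    stop("'freqs' must be non-negative and finite")
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  freqs <- freqs + pseudocount
  rs <- rowSums(freqs)
  if (any(rs <= 0)) stop("a position has zero total frequency; use a pseudocount")
  freqs <- freqs / rs
  dimnames(freqs) <- list(NULL, DNA_BASES)
  info <- apply(freqs, 1L, function(f) {
    nz <- f > 0
    sum(f[nz] * log(4 * f[nz]))
  })
  if (!is.na(cutoff) && (cutoff < 0 || cutoff > 1))
    stop("'cutoff' must lie in [0, 1]")
  structure(
    list(id = as.character(id), length = nrow(freqs), freqs = freqs,
         info = as.numeric(info), cutoff = as.numeric(cutoff)),
    class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: %d positions, consensus %s, cutoff %s\n",
              x$id, x$length, pwm_consensus(x),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff, digits = 4)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The most frequent base at each position (ties resolved toward the
#' alphabetically first base).
#' @param x a [pwm()] object.
#' @return A character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$freqs, 1L, which.max)], collapse = "")
}

# info-weighted frequency matrix (4 x L) plus scan bounds, shared by the
# R scorer and the C++ kernel
pwm_weights <- function(pwm) {
  W <- t(pwm$freqs) * rep(pwm$info, each = 4L)
  list(W = W,
       wN = colMeans(W),
       minS = sum(apply(W, 2L, min)),
       maxS = sum(apply(W, 2L, max)))
}

encode_dna <- function(x) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(x)]
}

revcomp_int <- function(v) {
  out <- rev(v)
  nz <- out != 0L
  out[nz] <- 5L - out[nz]
  out
}

#' Reverse complement of a DNA string
#'
#' Ambiguity codes other than N are not preserved; anything outside
#' A/C/G/T maps to N.
#' @param x character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    v <- rev(strsplit(chartr("acgtACGT", "TGCATGCA", s), "", fixed = TRUE)[[1L]])
    v[!v %in% DNA_BASES] <- "N"
    paste(v, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Normalized PWM similarity score of one window
#'
#' Scores a window of the motif's length with the information-weighted
#' matrix similarity
#' \deqn{score = \frac{\sum_i I_i f_i(w_i) - Min}{Max - Min}}
#' where `Min`/`Max` sum the per-position minima/maxima of the weighted
#' frequencies.  The consensus window scores exactly 1 and the
#' anti-consensus exactly 0.  Ambiguous bases (anything outside A/C/G/T)
#' contribute the position's mean weighted frequency.
#'
#' @param pwm a [pwm()] object.
#' @param window DNA string of length `pwm$length`.
#' @return Similarity score in `[0, 1]`.
#' @export
match_score <- function(pwm, window) {
  v <- encode_dna(window)
  if (length(v) != pwm$length)
    stop(sprintf("window length %d does not match PWM length %d",
                 length(v), pwm$length))
  w <- pwm_weights(pwm)
  as.numeric(scan_scores_cpp(v, w$W, w$wN, w$minS, w$maxS))
}

scan_strand <- function(v, w, cutoff) {
  s <- scan_scores_cpp(v, w$W, w$wN, w$minS, w$maxS)
  keep <- which(s >= cutoff)
  list(offsets = keep - 1L, scores = s[keep])
}

#' Scan a sequence for PWM hits on both strands
#'
#' Every forward and reverse-complement window is scored with
#' [match_score()]; windows at or above `cutoff` are reported as hits in
#' forward-strand coordinates (0-based, half-open), sorted by start.
#'
#' @param pwm a [pwm()] object.
#' @param sequence DNA string.
#' @param cutoff similarity cutoff in `[0, 1]`; defaults to the PWM's own.
#' @param sequence_id identifier used in the output.
#' @return A data frame with columns `sequence_id`, `matrix_id`, `start`,
#'   `end`, `strand` (`+`/`-`) and `score`.
#' @export
scan_hits <- function(pwm, sequence, cutoff = pwm$cutoff,
                      sequence_id = "seq") {
  if (is.na(cutoff))
    stop(sprintf("PWM %s has no cutoff; set one or pass 'cutoff'", pwm$id))
  if (cutoff < 0 || cutoff > 1) stop("'cutoff' must lie in [0, 1]")
  v <- encode_dna(sequence)
  L <- pwm$length
  empty <- data.frame(sequence_id = character(), matrix_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(v) < L) return(empty)
  w <- pwm_weights(pwm)
  fw <- scan_strand(v, w, cutoff)
  rv <- scan_strand(revcomp_int(v), w, cutoff)
  # a reverse window starting at o (0-based on the reverse strand) covers
  # forward positions [n - L - o, n - o)
  rv_start <- length(v) - L - rv$offsets
  if (length(fw$offsets) + length(rv_start) == 0L) return(empty)
  out <- data.frame(
    sequence_id = sequence_id,
    matrix_id = pwm$id,
    start = c(fw$offsets, rv_start),
    end = c(fw$offsets, rv_start) + L,
    strand = rep(c("+", "-"), c(length(fw$offsets), length(rv_start))),
    score = c(fw$scores, rv$scores),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' TFBS enrichment score of a sequence
#'
#' The per-sequence explanatory variable: the sum of the similarity scores
#' of all windows (both strands) that pass the matrix cutoff.  A sequence
#' with no passing window scores 0.
#'
#' @param pwm a [pwm()] object with its `cutoff` set.
#' @param sequence DNA string.
#' @return Non-negative numeric scalar.
#' @export
enrichment_score <- function(pwm, sequence) {
  if (is.na(pwm$cutoff))
    stop(sprintf("PWM %s has no cutoff; calibrate or set one first", pwm$id))
  v <- encode_dna(sequence)
  if (length(v) < pwm$length) return(0)
  w <- pwm_weights(pwm)
  tot <- 0
  for (enc in list(v, revcomp_int(v))) {
    s <- scan_scores_cpp(enc, w$W, w$wN, w$minS, w$maxS)
    tot <- tot + sum(s[s >= pwm$cutoff])
  }
  tot
}

#' TFBS enrichment matrix for a set of sequences
#'
#' @param pwms list of [pwm()] objects, all with cutoffs set.
#' @param sequences named character vector of DNA strings (names become
#'   row names).
#' @return Numeric matrix, sequences x matrices, with matrix ids as column
#'   names.
#' @export
enrichment_matrix <- function(pwms, sequences) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  ids <- unname(vapply(pwms, `[[`, character(1L), "id"))
  enc <- lapply(sequences, encode_dna)
  enc_rc <- lapply(enc, revcomp_int)
  E <- matrix(0, nrow = length(sequences), ncol = length(pwms),
              dimnames = list(names(sequences), ids))
  for (k in seq_along(pwms)) {
    pw <- pwms[[k]]
    if (is.na(pw$cutoff))
      stop(sprintf("PWM %s has no cutoff; calibrate or set one first", pw$id))
    w <- pwm_weights(pw)
    for (i in seq_along(enc)) {
      s1 <- scan_scores_cpp(enc[[i]], w$W, w$wN, w$minS, w$maxS)
      s2 <- scan_scores_cpp(enc_rc[[i]], w$W, w$wN, w$minS, w$maxS)
      E[i, k] <- sum(s1[s1 >= pw$cutoff]) + sum(s2[s2 >= pw$cutoff])
    }
  }
  E
}

#' Calibrate a minimum-false-negative cutoff for a PWM
#'
#' Draws `n_samples` sites from the PWM's own frequency model, scores them
#' with [match_score()], and returns the `target_fnr` quantile of the
#' score distribution, so that at least `1 - target_fnr` of true sites
#' pass the cutoff.  This mirrors the minFN philosophy of database-supplied
#' matrix profiles without redistributing any database content.
#'
#' @param pwm a [pwm()] object.
#' @param target_fnr tolerated false negative rate, in (0, 1).
#' @param n_samples Monte-Carlo sample size.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return Cutoff in `[0, 1]` (a degenerate matrix returns `1 - 1e-9`).
#' @export
calibrate_minfn_cutoff <- function(pwm, target_fnr = 0.05,
                                   n_samples = 10000, seed = NULL) {
  if (target_fnr <= 0 || target_fnr >= 1)
    stop("'target_fnr' must lie in (0, 1)")
  w <- pwm_weights(pwm)
  if (w$maxS - w$minS <= 0) return(1 - 1e-9)
  scores <- with_seed(seed, {
    L <- pwm$length
    draws <- vapply(seq_len(L), function(i) {
      sample.int(4L, n_samples, replace = TRUE, prob = pwm$freqs[i, ])
    }, integer(n_samples))
    raw <- numeric(n_samples)
    for (i in seq_len(L)) raw <- raw + w$W[cbind(draws[, i], i)]
    (raw - w$minS) / (w$maxS - w$minS)
  })
  cut <- as.numeric(quantile(scores, probs = target_fnr, type = 7))
  min(max(cut, 0), 1 - 1e-9)
}
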