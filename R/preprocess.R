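# MPRA barcode-count preprocessing: counts -> activities -> irregular-
# construct filtering.

#' Convert barcode counts to construct activities
#'
#' The transcriptional activity of a construct is derived from the log2
#' ratio of mRNA to DNA barcode counts: per barcode
#' `log2((mrna + pseudocount) / (dna + pseudocount))`, aggregated as the
#' median across barcodes within a replicate (robust to barcode dropout)
#' and then the mean across replicates.  The standard deviation of the
#' per-replicate values is recorded as `replicate_sd` and feeds the
#' irregularity filter.
#'
#' @param counts data frame with columns `construct_id`, `barcode`,
#'   `replicate`, `dna_count`, `mrna_count` and optionally `condition`
#'   (absent means a single unnamed condition, labelled `"none"`).
#' @param pseudocount added to both counts before the ratio; must be > 0
#'   if any count is zero.
#' @return A data frame (one row per construct x condition) with columns
#'   `construct_id`, `condition`, `activity`, `replicate_sd`,
#'   `n_replicates`, `n_barcodes`.  The number of rows dropped for having
#'   no usable barcode is attached as attribute `n_excluded`.
#' @export
activity_from_counts <- function(counts, pseudocount = 1) {
  need <- c("construct_id", "barcode", "replicate", "dna_count", "mrna_count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0L)
    stop("counts table lacks columns: ", paste(miss, collapse = ", "))
  if (!"condition" %in% names(counts)) counts$condition <- "none"
  if (any(counts$dna_count < 0) || any(counts$mrna_count < 0))
    stop("counts must be non-negative")
  ok <- is.finite(counts$dna_count) & is.finite(counts$mrna_count)
  n_excluded <- sum(!ok)
  counts <- counts[ok, , drop = FALSE]
  if (nrow(counts) == 0L) stop("no usable count rows")
  if (pseudocount <= 0 &&
      any(counts$dna_count == 0 | counts$mrna_count == 0))
    stop("zero counts present; use a positive pseudocount")

  ratio <- log2((counts$mrna_count + pseudocount) /
                (counts$dna_count + pseudocount))
  rep_key <- paste(counts$construct_id, counts$condition,
                   counts$replicate, sep = "\r")
  rep_med <- vapply(split(ratio, rep_key), median, numeric(1L))
  rep_nbc <- vapply(split(ratio, rep_key), length, integer(1L))
  parts <- strsplit(names(rep_med), "\r", fixed = TRUE)
  cc_key <- vapply(parts, function(p) paste(p[1L], p[2L], sep = "\r"),
                   character(1L))

  agg <- function(f, x) vapply(split(x, cc_key), f, numeric(1L))
  act <- agg(mean, rep_med)
  rsd <- vapply(split(rep_med, cc_key), function(v)
    if (length(v) > 1L) sd(v) else 0, numeric(1L))
  nrep <- vapply(split(rep_med, cc_key), length, numeric(1L))
  nbc <- agg(function(v) mean(v), as.numeric(rep_nbc))

  kp <- strsplit(names(act), "\r", fixed = TRUE)
  out <- data.frame(
    construct_id = vapply(kp, `[[`, character(1L), 1L),
    condition = vapply(kp, `[[`, character(1L), 2L),
    activity = as.numeric(act),
    replicate_sd = as.numeric(rsd),
    n_replicates = as.integer(nrep),
    n_barcodes = as.numeric(nbc),
    stringsAsFactors = FALSE)
  out <- out[order(out$construct_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Remove irregular constructs by replicate variability
#'
#' Experimental precision is estimated from replicates: constructs whose
#' `replicate_sd` exceeds the `sd_quantile` quantile of all replicate SDs
#' are removed as irregular.  Ties at the threshold are kept, so when all
#' replicates agree (SD 0 everywhere) nothing is removed.
#'
#' @param activities data frame from [activity_from_counts()] (must carry
#'   `replicate_sd`).
#' @param sd_quantile quantile in (0, 1) above which constructs are
#'   dropped; default 0.95.
#' @return `list(kept = <activity table>, removed_ids = <character>,
#'   threshold = <numeric>)`.
#' @export
filter_irregular <- function(activities, sd_quantile = 0.95) {
  if (!"replicate_sd" %in% names(activities))
    stop("'activities' lacks a replicate_sd column")
  if (sd_quantile <= 0 || sd_quantile >= 1)
    stop("'sd_quantile' must lie in (0, 1)")
  thr <- as.numeric(quantile(activities$replicate_sd, sd_quantile, type = 7))
  drop <- activities$replicate_sd > thr
  if (all(drop)) stop("irregularity threshold removed every construct")
  list(kept = activities[!drop, , drop = FALSE],
       removed_ids = unique(activities$construct_id[drop]),
       threshold = thr)
}

#' Read a barcode count table from TSV
#' @param path TSV with the [activity_from_counts()] input columns.
#' @return Data frame.
#' @export
read_counts <- function(path) read_tsv(path)

#' Read an activity table from TSV
#' @param path TSV with at least `construct_id`, `condition`, `activity`.
#' @return Data frame.
#' @export
read_activities <- function(path) {
  df <- read_tsv(path)
  if (!"condition" %in% names(df)) df$condition <- "none"
  df
}

#' Write an activity table to TSV
#' @param activities data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activities <- function(activities, path) write_tsv(activities, path)

#' QC summary of the preprocessing step
#'
#' @param activities table from [activity_from_counts()].
#' @param filtered result of [filter_irregular()].
#' @param breaks number of histogram bins for the replicate-SD summary.
#' @return Data frame with kept/removed counts and SD histogram rows.
#' @export
preprocess_qc <- function(activities, filtered, breaks = 20) {
  h <- graphics::hist(activities$replicate_sd, breaks = breaks, plot = FALSE)
  data.frame(
    metric = c("n_total", "n_kept", "n_removed", "sd_threshold",
               paste0("sd_bin_", format(h$mids, digits = 3))),
    value = c(nrow(activities), nrow(filtered$kept),
              nrow(activities) - nrow(filtered$kept), filtered$threshold,
              h$counts),
    stringsAsFactors = FALSE)
}
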