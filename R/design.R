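# Explanatory-variable matrix assembly and the feature redundancy-
# dependent sizing formulas.

#' Assemble the explanatory-variable matrix
#'
#' One row per (construct, condition) pairing present in `activities`;
#' columns are the TFBS enrichment scores plus one 0/1 indicator column
#' per distinct condition label.  A single-condition table gets no
#' condition columns, and the reserved label `"none"` encodes the
#' all-zero "no condition" row used for cross-condition prediction.
#'
#' @param enrichments numeric matrix from [enrichment_matrix()], rows
#'   named by construct/sequence id.
#' @param activities data frame with `construct_id`, `condition`,
#'   `activity` (e.g. from [activity_from_counts()]).
#' @return An object of class `design_matrix`: list with `x` (numeric
#'   matrix), `y` (response), `construct`, `condition`, `tfbs_columns`,
#'   `condition_columns` and `row_id`.
#' @export
build_design_matrix <- function(enrichments, activities) {
  if (!"condition" %in% names(activities)) activities$condition <- "none"
  miss <- setdiff(unique(activities$construct_id), rownames(enrichments))
  if (length(miss) > 0L)
    stop("activities without an enrichment row: ",
         paste(head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L))
  E <- enrichments[activities$construct_id, , drop = FALSE]
  labels <- sort(setdiff(unique(activities$condition), "none"))
  if (length(labels) < 2L && !("none" %in% activities$condition &&
                               length(labels) >= 1L)) labels <- character()
  C <- NULL
  if (length(labels) > 0L) {
    C <- vapply(labels, function(l) as.numeric(activities$condition == l),
                numeric(nrow(activities)))
    C <- matrix(C, nrow = nrow(activities),
                dimnames = list(NULL, labels))
  }
  x <- if (is.null(C)) E else cbind(E, C)
  rid <- if (length(labels) > 0L)
    paste(activities$construct_id, activities$condition, sep = "@")
  else activities$construct_id
  rownames(x) <- rid
  structure(list(
    x = x,
    y = as.numeric(activities$activity),
    construct = activities$construct_id,
    condition = activities$condition,
    tfbs_columns = colnames(enrichments),
    condition_columns = labels,
    row_id = rid), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix: %d rows, %d TFBS columns, %d condition columns\n",
              nrow(x$x), length(x$tfbs_columns), length(x$condition_columns)))
  invisible(x)
}

subset_design <- function(design, rows) {
  structure(list(
    x = design$x[rows, , drop = FALSE],
    y = design$y[rows],
    construct = design$construct[rows],
    condition = design$condition[rows],
    tfbs_columns = design$tfbs_columns,
    condition_columns = design$condition_columns,
    row_id = design$row_id[rows]), class = "design_matrix")
}

#' Proportion of variance on the first principal component
#'
#' The redundancy measure of the TFBS enrichment columns: PCA is run on
#' the standardized (unit-variance) TFBS columns only -- condition
#' indicator columns are excluded -- and the fraction of total variance
#' carried by the first component is returned.  Redundant (correlated)
#' feature sets give values near 1; independent features give about
#' `1 / p`.
#'
#' @param design a `design_matrix`, or a plain numeric matrix of TFBS
#'   enrichment scores.
#' @return Numeric scalar in (0, 1].
#' @export
pc1_proportion <- function(design) {
  X <- if (inherits(design, "design_matrix"))
    design$x[, design$tfbs_columns, drop = FALSE] else as.matrix(design)
  sds <- apply(X, 2L, sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < 2L)
    stop("pc1_proportion needs at least 2 TFBS columns with nonzero variance")
  R <- cor(X[, keep, drop = FALSE])
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  max(ev) / sum(ev)
}

#' Redundancy-dependent sizing of the regression tree
#'
#' Converts feature redundancy and sample size into the minimum terminal
#' cluster size of the regression tree:
#' \deqn{variation\ parameter = \frac{2^{-pc1} \cdot 10^7}{n^2}, \qquad
#'       minbucket = variation\ parameter \cdot n.}
#' Highly redundant features (pc1 near 1) shrink `minbucket`; small data
#' sets blow it up past `n` so that no clustering is performed and a
#' single response function is fitted.  `minbucket` is returned as a real
#' number; tree growing enforces `ceiling(minbucket)`.
#'
#' @param pc1 proportion of variance of the first principal component, in
#'   (0, 1] (see [pc1_proportion()]).
#' @param n_observations number of rows of the design matrix.
#' @return An object of class `sizing_params`: list with `pc1_proportion`,
#'   `n_observations`, `variation_parameter`, `minbucket`.
#' @export
sizing_params <- function(pc1, n_observations) {
  if (pc1 <= 0 || pc1 > 1) stop("'pc1' must lie in (0, 1]")
  if (n_observations < 1) stop("'n_observations' must be >= 1")
  vp <- 2^(-pc1) * 1e7 / n_observations^2
  structure(list(
    pc1_proportion = pc1,
    n_observations = as.integer(n_observations),
    variation_parameter = vp,
    minbucket = vp * n_observations), class = "sizing_params")
}

#' @export
print.sizing_params <- function(x, ...) {
  cat(sprintf(
    "sizing: pc1 = %.4f, n = %d, variation parameter = %.4g, minbucket = %.2f%s\n",
    x$pc1_proportion, x$n_observations, x$variation_parameter, x$minbucket,
    if (ceiling(x$minbucket) >= x$n_observations) " (no clustering)" else ""))
  invisible(x)
}

#' Write / read a design matrix as TSV
#'
#' Header: `row_id`, `construct_id`, `condition`, the condition columns,
#' the TFBS columns, then `activity`.
#' @param design a `design_matrix`.
#' @param path file path.
#' @return `path` (write) or a `design_matrix` (read).
#' @export
write_design_matrix <- function(design, path) {
  df <- data.frame(row_id = design$row_id,
                   construct_id = design$construct,
                   condition = design$condition,
                   design$x, activity = design$y,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path) {
  df <- read_tsv(path)
  fixed <- c("row_id", "construct_id", "condition", "activity")
  cols <- setdiff(names(df), fixed)
  x <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- df$row_id
  labels <- sort(setdiff(unique(df$condition), "none"))
  cond_cols <- intersect(cols, labels)
  structure(list(
    x = x, y = as.numeric(df$activity),
    construct = df$construct_id, condition = df$condition,
    tfbs_columns = setdiff(cols, cond_cols),
    condition_columns = cond_cols,
    row_id = df$row_id), class = "design_matrix")
}
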