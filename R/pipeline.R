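# End-to-end predictor: redundancy-sized tree clustering + per-cluster
# MARS, cross-validated evaluation and interpretation reports.

default_config <- function(config = list()) {
  defaults <- list(
    cp = 0.01,            # tree complexity parameter
    tree_cv_folds = 10,   # folds for cost-complexity pruning
    max_terms = 61,       # MARS forward basis cap (incl. intercept)
    max_degree = 2,       # allow two-hinge products
    penalty = NULL,       # GCV penalty (NULL: 3 if interactions, else 2)
    thresh = 1e-4,        # MARS forward stop
    knot_max = 500,       # candidate knots per column
    minbucket = NULL,     # override the sizing formula (mainly for tests)
    seed = 1)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0L)
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, config)
}

#' Fit the full activity-prediction pipeline
#'
#' Computes the feature-redundancy sizing ([pc1_proportion()],
#' [sizing_params()]), grows and cross-validation-prunes the regression
#' tree, and fits a MARS response function inside every terminal cluster.
#' When `ceiling(minbucket) >= n` the tree is a single root and one
#' response function is fitted to the whole data set.
#'
#' @param design a `design_matrix` from [build_design_matrix()].
#' @param config named list overriding the defaults: `cp`,
#'   `tree_cv_folds`, `max_terms`, `max_degree`, `penalty`, `thresh`,
#'   `knot_max`, `minbucket` (overrides the sizing formula), `seed`.
#' @return An object of class `mpra_pipeline`: `tree`, `leaf_models`
#'   (one `mars_model` per cluster), `sizing`, `config`,
#'   `tfbs_columns`, `condition_columns`.
#' @export
mpra_fit <- function(design, config = list()) {
  cfg <- default_config(config)
  n <- nrow(design$x)
  if (is.null(cfg$minbucket)) {
    sizing <- sizing_params(pc1_proportion(design), n)
  } else {
    sizing <- structure(list(pc1_proportion = NA_real_, n_observations = n,
                             variation_parameter = cfg$minbucket / n,
                             minbucket = cfg$minbucket),
                        class = "sizing_params")
  }
  tree <- grow_tree(design, sizing$minbucket, cfg$cp)
  tree <- cv_prune(tree, design, n_folds = cfg$tree_cv_folds,
                   seed = cfg$seed)
  clusters <- assign_cluster(tree, design$x)
  leaf_models <- lapply(seq_len(tree$n_leaves), function(k) {
    rows <- which(clusters == k)
    mars_fit(design$x[rows, , drop = FALSE], design$y[rows],
             max_terms = cfg$max_terms, max_degree = cfg$max_degree,
             penalty = cfg$penalty, thresh = cfg$thresh,
             knot_max = cfg$knot_max)
  })
  structure(list(
    tree = tree, leaf_models = leaf_models, sizing = sizing, config = cfg,
    tfbs_columns = design$tfbs_columns,
    condition_columns = design$condition_columns), class = "mpra_pipeline")
}

#' @export
print.mpra_pipeline <- function(x, ...) {
  print(x$sizing)
  print(x$tree)
  for (k in seq_along(x$leaf_models)) {
    cat(sprintf("cluster %d: ", k))
    print(x$leaf_models[[k]])
  }
  invisible(x)
}

pipeline_rows <- function(pipeline, enrichments, condition) {
  E <- as.matrix(enrichments)
  miss <- setdiff(pipeline$tfbs_columns, colnames(E))
  if (length(miss) > 0L)
    stop("enrichments lack matrix columns: ", paste(miss, collapse = ", "))
  E <- E[, pipeline$tfbs_columns, drop = FALSE]
  labels <- pipeline$condition_columns
  if (length(labels) == 0L) return(E)
  if (!condition %in% c(labels, "none"))
    stop(sprintf("unknown condition '%s'; known: %s", condition,
                 paste(c(labels, "none"), collapse = ", ")))
  C <- matrix(as.numeric(labels == condition), nrow(E), length(labels),
              byrow = TRUE, dimnames = list(NULL, labels))
  cbind(E, C)
}

#' Predict activities for new sequences
#'
#' Builds rows from an enrichment matrix under one condition label
#' (`"none"` sets every condition indicator to 0, the device used for
#' cross-condition prediction), routes each row through the tree, and
#' evaluates the cluster's response function.
#'
#' @param object a fitted `mpra_pipeline`.
#' @param enrichments numeric matrix with the training TFBS columns.
#' @param condition one of the training condition labels, or `"none"`.
#' @param ... unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.mpra_pipeline <- function(object, enrichments,
                                  condition = "none", ...) {
  X <- pipeline_rows(object, enrichments, condition)
  clusters <- assign_cluster(object$tree, X)
  out <- numeric(nrow(X))
  for (k in unique(clusters)) {
    at <- clusters == k
    out[at] <- predict(object$leaf_models[[k]], X[at, , drop = FALSE])
  }
  out
}

# closed-test predictions of the training design
pipeline_fitted <- function(pipeline, design) {
  clusters <- assign_cluster(pipeline$tree, design$x)
  out <- numeric(nrow(design$x))
  for (k in unique(clusters)) {
    at <- clusters == k
    out[at] <- predict(pipeline$leaf_models[[k]],
                       design$x[at, , drop = FALSE])
  }
  out
}

#' Cross-validated evaluation of the pipeline
#'
#' Partitions the design rows into `n_folds` seeded folds, refits the
#' whole pipeline (sizing, tree, pruning, per-cluster MARS) on each
#' training fold and predicts the held-out rows.  Reports the Pearson
#' correlation of the closed test (full-data fit) and of the open test
#' (pooled held-out predictions), following the 100-fold convention.
#'
#' @param design a `design_matrix`.
#' @param config pipeline configuration (see [mpra_fit()]).
#' @param n_folds number of folds, default 100.
#' @param seed fold-assignment seed (also seeds the per-fold refits).
#' @return List of class `mpra_evaluation`: `pearson_r_closed`,
#'   `pearson_r_open`, `n_folds`, `max_predictors` (largest pruned model
#'   over the full fit's clusters), `predictions` (per-row closed/open
#'   values and fold), and the full-data `pipeline`.
#' @export
evaluate_cv <- function(design, config = list(), n_folds = 100,
                        seed = 1) {
  n <- nrow(design$x)
  if (n_folds > n) stop("more folds than rows")
  cfg <- default_config(config)
  cfg$seed <- seed
  full <- mpra_fit(design, cfg)
  closed <- pipeline_fitted(full, design)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  open <- rep(NA_real_, n)
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    cfg_f <- cfg
    cfg_f$seed <- seed + f
    fit_f <- mpra_fit(subset_design(design, tr), cfg_f)
    clusters <- assign_cluster(fit_f$tree, design$x[te, , drop = FALSE])
    for (k in unique(clusters)) {
      at <- te[clusters == k]
      open[at] <- predict(fit_f$leaf_models[[k]],
                          design$x[at, , drop = FALSE])
    }
  }
  structure(list(
    pearson_r_closed = cor(design$y, closed),
    pearson_r_open = cor(design$y, open),
    n_folds = n_folds,
    max_predictors = max(0L, vapply(full$leaf_models, function(m)
      length(m$terms), integer(1L))),
    predictions = data.frame(row_id = design$row_id, observed = design$y,
                             closed = closed, open = open, fold = folds,
                             stringsAsFactors = FALSE),
    pipeline = full), class = "mpra_evaluation")
}

#' @export
print.mpra_evaluation <- function(x, ...) {
  cat(sprintf(
    "closed-test r = %.3f, open-test r = %.3f (%d-fold CV), max predictors = %d\n",
    x$pearson_r_closed, x$pearson_r_open, x$n_folds, x$max_predictors))
  invisible(x)
}

#' Candidate-active TFBS tree report
#'
#' One row per tree node: internal nodes carry the split rule (matrix id
#' and threshold); leaves carry the cluster id, mean activity, sample
#' count and percentage, and the size of the cluster's response function.
#'
#' @param pipeline a fitted `mpra_pipeline`.
#' @return Data frame with columns `node_id`, `type`, `column`,
#'   `threshold`, `cluster`, `n`, `proportion_pct`, `mean_activity`,
#'   `model_terms`.
#' @export
tfbs_tree_report <- function(pipeline) {
  tree <- pipeline$tree
  ids <- sort(as.integer(names(tree$nodes)))
  rows <- lapply(ids, function(id) {
    nd <- tree_node(tree, id)
    if (nd$leaf) {
      data.frame(node_id = id, type = "leaf", column = NA_character_,
                 threshold = NA_real_, cluster = nd$cluster, n = nd$n,
                 proportion_pct = 100 * nd$proportion,
                 mean_activity = nd$mean,
                 model_terms = length(pipeline$leaf_models[[nd$cluster]]$terms),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(node_id = id, type = "split", column = nd$column,
                 threshold = nd$threshold, cluster = NA_integer_,
                 n = nd$n, proportion_pct = 100 * nd$n / tree$n,
                 mean_activity = nd$mean, model_terms = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Frequencies of TFBSs selected by the response functions
#'
#' Counts, over all clusters and all basis terms, how often each matrix
#' id appears as a hinge factor.  Condition indicator columns are
#' excluded: the count reflects binding sites, not assay conditions.
#'
#' @param pipeline a fitted `mpra_pipeline`.
#' @return Named integer vector (descending), possibly empty.
#' @export
selected_tfbs_frequencies <- function(pipeline) {
  cols <- unlist(lapply(pipeline$leaf_models, function(m)
    unlist(lapply(m$terms, function(tm)
      vapply(tm$factors, `[[`, character(1L), "col")))))
  cols <- cols[cols %in% pipeline$tfbs_columns]
  if (length(cols) == 0L)
    return(structure(integer(0), names = character(0)))
  sort(table(cols), decreasing = TRUE) |> c()
}

#' Condition-specific TFBS sets of two fitted pipelines
#'
#' Set algebra on the matrix ids selected by the two pipelines' response
#' functions, used to contrast e.g. two cell states: sites selected under
#' both, and sites specific to either.
#'
#' @param pipeline_a,pipeline_b fitted `mpra_pipeline` objects.
#' @return `list(shared =, only_a =, only_b =)` of character vectors.
#' @export
condition_specific_tfbs <- function(pipeline_a, pipeline_b) {
  a <- names(selected_tfbs_frequencies(pipeline_a))
  b <- names(selected_tfbs_frequencies(pipeline_b))
  list(shared = sort(intersect(a, b)),
       only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)))
}

#' Enrichment fold changes of badly fitted constructs
#'
#' Contrasts the most over-estimated and most under-estimated constructs
#' against the best fitted ones: residuals are `predicted - observed`;
#' the top/bottom `tail_frac` form the two misfit tails and the
#' `best_frac` smallest absolute residuals form the reference set.  For
#' every matrix the fold change of mean enrichment (tail vs reference,
#' stabilized by the pseudo-mean `eps`) is computed, and matrices with
#' fold change `>= min_fold` or `<= 1/min_fold` in either tail are
#' reported.  The report is invariant to shifting all activities by a
#' constant.
#'
#' @param pipeline a fitted `mpra_pipeline`.
#' @param design the `design_matrix` to evaluate on.
#' @param tail_frac fraction in each misfit tail (default 0.05).
#' @param best_frac fraction forming the best-fitted reference set
#'   (default 0.10).
#' @param min_fold fold-change threshold (default 2).
#' @param eps pseudo-mean added to numerator and denominator.
#' @return Data frame `matrix_id`, `tail` (`"over"`/`"under"`),
#'   `fold_change`, `mean_tail`, `mean_best`, sorted by descending
#'   deviation from 1; zero rows when predictions are uniformly good.
#' @export
misfit_enrichment <- function(pipeline, design, tail_frac = 0.05,
                              best_frac = 0.10, min_fold = 2.0,
                              eps = 0.01) {
  stopifnot(tail_frac > 0, tail_frac < 0.5, best_frac > 0, best_frac < 0.5)
  resid <- pipeline_fitted(pipeline, design) - design$y
  n <- length(resid)
  k_tail <- max(1L, floor(tail_frac * n))
  k_best <- max(1L, floor(best_frac * n))
  o <- order(resid)
  under <- o[seq_len(k_tail)]                 # most under-estimated
  over <- o[seq.int(n - k_tail + 1L, n)]      # most over-estimated
  best <- order(abs(resid))[seq_len(k_best)]
  E <- design$x[, pipeline$tfbs_columns, drop = FALSE]
  mb <- colMeans(E[best, , drop = FALSE])
  out <- lapply(c(over = "over", under = "under"), function(tail) {
    rows <- if (tail == "over") over else under
    mt <- colMeans(E[rows, , drop = FALSE])
    fc <- (mt + eps) / (mb + eps)
    hit <- fc >= min_fold | fc <= 1 / min_fold
    data.frame(matrix_id = names(fc)[hit], tail = rep(tail, sum(hit)),
               fold_change = unname(fc[hit]), mean_tail = unname(mt[hit]),
               mean_best = unname(mb[hit]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-abs(log(out$fold_change))), , drop = FALSE]
}

#' Save / load a fitted pipeline as JSON
#'
#' The whole pipeline -- tree, per-cluster response functions, sizing,
#' configuration and the motif cutoffs in force -- round-trips through a
#' single JSON document so that any result can be replayed.
#'
#' @param pipeline a fitted `mpra_pipeline`.
#' @param path JSON file path.
#' @param motifs optional list of [pwm()] objects whose ids/cutoffs are
#'   recorded alongside the model.
#' @return `path` (write) or an `mpra_pipeline` (read).
#' @export
write_pipeline <- function(pipeline, path, motifs = NULL) {
  doc <- list(
    tree = tree_to_list(pipeline$tree),
    leaf_models = lapply(pipeline$leaf_models, mars_to_list),
    sizing = unclass(pipeline$sizing),
    config = pipeline$config,
    tfbs_columns = pipeline$tfbs_columns,
    condition_columns = pipeline$condition_columns,
    motif_cutoffs = if (!is.null(motifs))
      stats::setNames(lapply(motifs, `[[`, "cutoff"),
                      vapply(motifs, `[[`, character(1L), "id")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(path) {
  doc <- jsonlite::read_json(path)
  structure(list(
    tree = tree_from_list(doc$tree),
    leaf_models = lapply(doc$leaf_models, mars_from_list),
    sizing = structure(doc$sizing, class = "sizing_params"),
    config = doc$config,
    tfbs_columns = unlist(doc$tfbs_columns),
    condition_columns = as.character(unlist(doc$condition_columns)),
    motif_cutoffs = doc$motif_cutoffs), class = "mpra_pipeline")
}
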