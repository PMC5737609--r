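# Redundancy-sized regression tree: SSE (anova) splitting under a
# minimum terminal-cluster size, with cost-complexity pruning selected by
# cross-validation.

#' Best SSE-reducing split of a set of rows
#'
#' Scans every column and every midpoint between consecutive distinct
#' observed values, and returns the split maximizing the reduction in the
#' residual sum of squares subject to both children holding at least
#' `ceiling(minbucket)` rows.  Rows with value `< threshold` go left;
#' values equal to the threshold go right.  Equal-gain ties are broken
#' toward the lowest column index, then the lowest threshold.
#'
#' @param X numeric matrix of explanatory variables.
#' @param y numeric response.
#' @param rows integer row indices considered (default: all).
#' @param minbucket minimum child size (real; enforced as its ceiling).
#' @return `NULL` if no legal split reduces the SSE; otherwise a list
#'   with `column`, `col_index`, `threshold`, `gain` (SSE reduction) and
#'   `n_left`.
#' @export
best_split <- function(X, y, rows = seq_len(nrow(X)), minbucket = 1) {
  mb <- as.integer(ceiling(minbucket))
  n <- length(rows)
  if (n < 2L * mb || n < 2L) return(NULL)
  yv <- y[rows]
  sse_p <- sum((yv - mean(yv))^2)
  if (sse_p <= 0) return(NULL)
  best <- NULL
  bg <- 0
  i <- seq_len(n - 1L)
  for (j in seq_len(ncol(X))) {
    x <- X[rows, j]
    o <- order(x)
    xs <- x[o]
    if (xs[1L] == xs[n]) next
    ys <- yv[o]
    cs <- cumsum(ys)
    cs2 <- cumsum(ys * ys)
    sseL <- cs2[i] - cs[i]^2 / i
    sseR <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
    gain <- sse_p - sseL - sseR
    gain[i < mb | (n - i) < mb | xs[i] == xs[i + 1L]] <- -Inf
    k <- which.max(gain)
    if (is.finite(gain[k]) && gain[k] > bg + 1e-12 * max(1, bg)) {
      bg <- gain[k]
      best <- list(column = colnames(X)[j], col_index = j,
                   threshold = (xs[k] + xs[k + 1L]) / 2,
                   gain = gain[k], n_left = k)
    }
  }
  best
}

node_stats <- function(y, rows) {
  m <- mean(y[rows])
  list(n = length(rows), mean = m, sse = sum((y[rows] - m)^2))
}

#' Grow the redundancy-sized regression tree
#'
#' Recursive binary splitting by [best_split()] until no legal split
#' remains or the relative SSE improvement of the best split falls below
#' `cp` (as a fraction of the root SSE, the `rpart` convention).  When
#' `ceiling(minbucket) >= n` the root cannot split and the tree is a
#' single cluster -- the intended behaviour for small data sets.
#'
#' @param design a `design_matrix` (see [build_design_matrix()]), or a
#'   list with elements `x` and `y`.
#' @param minbucket minimum terminal cluster size, usually
#'   `sizing_params(...)$minbucket`.
#' @param cp complexity parameter; a split must reduce the SSE by at
#'   least `cp * SSE(root)`.
#' @return An object of class `redundancy_tree`: `nodes` (list keyed by
#'   node id: internal nodes carry `column`, `threshold`, `gain`; leaves
#'   carry `cluster`), plus `minbucket`, `cp`, `n`, `root_sse`.  Node ids
#'   follow the binary heap convention (children of `k` are `2k`,
#'   `2k + 1`).
#' @export
grow_tree <- function(design, minbucket, cp = 0.01) {
  X <- design$x
  y <- design$y
  if (is.null(X) || nrow(X) == 0L) stop("empty design matrix")
  if (length(y) != nrow(X)) stop("response length does not match design")
  mb <- as.integer(ceiling(minbucket))
  root <- node_stats(y, seq_len(nrow(X)))
  nodes <- new.env(parent = emptyenv())
  build <- function(rows, id) {
    st <- node_stats(y, rows)
    s <- if (root$sse > 0) best_split(X, y, rows, mb) else NULL
    if (!is.null(s) && s$gain >= cp * root$sse) {
      nd <- c(st, list(id = id, leaf = FALSE, column = s$column,
                       threshold = s$threshold, gain = s$gain))
      assign(as.character(id), nd, envir = nodes)
      go_left <- X[rows, s$column] < s$threshold
      build(rows[go_left], 2L * id)
      build(rows[!go_left], 2L * id + 1L)
    } else {
      assign(as.character(id),
             c(st, list(id = id, leaf = TRUE)), envir = nodes)
    }
    invisible(NULL)
  }
  build(seq_len(nrow(X)), 1L)
  tree <- structure(list(
    nodes = as.list(nodes), minbucket = minbucket, cp = cp,
    n = nrow(X), root_sse = root$sse), class = "redundancy_tree")
  relabel_clusters(tree)
}

# Assign cluster ids 1..K to leaves in increasing node-id order and store
# sample proportions.
relabel_clusters <- function(tree) {
  ids <- sort(as.integer(names(tree$nodes)))
  k <- 0L
  for (id in ids) {
    key <- as.character(id)
    nd <- tree$nodes[[key]]
    if (nd$leaf) {
      k <- k + 1L
      nd$cluster <- k
      nd$proportion <- nd$n / tree$n
      tree$nodes[[key]] <- nd
    } else {
      tree$nodes[[key]]$cluster <- NULL
    }
  }
  tree$n_leaves <- k
  tree
}

tree_node <- function(tree, id) tree$nodes[[as.character(id)]]

tree_leaf_ids <- function(tree) {
  ids <- sort(as.integer(names(tree$nodes)))
  ids[vapply(as.character(ids), function(k) tree$nodes[[k]]$leaf, logical(1L))]
}

#' Route rows to leaf clusters
#'
#' Deterministic descent: at each internal node rows with
#' `value < threshold` go left, others (including exact ties) go right.
#'
#' @param tree a `redundancy_tree`.
#' @param X numeric matrix (or single named row) containing every split
#'   column.
#' @return Integer vector of cluster ids (leaf numbering of the tree).
#' @export
assign_cluster <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  used <- tree_split_columns(tree)
  miss <- setdiff(used, colnames(X))
  if (length(miss) > 0L)
    stop("rows lack split columns: ", paste(miss, collapse = ", "))
  node <- rep(1L, nrow(X))
  repeat {
    open <- which(vapply(as.character(node), function(k)
      !tree$nodes[[k]]$leaf, logical(1L)))
    if (length(open) == 0L) break
    for (id in unique(node[open])) {
      nd <- tree_node(tree, id)
      at <- open[node[open] == id]
      left <- X[at, nd$column] < nd$threshold
      node[at] <- ifelse(left, 2L * id, 2L * id + 1L)
    }
  }
  vapply(as.character(node), function(k) tree$nodes[[k]]$cluster, integer(1L),
         USE.NAMES = FALSE)
}

tree_split_columns <- function(tree) {
  unique(unlist(lapply(tree$nodes, function(nd)
    if (!nd$leaf) nd$column else NULL)))
}

# mean-activity prediction of the tree alone (used for pruning CV)
predict_tree_mean <- function(tree, X) {
  cl <- assign_cluster(tree, X)
  means <- vapply(tree_leaf_ids(tree), function(id)
    tree_node(tree, id)$mean, numeric(1L))
  means[cl]
}

# Weakest-link g(t) for every internal node, normalized by the root SSE.
internal_g <- function(tree) {
  leaf_below <- function(id) {
    nd <- tree_node(tree, id)
    if (nd$leaf) return(c(sse = nd$sse, k = 1))
    l <- leaf_below(2L * id)
    r <- leaf_below(2L * id + 1L)
    c(sse = l[["sse"]] + r[["sse"]], k = l[["k"]] + r[["k"]])
  }
  ids <- sort(as.integer(names(tree$nodes)))
  ids <- ids[!vapply(as.character(ids), function(k) tree$nodes[[k]]$leaf,
                     logical(1L))]
  if (length(ids) == 0L) return(numeric(0))
  g <- vapply(ids, function(id) {
    nd <- tree_node(tree, id)
    lb <- leaf_below(id)
    (nd$sse - lb[["sse"]]) / (lb[["k"]] - 1) / tree$root_sse
  }, numeric(1L))
  names(g) <- as.character(ids)
  g
}

collapse_node <- function(tree, id) {
  drop <- function(k) {
    if (!is.null(tree$nodes[[as.character(k)]])) {
      tree$nodes[[as.character(k)]] <<- NULL
      drop(2L * k); drop(2L * k + 1L)
    }
  }
  drop(2L * id)
  drop(2L * id + 1L)
  nd <- tree_node(tree, id)
  nd$leaf <- TRUE
  nd$column <- NULL; nd$threshold <- NULL; nd$gain <- NULL
  tree$nodes[[as.character(id)]] <- nd
  tree
}

# Prune the tree to complexity cp_val: iteratively collapse weakest links
# with g <= cp_val.
prune_at <- function(tree, cp_val) {
  repeat {
    g <- internal_g(tree)
    if (length(g) == 0L) break
    mn <- min(g)
    if (mn > cp_val * (1 + 1e-9) + 1e-15) break
    for (id in as.integer(names(g)[g <= mn * (1 + 1e-9) + 1e-15])) {
      if (!is.null(tree$nodes[[as.character(id)]]) &&
          !tree_node(tree, id)$leaf)
        tree <- collapse_node(tree, id)
    }
  }
  relabel_clusters(tree)
}

# alpha sequence of the nested cost-complexity subtrees (ascending)
cp_sequence <- function(tree) {
  alphas <- numeric(0)
  t <- tree
  repeat {
    g <- internal_g(t)
    if (length(g) == 0L) break
    a <- min(g)
    alphas <- c(alphas, a)
    t <- prune_at(t, a)
  }
  alphas
}

#' Cross-validated cost-complexity pruning
#'
#' Builds the nested weakest-link subtree sequence of the grown tree,
#' evaluates each candidate complexity by seeded k-fold cross-validation
#' (re-growing the tree on each training fold and scoring held-out SSE of
#' the leaf-mean prediction), and prunes the full tree at the complexity
#' with the minimum cross-validated error.  Error ties are resolved
#' toward the smaller tree.
#'
#' @param tree a `redundancy_tree` from [grow_tree()].
#' @param design the `design_matrix` the tree was grown on.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold assignment; results are
#'   deterministic given the seed.
#' @return The pruned `redundancy_tree`, with the cross-validation table
#'   attached as attribute `cv`.
#' @export
cv_prune <- function(tree, design, n_folds = 10, seed = NULL) {
  alphas <- cp_sequence(tree)
  if (length(alphas) == 0L) return(tree)
  # representative cp inside each interval of constant subtree
  reps <- c(alphas[1L] / 2,
            if (length(alphas) > 1L)
              sqrt(alphas[-length(alphas)] * alphas[-1L]),
            alphas[length(alphas)] * 2)
  n <- tree$n
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  err <- numeric(length(reps))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    if (length(tr) < 2L || length(te) == 0L) next
    dtr <- subset_design(design, tr)
    ft <- grow_tree(dtr, tree$minbucket, tree$cp)
    for (k in seq_along(reps)) {
      pt <- prune_at(ft, reps[k])
      pred <- predict_tree_mean(pt, design$x[te, , drop = FALSE])
      err[k] <- err[k] + sum((design$y[te] - pred)^2)
    }
  }
  pick <- which(err <= min(err) + 1e-12 * max(1, min(err)))
  chosen <- reps[max(pick)]
  out <- prune_at(tree, chosen)
  attr(out, "cv") <- data.frame(cp = reps, cv_sse = err,
                                chosen = seq_along(reps) == max(pick))
  out
}

#' @export
print.redundancy_tree <- function(x, ...) {
  cat(sprintf("redundancy tree: n = %d, minbucket = %.2f (%d enforced), %d cluster(s)\n",
              x$n, x$minbucket, ceiling(x$minbucket), x$n_leaves))
  show <- function(id, depth) {
    nd <- tree_node(x, id)
    pad <- strrep("  ", depth)
    if (nd$leaf) {
      cat(sprintf("%s* cluster %d: n = %d (%.1f%%), mean activity = %.3f\n",
                  pad, nd$cluster, nd$n, 100 * nd$proportion, nd$mean))
    } else {
      cat(sprintf("%s%s < %.4g ? (n = %d)\n", pad, nd$column, nd$threshold, nd$n))
      show(2L * id, depth + 1L)
      show(2L * id + 1L, depth + 1L)
    }
  }
  show(1L, 0L)
  invisible(x)
}

#' Render the tree as a Graphviz DOT string
#' @param tree a `redundancy_tree`.
#' @return Character scalar in DOT syntax.
#' @export
tree_to_dot <- function(tree) {
  lines <- c("digraph redundancy_tree {", "  node [shape=box];")
  for (id in sort(as.integer(names(tree$nodes)))) {
    nd <- tree_node(tree, id)
    lab <- if (nd$leaf)
      sprintf("cluster %d\\nmean %.3f\\n%d (%.1f%%)",
              nd$cluster, nd$mean, nd$n, 100 * nd$proportion)
    else sprintf("%s < %.4g", nd$column, nd$threshold)
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", id, lab))
    if (!nd$leaf) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", id, 2L * id),
                 sprintf("  n%d -> n%d [label=\"no\"];", id, 2L * id + 1L))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

tree_to_list <- function(tree) {
  list(nodes = lapply(tree$nodes, function(nd) nd[!vapply(nd, is.null, logical(1L))]),
       minbucket = tree$minbucket, cp = tree$cp, n = tree$n,
       root_sse = tree$root_sse, n_leaves = tree$n_leaves)
}

tree_from_list <- function(lst) {
  nodes <- lapply(lst$nodes, function(nd) {
    nd$leaf <- isTRUE(nd$leaf)
    nd$id <- as.integer(nd$id)
    if (nd$leaf) nd$cluster <- as.integer(nd$cluster)
    nd
  })
  structure(list(nodes = nodes, minbucket = lst$minbucket, cp = lst$cp,
                 n = as.integer(lst$n), root_sse = lst$root_sse,
                 n_leaves = as.integer(lst$n_leaves)),
            class = "redundancy_tree")
}
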