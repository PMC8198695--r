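#' Random-forest false-positive filter
#'
#' A compact CART/bagging random forest implemented in-package (no
#' random-forest package ships with this stack): 100 trees grown to
#' purity on bootstrap samples, Gini impurity as the split criterion,
#' minimum node size 2 for splitting, `floor(sqrt(p))` features tried
#' per node. Probabilities are the fraction of trees voting positive
#' (each leaf votes its majority class). Deterministic under `seed`.
#'
#' @name rf_filter
NULL

#' Stratified train/test/validation split
#'
#' Splits samples 1:1 into training and test sets, stratified by label,
#' then holds out 30% of the training set as a validation set.
#' Deterministic under `seed`.
#'
#' @param labels factor or 0/1 vector, one per sample
#' @param seed RNG seed
#' @param train_frac fraction to the training side (default 0.5)
#' @param val_frac fraction of the training side held out (default 0.3)
#' @return list of integer index vectors `train`, `validation`, `test`
#' @export
split_data <- function(labels, seed = 1L, train_frac = 0.5, val_frac = 0.3) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  set.seed(seed)
  train <- integer(); test <- integer()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- sample(idx)
    ntr <- round(length(idx) * train_frac)
    train <- c(train, idx[seq_len(ntr)])
    test <- c(test, idx[-seq_len(ntr)])
  }
  train <- sample(train)
  nval <- round(length(train) * val_frac)
  list(train = sort(train[-seq_len(nval)]),
       validation = sort(train[seq_len(nval)]),
       test = sort(test))
}

# Best Gini split for one feature at one node (vectorized threshold scan).
# Returns c(gain_proxy, threshold) or NULL. The proxy maximized is the
# weighted decrease in sum over children of n_k * gini_k.
best_split_feature <- function(xv, y01) {
  o <- order(xv)
  xs <- xv[o]; ys <- y01[o]
  n <- length(xs)
  cut_ok <- which(xs[-n] < xs[-1])  # split between distinct values only
  if (length(cut_ok) == 0) return(NULL)
  cp <- cumsum(ys)
  nl <- cut_ok
  pl <- cp[cut_ok]
  nr <- n - nl
  pr <- cp[n] - pl
  # child impurity mass: n_k * gini_k = 2 * pos_k * neg_k / n_k
  mass <- 2 * pl * (nl - pl) / nl + 2 * pr * (nr - pr) / nr
  k <- which.min(mass)
  parent <- 2 * cp[n] * (n - cp[n]) / n
  gain <- parent - mass[k]
  if (gain <= 1e-12) return(NULL)
  c(gain = gain, threshold = (xs[cut_ok[k]] + xs[cut_ok[k] + 1L]) / 2)
}

grow_tree <- function(x, y01, mtry, min_split, max_depth = 30L) {
  p <- ncol(x)
  build <- function(idx, depth) {
    n <- length(idx)
    pos <- sum(y01[idx])
    if (pos == 0 || pos == n || n < min_split || depth >= max_depth) {
      return(list(leaf = TRUE, vote = as.integer(pos * 2 > n),
                  prob = pos / n))
    }
    feats <- sample.int(p, mtry)
    best <- NULL; bvar <- NA_integer_
    for (j in feats) {
      s <- best_split_feature(x[idx, j], y01[idx])
      if (!is.null(s) && (is.null(best) || s["gain"] > best["gain"])) {
        best <- s; bvar <- j
      }
    }
    if (is.null(best)) {
      return(list(leaf = TRUE, vote = as.integer(pos * 2 > n),
                  prob = pos / n))
    }
    go_left <- x[idx, bvar] <= best["threshold"]
    list(leaf = FALSE, var = bvar, threshold = unname(best["threshold"]),
         left = build(idx[go_left], depth + 1L),
         right = build(idx[!go_left], depth + 1L))
  }
  build(seq_len(nrow(x)), 0L)
}

#' Train the random-forest classifier
#'
#' @param x numeric feature matrix (rows = samples); column names become
#'   the model schema and must match at prediction time
#' @param labels 0/1 or logical/factor vector (positive = 1 / TRUE /
#'   second level)
#' @param n_trees number of trees (default 100)
#' @param mtry features tried per split (default `floor(sqrt(p))`)
#' @param min_split minimum node size to attempt a split (default 2)
#' @param seed training seed (stored in the model)
#' @return an `rf_model` object
#' @export
rf_train <- function(x, labels, n_trees = 100L, mtry = NULL, min_split = 2L,
                     seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("non-finite feature values")
  y01 <- to_binary(labels)
  if (length(unique(y01)) < 2) stop("both classes required for training")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  n <- nrow(x)
  trees <- lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(n, n, replace = TRUE)
    grow_tree(x[boot, , drop = FALSE], y01[boot], mtry, min_split)
  })
  structure(list(trees = trees, schema = colnames(x),
                 n_trees = n_trees, mtry = mtry, min_split = min_split,
                 seed = seed),
            class = "rf_model")
}

to_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2]))
  as.integer(labels != 0)
}

tree_route <- function(node, x, idx, out) {
  if (node$leaf) { out[idx] <- node$vote; return(out) }
  go_left <- x[idx, node$var] <= node$threshold
  out <- tree_route(node$left, x, idx[go_left], out)
  tree_route(node$right, x, idx[!go_left], out)
}

#' Predict positive-class probability
#'
#' The probability is the fraction of trees whose leaf votes positive.
#'
#' @param model an `rf_model`
#' @param x feature matrix with the training schema's columns
#' @return numeric vector in `[0, 1]`, one per row of `x`
#' @export
rf_predict_proba <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == length(model$schema)) {
    colnames(x) <- model$schema
  }
  missing <- setdiff(model$schema, colnames(x))
  extra <- setdiff(colnames(x), model$schema)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  }
  x <- x[, model$schema, drop = FALSE]
  n <- nrow(x)
  votes <- numeric(n)
  for (tree in model$trees) {
    votes <- votes + tree_route(tree, x, seq_len(n), numeric(n))
  }
  votes / model$n_trees
}

#' ROC curve and AUC
#'
#' AUC is computed with the Mann-Whitney rank statistic (probability
#' that a random positive scores above a random negative, ties counted
#' half); the returned ROC points integrate to the same value by the
#' trapezoid rule.
#'
#' @param scores numeric classifier scores
#' @param labels 0/1 (or logical/factor) truth
#' @return list with `auc`, `auc_trapezoid`, and a data.frame `roc` of
#'   (fpr, tpr) points
#' @export
evaluate_roc <- function(scores, labels) {
  y <- to_binary(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  np <- sum(y == 1); nn <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / nn, numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc_trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                   utils::tail(roc$tpr, -1)) / 2)
  list(auc = auc, auc_trapezoid = auc_trap, roc = roc)
}

#' Persist / restore a model with its schema sidecar
#'
#' The model is serialized with [saveRDS()]; a JSON sidecar records the
#' schema, parameters and training seed so schema mismatches are caught
#' across sessions.
#'
#' @param model an `rf_model`
#' @param path model file (sidecar written to `<path>.json`)
#' @export
rf_save <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(schema = model$schema, n_trees = model$n_trees,
                            mtry = model$mtry, min_split = model$min_split,
                            seed = model$seed,
                            r_version = as.character(getRversion())),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rf_save
#' @return `rf_load`: the restored `rf_model`
#' @export
rf_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rf_model"))
  model
}
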