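# Weighted binary classification tree with best-first growth and a cap on
# the total number of splits (the natural parameterization for "max number
# of splits" ensembles). Implemented natively: no tree package is available
# at runtime, and the boosting/bagging layers need weighted fitting and a
# split-count cap. Features are numeric; missing values are imputed before
# fitting (see train_ensemble).

# Best weighted-Gini split of rows `idx` of X.  Returns NULL if no split
# reduces impurity. `mtry` optionally subsamples candidate features.
best_split <- function(X, y01, w, idx, mtry = NULL, min_leaf = 1L) {
  p <- ncol(X)
  feats <- seq_len(p)
  if (!is.null(mtry) && mtry < p) feats <- sort(sample.int(p, mtry))
  wt <- w[idx]
  wy <- wt * y01[idx]
  W <- sum(wt); WY <- sum(wy)
  if (W <= 0) return(NULL)
  parent_gini <- 2 * (WY / W) * (1 - WY / W) * W
  best <- NULL; best_gain <- 1e-12
  for (j in feats) {
    xj <- X[idx, j]
    o <- order(xj)
    xs <- xj[o]
    cw <- cumsum(wt[o]); cy <- cumsum(wy[o])
    n <- length(xs)
    if (n < 2L * min_leaf) next
    cut_ok <- which(diff(xs) > 1e-12)
    cut_ok <- cut_ok[cut_ok >= min_leaf & cut_ok <= n - min_leaf]
    if (!length(cut_ok)) next
    wl <- cw[cut_ok]; yl <- cy[cut_ok]
    wr <- W - wl; yr <- WY - yl
    gini <- 2 * yl * (1 - yl / pmax(wl, 1e-300)) +
      2 * yr * (1 - yr / pmax(wr, 1e-300))
    gain <- parent_gini - gini
    k <- which.max(gain)
    if (gain[k] > best_gain) {
      best_gain <- gain[k]
      thr <- (xs[cut_ok[k]] + xs[cut_ok[k] + 1L]) / 2
      best <- list(feature = j, threshold = thr, gain = gain[k])
    }
  }
  best
}

#' Fit a depth-limited classification tree
#'
#' Greedy best-first growth: at each step the pending leaf whose best split
#' yields the largest weighted-Gini decrease is split, until `max_splits`
#' internal nodes exist or no split improves. Leaves store the weighted
#' positive-class fraction.
#'
#' @param X numeric matrix (rows = samples).
#' @param y integer/numeric labels coded -1/+1 (or 0/1).
#' @param w sample weights (default uniform).
#' @param max_splits maximum number of internal splits.
#' @param mtry features sampled per split (`NULL` = all; used by the
#'   random forest).
#' @param min_leaf minimum samples per leaf.
#' @return list of class `oculo_tree` with a node table.
#' @keywords internal
fit_tree <- function(X, y, w = NULL, max_splits = 5L, mtry = NULL,
                     min_leaf = 1L) {
  n <- nrow(X)
  y01 <- as.numeric(y > 0)
  if (is.null(w)) w <- rep(1 / n, n)
  # node table columns: feature (NA = leaf), threshold, left, right, prob
  nodes <- list(list(feature = NA_integer_, threshold = NA_real_,
                     left = NA_integer_, right = NA_integer_,
                     prob = sum(w * y01) / sum(w)))
  members <- list(seq_len(n))
  pending <- list()  # per-leaf precomputed best split (may hold NULL)
  pending[1] <- list(best_split(X, y01, w, members[[1]], mtry, min_leaf))
  n_splits <- 0L
  while (n_splits < max_splits) {
    gains <- vapply(seq_along(nodes), function(i) {
      if (!is.na(nodes[[i]]$feature)) return(-Inf)
      s <- if (i <= length(pending)) pending[[i]] else NULL
      if (is.null(s)) -Inf else s$gain
    }, 0)
    i <- which.max(gains)
    if (!is.finite(gains[i])) break
    s <- pending[[i]]
    idx <- members[[i]]
    go_left <- X[idx, s$feature] <= s$threshold
    li <- length(nodes) + 1L; ri <- length(nodes) + 2L
    for (child in list(list(id = li, rows = idx[go_left]),
                       list(id = ri, rows = idx[!go_left]))) {
      wr <- w[child$rows]
      nodes[[child$id]] <- list(feature = NA_integer_,
                                threshold = NA_real_,
                                left = NA_integer_, right = NA_integer_,
                                prob = sum(wr * y01[child$rows]) /
                                  max(sum(wr), 1e-300))
      members[[child$id]] <- child$rows
      pending[child$id] <- list(best_split(X, y01, w, child$rows, mtry,
                                           min_leaf))
    }
    nodes[[i]]$feature <- s$feature
    nodes[[i]]$threshold <- s$threshold
    nodes[[i]]$left <- li; nodes[[i]]$right <- ri
    n_splits <- n_splits + 1L
  }
  tab <- data.frame(
    feature = vapply(nodes, function(x) as.integer(x$feature %||% NA), 1L),
    threshold = vapply(nodes, function(x) as.numeric(x$threshold), 1),
    left = vapply(nodes, function(x) as.integer(x$left %||% NA), 1L),
    right = vapply(nodes, function(x) as.integer(x$right %||% NA), 1L),
    prob = vapply(nodes, function(x) as.numeric(x$prob), 1))
  structure(list(nodes = tab, n_splits = n_splits), class = "oculo_tree")
}

# Positive-class probability per row.
predict_tree <- function(tree, X) {
  tab <- tree$nodes
  n <- nrow(X)
  node <- rep(1L, n)
  repeat {
    at_internal <- !is.na(tab$feature[node])
    if (!any(at_internal)) break
    i <- which(at_internal)
    f <- tab$feature[node[i]]
    thr <- tab$threshold[node[i]]
    xv <- X[cbind(i, f)]
    node[i] <- ifelse(xv <= thr, tab$left[node[i]], tab$right[node[i]])
  }
  tab$prob[node]
}
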