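# Fatigue classification: KSS dichotomization, confusion/Youden metrics,
# the pluggable classifier contract (native robust-boosted decision-tree
# ensemble, exponential-loss boosting baseline, random forest, single tree,
# nearest-centroid), leave-one-person-out evaluation, SFFS feature
# selection, and the permutation test against chance.

#' Dichotomize KSS ratings into fatigued/alert
#'
#' A segment is fatigued iff its KSS rating is at least `threshold`
#' (default 5, "neither alert nor sleepy").
#'
#' @param kss integer vector, values in `[1, 10]` (`NA` allowed).
#' @param threshold dichotomization threshold.
#' @return factor with levels `alert`, `fatigued`.
#' @export
dichotomize_kss <- function(kss, threshold = 5L) {
  check_kss(kss)
  factor(ifelse(kss >= threshold, "fatigued", "alert"),
         levels = c("alert", "fatigued"))
}

#' Confusion-matrix counts
#'
#' @param tp,tn,fp,fn non-negative counts; positive class = fatigued.
#' @return list of class `confusion` with derived `tpr`, `tnr`, `acc`.
#' @export
confusion <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) abort("counts must be >= 0",
                                        "validation_error")
  p <- tp + fn; n <- tn + fp
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, P = p, N = n,
                 tpr = if (p > 0) tp / p else NA_real_,
                 tnr = if (n > 0) tn / n else NA_real_,
                 acc = if (p + n > 0) (tp + tn) / (p + n) else NA_real_),
            class = "confusion")
}

#' Youden's J statistic
#'
#' `J = TPR + TNR - 1`, in `[-1, 1]`; requires at least one instance of
#' each class.
#'
#' @param c a [confusion()].
#' @return numeric scalar.
#' @export
youden_index <- function(c) {
  if (c$P == 0 || c$N == 0)
    abort("Youden's J undefined: a class has no instances", "metric_error")
  c$tpr + c$tnr - 1
}

#' Classifier specification
#'
#' Pluggable classifier contract. The native deployment classifier is
#' `dt_ensemble`: 50 boosting rounds of depth-limited trees (at most 5
#' splits each) with a label-noise-robust margin-weighted update
#' (`method = "robust_boost"`, see vignette) parameterized by
#' `error_goal` and `max_margin`; `method = "exp_boost"` selects the
#' exponential-loss (AdaBoost-style) baseline with identical trees.
#' `random_forest` (bagged trees, feature subsampling) is the SFFS base
#' learner; `single_tree` and `centroid` are light adapters used for fast
#' simulation studies.
#'
#' @param kind one of `dt_ensemble`, `random_forest`, `single_tree`,
#'   `centroid`.
#' @param ... hyperparameter overrides, validated per kind.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("dt_ensemble", "random_forest",
                                     "single_tree", "centroid"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    dt_ensemble = list(max_splits = 5L, n_learners = 50L,
                       method = "robust_boost", error_goal = 0.25,
                       max_margin = 1),
    random_forest = list(max_splits = 5L, n_trees = 51L, mtry = NULL),
    single_tree = list(max_splits = 5L),
    centroid = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown hyperparameter(s) for %s: %s", kind,
                  paste(unknown, collapse = ", ")), "validation_error")
  hp <- modifyList(defaults, over)
  if (kind == "dt_ensemble") {
    if (!hp$method %in% c("robust_boost", "exp_boost"))
      abort("method must be robust_boost or exp_boost", "validation_error")
    if (hp$error_goal <= 0 || hp$error_goal >= 0.5)
      abort("error_goal must lie in (0, 0.5)", "validation_error")
    if (hp$max_margin <= 0)
      abort("max_margin must be positive", "validation_error")
  }
  structure(c(list(kind = kind), hp), class = "classifier_spec")
}

# ---- feature matrix preparation -------------------------------------------

model_feature_pool <- function() c(OCULOMETRIC_FEATURES, "age", "sex")

# numeric matrix (sex encoded F=0, M=1); NAs preserved for imputation
prepare_X <- function(df, features) {
  X <- matrix(NA_real_, nrow(df), length(features),
              dimnames = list(NULL, features))
  for (f in features) {
    v <- df[[f]]
    if (is.null(v)) abort(sprintf("missing feature column: %s", f),
                          "validation_error")
    if (f == "sex") v <- ifelse(v == "M", 1, ifelse(v == "F", 0, NA))
    X[, f] <- as.numeric(v)
  }
  X
}

impute_fit <- function(X) {
  med <- apply(X, 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

impute_apply <- function(X, med) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  X
}

labels_to_y <- function(label) ifelse(label == "fatigued", 1, -1)

# ---- classifier fitting ----------------------------------------------------

fit_core <- function(spec, X, y, seed = 1L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  switch(spec$kind,
    dt_ensemble = fit_boost(X, y, spec),
    random_forest = fit_forest(X, y, spec),
    single_tree = list(kind = "single_tree",
                       tree = fit_tree(X, y, max_splits = spec$max_splits)),
    centroid = fit_centroid(X, y))
}

# Boost-by-majority-style robust boosting: per-round sample weights are a
# Gaussian in the normalized margin, centered on a target margin that ramps
# from 0 to max_margin and with a width narrowing toward
# max_margin / qnorm(1 - error_goal). Examples far below the margin target
# (likely label noise) and examples already beyond it both receive little
# weight; exp_boost instead weights by exp(-margin) (AdaBoost).
fit_boost <- function(X, y, spec) {
  n <- nrow(X)
  T <- spec$n_learners
  trees <- vector("list", T)
  alphas <- numeric(T)
  Fx <- numeric(n)
  A <- 0
  sigma_end <- spec$max_margin / qnorm(1 - spec$error_goal)
  sigma_start <- 2
  used <- 0L
  for (k in seq_len(T)) {
    if (spec$method == "robust_boost") {
      t <- (k - 1) / T
      mu <- spec$max_margin * t
      sig <- sigma_start + (sigma_end - sigma_start) * t
      m <- if (A > 0) y * Fx / A else numeric(n)
      w <- exp(-(m - mu)^2 / (2 * sig^2))
    } else {
      w <- exp(pmin(-y * Fx, 30))
    }
    w <- w / sum(w)
    tree <- fit_tree(X, y, w, max_splits = spec$max_splits)
    h <- ifelse(predict_tree(tree, X) >= 0.5, 1, -1)
    err <- sum(w[h != y])
    if (err >= 0.5) break
    alpha <- min(0.5 * log((1 - max(err, 1e-8)) / max(err, 1e-8)), 4)
    used <- used + 1L
    trees[[used]] <- tree
    alphas[used] <- alpha
    Fx <- Fx + alpha * h
    A <- A + alpha
  }
  if (used == 0L) {  # degenerate: constant classifier at the base rate
    trees[[1]] <- fit_tree(X, y, max_splits = 0L)
    alphas[1] <- 1
    used <- 1L
  }
  list(kind = "dt_ensemble", trees = trees[seq_len(used)],
       alphas = alphas[seq_len(used)])
}

fit_forest <- function(X, y, spec) {
  n <- nrow(X)
  mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(X))))
  trees <- lapply(seq_len(spec$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_tree(X[idx, , drop = FALSE], y[idx], max_splits = spec$max_splits,
             mtry = mtry)
  })
  list(kind = "random_forest", trees = trees)
}

fit_centroid <- function(X, y) {
  mu <- apply(X, 2, mean)
  s <- apply(X, 2, sd); s[s < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, s, `/`)
  list(kind = "centroid", mu = mu, s = s,
       c_pos = colMeans(Z[y > 0, , drop = FALSE]),
       c_neg = colMeans(Z[y < 0, , drop = FALSE]))
}

# posterior P(fatigued) in [0, 1]
posterior_core <- function(core, X) {
  switch(core$kind,
    dt_ensemble = {
      A <- sum(core$alphas)
      Fx <- numeric(nrow(X))
      for (i in seq_along(core$trees)) {
        h <- ifelse(predict_tree(core$trees[[i]], X) >= 0.5, 1, -1)
        Fx <- Fx + core$alphas[i] * h
      }
      pmin(pmax((Fx / A + 1) / 2, 0), 1)
    },
    random_forest = {
      probs <- vapply(core$trees, function(tr) predict_tree(tr, X),
                      numeric(nrow(X)))
      if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
      rowMeans(probs)
    },
    single_tree = predict_tree(core$tree, X),
    centroid = {
      Z <- sweep(sweep(X, 2, core$mu), 2, core$s, `/`)
      dp <- sqrt(rowSums(sweep(Z, 2, core$c_pos)^2))
      dn <- sqrt(rowSums(sweep(Z, 2, core$c_neg)^2))
      1 / (1 + exp(dp - dn))
    })
}

#' Train the deployed decision-tree ensemble
#'
#' Fits the `dt_ensemble` classifier on a labeled dataset. Missing feature
#' values are imputed by per-feature medians computed on the training data
#' and stored in the model; training is deterministic given `seed`.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [classifier_spec()] of kind `dt_ensemble`.
#' @param features feature subset (default: the five deployed features
#'   BF, PERCLOS, SF, SVA, PDIR).
#' @param seed integer RNG seed.
#' @param threshold posterior decision threshold (ties classify as
#'   fatigued).
#' @return object of class `fatigue_model`.
#' @export
train_ensemble <- function(dataset, spec = classifier_spec("dt_ensemble"),
                           features = c("BF", "PERCLOS", "SF", "SVA",
                                        "PDIR"),
                           seed = 1L, threshold = 0.5) {
  if (length(unique(dataset$label)) < 2L)
    abort("training data must contain both classes", "validation_error")
  X <- prepare_X(dataset, features)
  med <- impute_fit(X)
  X <- impute_apply(X, med)
  y <- labels_to_y(dataset$label)
  core <- fit_core(spec, X, y, seed)
  structure(list(spec = spec, core = core, features = features,
                 impute = med, threshold = threshold, seed = seed),
            class = "fatigue_model")
}

#' Classify one segment
#'
#' Pure function of the model and a feature vector: missing features are
#' imputed with the model's stored training medians; the label is fatigued
#' iff the posterior is at least the model threshold (tie goes to
#' fatigued: in a fatigue-safety setting a spurious break beats a missed
#' detection).
#'
#' @param model a [train_ensemble()] result (or any `fatigue_model`).
#' @param features a `segment_features`, named list, or one-row data.frame
#'   containing the model's feature columns.
#' @return list with `label` (factor) and `posterior`.
#' @export
predict_segment <- function(model, features) {
  if (inherits(features, "segment_features")) features <- unclass(features)
  if (is.list(features) && !is.data.frame(features)) {
    missing_f <- setdiff(model$features, names(features))
    if (length(missing_f))
      abort(sprintf("feature vector missing: %s",
                    paste(missing_f, collapse = ", ")), "validation_error")
    features <- as.data.frame(
      lapply(features[model$features],
             function(v) if (is.null(v)) NA_real_ else v),
      optional = TRUE)
    names(features) <- model$features
  }
  X <- impute_apply(prepare_X(features, model$features), model$impute)
  post <- posterior_core(model$core, X)
  list(label = factor(ifelse(post >= model$threshold, "fatigued", "alert"),
                      levels = c("alert", "fatigued")),
       posterior = post)
}

#' Leave-one-person-out cross-validation
#'
#' One fold per participant: the classifier (and the median imputation) is
#' fitted on all other participants and scored on the held-out one, so no
#' test-participant statistic ever leaks into training. Folds whose
#' training data lack a class are skipped with a warning. Reports per-fold
#' confusions, across-fold mean TPR/TNR/ACC, pooled-count metrics, and an
#' ROC traced by sweeping the posterior threshold over `[0, 1]` and
#' averaging per-fold rates.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param features feature subset used by the classifier.
#' @param threshold posterior decision threshold for the confusions.
#' @param seed integer seed (refitting is per fold, seeded).
#' @return object of class `cv_result`.
#' @export
lopo_evaluate <- function(dataset, spec = classifier_spec("dt_ensemble"),
                          features = c("BF", "PERCLOS", "SF", "SVA",
                                       "PDIR"),
                          threshold = 0.5, seed = 1L) {
  ids <- unique(dataset$participant_id)
  if (length(ids) < 2L)
    abort("LOPO needs at least 2 participants", "validation_error")
  Xall <- prepare_X(dataset, features)
  yall <- labels_to_y(dataset$label)
  thr_grid <- c(seq(0, 1, by = 0.02), 1 + 1e-9)
  folds <- list()
  skipped <- character(0)
  for (pid in ids) {
    test <- dataset$participant_id == pid
    ytr <- yall[!test]
    if (length(unique(ytr)) < 2L) {
      warning(sprintf("fold %s skipped: training data single-class", pid))
      skipped <- c(skipped, as.character(pid))
      next
    }
    Xtr <- Xall[!test, , drop = FALSE]
    med <- impute_fit(Xtr)
    core <- fit_core(spec, impute_apply(Xtr, med), ytr, seed)
    Xte <- impute_apply(Xall[test, , drop = FALSE], med)
    post <- posterior_core(core, Xte)
    yte <- yall[test]
    cm <- confusion(sum(post >= threshold & yte > 0),
                    sum(post < threshold & yte < 0),
                    sum(post >= threshold & yte < 0),
                    sum(post < threshold & yte > 0))
    roc <- t(vapply(thr_grid, function(th) {
      c(tpr = if (any(yte > 0)) sum(post >= th & yte > 0) / sum(yte > 0)
          else NA_real_,
        fpr = if (any(yte < 0)) sum(post >= th & yte < 0) / sum(yte < 0)
          else NA_real_)
    }, c(tpr = 0, fpr = 0)))
    folds[[as.character(pid)]] <- list(participant = pid, confusion = cm,
                                       posterior = post, y = yte,
                                       roc = roc)
  }
  if (!length(folds))
    abort("no evaluable LOPO folds", "validation_error")
  mean_stat <- function(f) mean(vapply(folds, function(x) x$confusion[[f]],
                                       0), na.rm = TRUE)
  tp <- sum(vapply(folds, function(x) x$confusion$TP, 0))
  tn <- sum(vapply(folds, function(x) x$confusion$TN, 0))
  fp <- sum(vapply(folds, function(x) x$confusion$FP, 0))
  fn <- sum(vapply(folds, function(x) x$confusion$FN, 0))
  roc_mean <- data.frame(
    threshold = thr_grid,
    tpr = rowMeans(sapply(folds, function(x) x$roc[, "tpr"]), na.rm = TRUE),
    fpr = rowMeans(sapply(folds, function(x) x$roc[, "fpr"]), na.rm = TRUE))
  structure(list(folds = folds, skipped = skipped,
                 mean_tpr = mean_stat("tpr"), mean_tnr = mean_stat("tnr"),
                 mean_acc = mean_stat("acc"),
                 pooled = confusion(tp, tn, fp, fn),
                 roc = roc_mean,
                 youden = mean_stat("tpr") + mean_stat("tnr") - 1),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds | mean ACC %.3f TPR %.3f TNR %.3f | J %.3f\n",
    length(x$folds), x$mean_acc, x$mean_tpr, x$mean_tnr, x$youden))
  invisible(x)
}

# deterministic per-subset seed so SFFS is reproducible and cache-friendly
subset_seed <- function(seed, subset, pool) {
  idx <- sort(match(subset, pool))
  as.integer((seed + sum(idx * 1009L)) %% 2147483587L)
}

#' Sequential floating forward feature selection
#'
#' Classic SFFS under a wrapper criterion: repeated best-inclusion followed
#' by conditional worst-exclusion steps that are kept only while they
#' improve on the best subset of the smaller size. The criterion is
#' Youden's J (across-fold mean TPR + TNR - 1) from [lopo_evaluate()] with
#' `base_learner` (default: a random forest). Deterministic given
#' `dataset` and `seed`.
#'
#' @param dataset a [labeled_dataset()].
#' @param base_learner a [classifier_spec()] used inside the criterion.
#' @param max_size maximum subset size explored.
#' @param parsimony_tol the reported subset is the smallest whose
#'   criterion lies within this tolerance of the best seen (guards
#'   against noise features riding on wrapper-criterion noise).
#' @param pool candidate features (default: the 32 oculometrics + age +
#'   sex).
#' @param seed integer seed.
#' @return list: `subset` (best subset found), `size_best` (best subset per
#'   size), `trace` (data.frame of evaluated subsets and criteria).
#' @export
sffs_select <- function(dataset,
                        base_learner = classifier_spec("random_forest",
                                                       n_trees = 25L),
                        max_size = 5L, pool = model_feature_pool(),
                        parsimony_tol = 0.05, seed = 1L) {
  pool <- pool[pool %in% names(dataset)]
  if (length(pool) < 2L)
    abort("need at least 2 candidate features", "validation_error")
  cache <- new.env(parent = emptyenv())
  crit <- function(subset) {
    key <- paste(sort(subset), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    j <- tryCatch(
      lopo_evaluate(dataset, base_learner, features = subset,
                    seed = subset_seed(seed, subset, pool))$youden,
      error = function(e) -Inf)
    cache[[key]] <- j
    j
  }
  best_j <- rep(-Inf, max_size)   # best criterion seen per subset size
  best_sub <- vector("list", max_size)
  selected <- character(0)
  trace <- list()
  note <- function(action, subset, j)
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action, size = length(subset),
      subset = paste(subset, collapse = "+"), criterion = j)
  while (length(selected) < max_size) {
    cands <- setdiff(pool, selected)
    if (!length(cands)) break
    js <- vapply(cands, function(f) crit(c(selected, f)), 0)
    f_add <- cands[which.max(js)]
    j_add <- max(js)
    if (length(selected) == 0L && !is.finite(j_add))
      abort("criterion not evaluable on any single feature",
            "validation_error")
    selected <- c(selected, f_add)
    k <- length(selected)
    note("add", selected, j_add)
    if (j_add > best_j[k]) {
      best_j[k] <- j_add
      best_sub[[k]] <- selected
    }
    # floating exclusion
    while (length(selected) > 2L) {
      k <- length(selected)
      js_rm <- vapply(selected, function(f) crit(setdiff(selected, f)), 0)
      f_rm <- selected[which.max(js_rm)]
      j_rm <- max(js_rm)
      if (f_rm != f_add && j_rm > best_j[k - 1L]) {
        selected <- setdiff(selected, f_rm)
        best_j[k - 1L] <- j_rm
        best_sub[[k - 1L]] <- selected
        note("remove", selected, j_rm)
      } else break
    }
  }
  sizes_ok <- which(is.finite(best_j))
  if (!length(sizes_ok)) abort("SFFS found no evaluable subset",
                               "validation_error")
  # parsimony: smallest size whose criterion is within `parsimony_tol`
  # (about the Monte Carlo noise of the wrapper criterion) of the best
  jmax <- max(best_j[sizes_ok])
  best_k <- min(sizes_ok[best_j[sizes_ok] >= jmax - parsimony_tol])
  if (max_size > 1L && best_k == 1L)
    warning("no improving inclusion beyond a single feature")
  list(subset = best_sub[[best_k]], criterion = best_j[best_k],
       size_best = best_sub, size_criterion = best_j,
       trace = do.call(rbind, trace))
}

#' Permutation test of classification accuracy against chance
#'
#' The across-fold mean LOPO accuracy of `spec` is compared with its null
#' distribution under `n_permutations` random permutations of the class
#' labels over all segments; `p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations)`.
#'
#' @param dataset a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param features feature subset.
#' @param n_permutations number of label permutations (default 100).
#' @param seed integer seed.
#' @return list: `observed` (mean LOPO ACC), `null` (numeric vector),
#'   `p_value`.
#' @export
permutation_test <- function(dataset,
                             spec = classifier_spec("dt_ensemble"),
                             features = c("BF", "PERCLOS", "SF", "SVA",
                                          "PDIR"),
                             n_permutations = 100L, seed = 1L) {
  if (n_permutations < 1L)
    abort("n_permutations must be >= 1", "validation_error")
  observed <- lopo_evaluate(dataset, spec, features = features,
                            seed = seed)$mean_acc
  null <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(as.integer((seed + 7919L * b) %% 2147483587L))
    perm <- dataset
    perm$label <- sample(perm$label)
    null[b] <- suppressWarnings(
      lopo_evaluate(perm, spec, features = features,
                    seed = seed + b)$mean_acc)
  }
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed - 1e-12)) /
         (1 + n_permutations))
}
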