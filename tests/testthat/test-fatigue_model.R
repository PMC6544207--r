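test_that("KSS dichotomization and its threshold sensitivity", {
  expect_equal(as.character(dichotomize_kss(5L)), "fatigued")
  expect_equal(as.character(dichotomize_kss(1L)), "alert")
  expect_equal(as.character(dichotomize_kss(5L, threshold = 6L)), "alert")
  expect_equal(as.character(dichotomize_kss(c(4, 5, 6))),
               c("alert", "fatigued", "fatigued"))
  expect_error(dichotomize_kss(0L), "KSS")
  expect_error(dichotomize_kss(11L), "KSS")
})

test_that("Youden's J equals TPR + TNR - 1 for every confusion", {
  expect_equal(youden_index(confusion(10, 10, 0, 0)), 1)
  # the arithmetic behind TPR 0.61 / TNR 0.70 -> J = 0.31
  expect_equal(youden_index(confusion(61, 70, 30, 39)), 0.31,
               tolerance = 1e-9)
  expect_equal(youden_index(confusion(5, 5, 5, 5)), 0)
  # exhaustive over small confusions
  for (tp in 0:4) for (fn in 0:4) for (tn in 0:4) for (fp in 0:4) {
    p <- tp + fn; n <- tn + fp
    if (p == 0 || n == 0) next
    expect_equal(youden_index(confusion(tp, tn, fp, fn)),
                 tp / p + tn / n - 1, tolerance = 1e-12)
  }
  expect_error(youden_index(confusion(0, 5, 5, 0)), "class")
  expect_error(confusion(-1, 0, 0, 0), ">= 0")
})

test_that("classifier spec validates hyperparameters per kind", {
  spec <- classifier_spec("dt_ensemble")
  expect_equal(spec$max_splits, 5L)
  expect_equal(spec$n_learners, 50L)
  expect_equal(spec$method, "robust_boost")
  expect_equal(spec$error_goal, 0.25)
  expect_equal(spec$max_margin, 1)
  expect_error(classifier_spec("dt_ensemble", bogus = 1), "unknown")
  expect_error(classifier_spec("dt_ensemble", error_goal = 0.9),
               "error_goal")
  expect_error(classifier_spec("dt_ensemble", method = "magic"), "method")
})

test_that("the ensemble separates clean data and tolerates label noise", {
  ds <- make_separable_dataset(seed = 2)
  model <- train_ensemble(ds, seed = 1)
  pred <- predict_segment(model, ds)
  expect_equal(as.character(pred$label), as.character(ds$label))

  # XOR blobs: not linearly separable, solvable by a 5-split tree chain
  set.seed(3)
  n <- 200
  cx <- sample(0:1, n, TRUE); cy <- sample(0:1, n, TRUE)
  X <- cbind(cx + rnorm(n, 0, 0.12), cy + rnorm(n, 0, 0.12))
  y <- ifelse(xor(cx == 1, cy == 1), 1, -1)
  core <- oculofatigue:::fit_core(classifier_spec("dt_ensemble"), X, y, 1)
  post <- oculofatigue:::posterior_core(core, X)
  expect_gte(mean(ifelse(post >= 0.5, 1, -1) == y), 0.95)

  # 20% symmetric label noise: the robust update degrades less than the
  # same-config exponential-loss baseline in >= 80% of seeded replicates
  wins <- 0L
  for (sd in 1:20) {
    set.seed(sd)
    mk <- function(n) {
      yy <- rep(c(1, -1), length.out = n)
      list(X = cbind(yy * 0.8 + rnorm(n, 0, 0.55),
                     yy * 0.8 + rnorm(n, 0, 0.55)), y = yy)
    }
    tr <- mk(120); te <- mk(400)
    ytr <- tr$y
    flip <- sample(120, 24)
    ytr[flip] <- -ytr[flip]
    acc <- vapply(c("robust_boost", "exp_boost"), function(m) {
      core <- oculofatigue:::fit_core(
        classifier_spec("dt_ensemble", method = m), tr$X, ytr, sd)
      mean(ifelse(oculofatigue:::posterior_core(core, te$X) >= 0.5, 1, -1)
           == te$y)
    }, 0)
    wins <- wins + (acc["robust_boost"] >= acc["exp_boost"])
  }
  expect_gte(wins, 16L)
})

test_that("predict_segment is a pure thresholded function", {
  ds <- make_separable_dataset(seed = 4)
  model <- train_ensemble(ds, seed = 1)
  feats <- as.list(ds[1, c(model$features, "age", "sex")])
  p1 <- predict_segment(model, feats)
  p2 <- predict_segment(model, feats)
  expect_identical(p1, p2)
  # threshold rule with tie -> fatigued
  fake <- model
  fake$core <- list(kind = "single_tree",
                    tree = structure(list(nodes = data.frame(
                      feature = NA_integer_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_,
                      prob = 0.5)), class = "oculo_tree"))
  expect_equal(as.character(predict_segment(fake, feats)$label),
               "fatigued")
  fake$core$tree$nodes$prob <- 0.7
  expect_equal(as.character(predict_segment(fake, feats)$label),
               "fatigued")
  fake$core$tree$nodes$prob <- 0.2
  expect_equal(as.character(predict_segment(fake, feats)$label), "alert")
  # wrong schema
  expect_error(predict_segment(model, list(BF = 1)), "missing")
  # missing features fall back to training medians, not zeros
  feats_na <- feats; feats_na$PDIR <- NA_real_
  expect_s3_class(predict_segment(model, feats_na)$label, "factor")
})

test_that("LOPO evaluation: folds, metrics, ROC, and no leakage", {
  ds <- make_separable_dataset(n_participants = 4, seed = 5)
  cv <- lopo_evaluate(ds, classifier_spec("dt_ensemble"), seed = 1)
  expect_equal(length(cv$folds), 4L)
  expect_equal(cv$mean_acc, 1)
  expect_equal(cv$mean_tpr, 1)
  expect_equal(cv$mean_tnr, 1)

  # ROC endpoints and monotonicity
  roc <- cv$roc
  expect_equal(roc$tpr[1], 1); expect_equal(roc$fpr[1], 1)
  expect_equal(roc$tpr[nrow(roc)], 0); expect_equal(roc$fpr[nrow(roc)], 0)
  expect_true(all(diff(roc$tpr) <= 1e-9))
  expect_true(all(diff(roc$fpr) <= 1e-9))

  # one participant is a precondition violation
  ds1 <- ds[ds$participant_id == "P1", ]
  expect_error(lopo_evaluate(labeled_dataset(as.data.frame(ds1)),
                             classifier_spec("centroid")), "participants")

  # leakage guard: fold predictions must equal a manual train-only
  # pipeline (imputation fitted without the held-out participant)
  ds2 <- make_null_dataset(n_participants = 4, seed = 6)
  ds2$BF[ds2$participant_id == "P1"] <- NA  # imputation must come from P2-4
  ds2 <- labeled_dataset(as.data.frame(ds2))
  cv2 <- lopo_evaluate(ds2, classifier_spec("centroid"),
                       features = c("BF", "SF", "PERCLOS"), seed = 9)
  test <- ds2$participant_id == "P1"
  Xall <- oculofatigue:::prepare_X(ds2, c("BF", "SF", "PERCLOS"))
  med <- oculofatigue:::impute_fit(Xall[!test, , drop = FALSE])
  core <- oculofatigue:::fit_core(
    classifier_spec("centroid"),
    oculofatigue:::impute_apply(Xall[!test, , drop = FALSE], med),
    oculofatigue:::labels_to_y(ds2$label)[!test], 9)
  manual <- oculofatigue:::posterior_core(
    core, oculofatigue:::impute_apply(Xall[test, , drop = FALSE], med))
  expect_equal(unname(cv2$folds[["P1"]]$posterior), unname(manual),
               tolerance = 1e-12)

  # a single-class training fold is skipped with a warning
  ds3 <- make_separable_dataset(n_participants = 3, seed = 7)
  ds3$kss[ds3$participant_id != "P1"] <- 7L
  ds3 <- labeled_dataset(as.data.frame(ds3))
  expect_warning(cv3 <- lopo_evaluate(ds3, classifier_spec("centroid")),
                 "skipped")
  expect_equal(cv3$skipped, "P1")
})

test_that("SFFS selects a label-equal feature and honors max_size", {
  # one feature equal to the label dominates
  ds <- make_separable_dataset(n_participants = 4, seed = 8)
  # a single dominating feature triggers the "no improving inclusion
  # beyond a single feature" warning and is returned alone
  expect_warning(
    sel <- sffs_select(ds, classifier_spec("centroid"), max_size = 3L,
                       pool = c("BF", "SF", "PERCLOS", "SVA", "PDIR"),
                       seed = 1),
    "single feature")
  expect_equal(sel$subset, "BF")

  # max_size 1 equals the exhaustive best single feature
  sel1 <- sffs_select(ds, classifier_spec("centroid"), max_size = 1L,
                      pool = c("BF", "SF", "PERCLOS"), seed = 1)
  singles <- vapply(c("BF", "SF", "PERCLOS"), function(f)
    lopo_evaluate(ds, classifier_spec("centroid"), features = f,
                  seed = oculofatigue:::subset_seed(
                    1, f, c("BF", "SF", "PERCLOS")))$youden, 0)
  expect_equal(sel1$subset, names(which.max(singles)))

  # determinism given dataset and seed
  suppressWarnings(
    sel2 <- sffs_select(ds, classifier_spec("centroid"), max_size = 3L,
                        pool = c("BF", "SF", "PERCLOS", "SVA", "PDIR"),
                        seed = 1))
  expect_identical(sel$subset, sel2$subset)
  expect_error(sffs_select(ds, pool = "BF"), "2")
})

test_that("SFFS recovers planted informative features", {
  hits <- 0L
  for (sd in 1:20) {
    ds <- make_planted_dataset(seed = sd)
    sel <- sffs_select(ds, classifier_spec("random_forest", n_trees = 11L),
                       max_size = 4L, pool = OCULOMETRIC_FEATURES[1:10],
                       seed = sd)
    ok <- all(c("BF", "BD") %in% sel$subset) &&
      length(setdiff(sel$subset, c("BF", "BD"))) <= 1L
    hits <- hits + ok
  }
  expect_gte(hits, 18L)  # >= 90% of 20 seeded runs
})

test_that("permutation test formula, edge cases, and invariances", {
  ds <- make_separable_dataset(n_participants = 4, seed = 10)
  expect_error(permutation_test(ds, n_permutations = 0L), "permutations")

  # n = 1: p is either 1/2 or 1
  pt1 <- permutation_test(ds, classifier_spec("centroid"),
                          features = c("BF", "SF"), n_permutations = 1L,
                          seed = 3)
  expect_true(pt1$p_value %in% c(0.5, 1))

  # invariance to participant relabeling
  pt_a <- permutation_test(ds, classifier_spec("centroid"),
                           features = c("BF", "SF"),
                           n_permutations = 19L, seed = 5)
  ds_re <- as.data.frame(ds)
  ds_re$participant_id <- factor(ds_re$participant_id,
                                 levels = c("P1", "P2", "P3", "P4"),
                                 labels = c("Z9", "Z8", "Z7", "Z6"))
  pt_b <- permutation_test(labeled_dataset(ds_re),
                           classifier_spec("centroid"),
                           features = c("BF", "SF"),
                           n_permutations = 19L, seed = 5)
  expect_equal(pt_a$p_value, pt_b$p_value)
  expect_equal(pt_a$null, pt_b$null, tolerance = 1e-12)
})

test_that("a single-class dataset cannot train", {
  ds <- make_separable_dataset(seed = 11)
  ds$kss[] <- 7L
  ds <- labeled_dataset(as.data.frame(ds))
  expect_error(train_ensemble(ds), "both classes")
})
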