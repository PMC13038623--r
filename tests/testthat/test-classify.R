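synthetic_features <- function(seed = 1, n = 15, p = 6, shift = 0) {
  # p features, first half carries a group shift
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[(n + 1):(2 * n), seq_len(p / 2)] <- X[(n + 1):(2 * n), seq_len(p / 2)] + shift
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = rep(c("control", "nsbvd"), each = n))
}

test_that("z-scoring standardizes training data and transfers to test data", {
  set.seed(40)
  X <- matrix(rnorm(50, mean = 7, sd = 3), 10, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  sc <- zscore_fit(X)
  Z <- zscore_apply(sc, X)
  expect_equal(unname(colMeans(Z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 5), tolerance = 1e-10)
  # x = mu -> 0; x = mu + sigma -> 1
  probe <- rbind(sc$mu, sc$mu + sc$sigma)
  colnames(probe) <- names(sc$mu)
  Zp <- zscore_apply(sc, probe)
  expect_equal(unname(Zp[1, ]), rep(0, 5))
  expect_equal(unname(Zp[2, ]), rep(1, 5))
  # refitting on standardized data is idempotent
  sc2 <- zscore_fit(Z)
  expect_equal(unname(sc2$mu), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(sc2$sigma), rep(1, 5), tolerance = 1e-10)
  # zero-variance feature dropped with a warning
  Xz <- cbind(X, const = 1)
  expect_warning(scz <- zscore_fit(Xz), "zero-variance")
  expect_false("const" %in% scz$columns)
})

test_that("feature ranking follows |t| with deterministic tie-breaks", {
  fx <- synthetic_features(seed = 2, shift = 2)
  sel <- rank_features(fx$X, fx$y, 3)
  # oracle: recompute all t statistics with t.test
  tv <- abs(vapply(seq_len(ncol(fx$X)), function(j) {
    unname(t.test(fx$X[fx$y == "control", j], fx$X[fx$y == "nsbvd", j],
                  var.equal = TRUE)$statistic)
  }, 0))
  expect_equal(sort(sel), sort(order(-tv)[1:3]))
  # a constant-difference feature ranks last, a separated feature first
  X <- cbind(same = rep(c(1, 2), 10), sep = rep(c(0, 10), each = 10))
  y <- rep(c("control", "nsbvd"), each = 10)
  expect_equal(rank_features(X, y, 2), c(2, 1))
  expect_error(rank_features(X, y, 0), "positive")
  # ties broken lexicographically by name
  Xt <- cbind(b = c(1, 2, 3, 4), a = c(1, 2, 3, 4))
  expect_equal(rank_features(Xt, c("control", "control", "nsbvd", "nsbvd"), 2),
               c(2, 1))
})

test_that("LOOCV predicts every subject exactly once and is deterministic", {
  fx <- synthetic_features(seed = 3, shift = 3)
  for (m in c("svm_linear", "lda", "knn3")) {
    r <- nested_loocv(fx$X, m, k = 4, y = fx$y)
    expect_length(r$predictions, 30)
    expect_length(r$scores, 30)
    expect_equal(sum(r$confusion), 30)
    r2 <- nested_loocv(fx$X, m, k = 4, y = fx$y)
    expect_identical(r$scores, r2$scores)
    expect_identical(r$predictions, r2$predictions)
  }
  expect_error(nested_loocv(fx$X[c(1, 16, 17), ], "lda",
                            y = fx$y[c(1, 16, 17)]), ">= 2 subjects")
})

test_that("fold models are blind to the held-out subject", {
  # recomputing fold 1 by hand from the reduced data reproduces the
  # pipeline's prediction exactly
  fx <- synthetic_features(seed = 4, shift = 1.5)
  i <- 1
  Xtr <- fx$X[-i, ]; ytr <- fx$y[-i]
  sc <- zscore_fit(Xtr)
  Ztr <- zscore_apply(sc, Xtr)
  sel <- rank_features(Ztr, ytr, 4)
  model <- vergelab:::fit_classifier(Ztr[, sel, drop = FALSE], ytr, "svm_linear")
  s_manual <- model$score(zscore_apply(sc, fx$X[i, , drop = FALSE])[, sel, drop = FALSE])
  r <- nested_loocv(fx$X, "svm_linear", k = 4, y = fx$y)
  expect_equal(unname(r$scores[i]), unname(s_manual), tolerance = 1e-10)
})

test_that("shrinkage LDA agrees with the reference implementation when well-posed", {
  fx <- synthetic_features(seed = 5, n = 20, p = 4, shift = 2)
  fit <- vergelab:::fit_lda_shrink(fx$X, fx$y)
  ref <- MASS::lda(fx$X, grouping = fx$y)
  pred_ref <- predict(ref, fx$X)$class
  pred_own <- ifelse(fit$score(fx$X) > 0, "nsbvd", "control")
  expect_gt(mean(pred_own == as.character(pred_ref)), 0.97)
})

test_that("metrics reproduce their defining identities", {
  set.seed(41)
  labels <- rep(c("nsbvd", "control"), each = 10)
  scores <- rnorm(20) + (labels == "nsbvd") * 1.5
  preds <- ifelse(scores > 0.7, "nsbvd", "control")
  r <- compute_metrics(preds, scores, labels)
  cf <- r$confusion
  expect_equal(cf[["TP"]] + cf[["FN"]], 10)
  expect_equal(cf[["TN"]] + cf[["FP"]], 10)
  expect_equal(r$accuracy, (cf[["TP"]] + cf[["TN"]]) / 20)
  expect_equal(r$f1, 2 * r$precision * r$sensitivity / (r$precision + r$sensitivity),
               tolerance = 1e-12)
  # AUC equals the reference ROC implementation
  ref_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("control", "nsbvd"),
                                            direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref_auc, tolerance = 1e-10)
  # perfect and inverted scores
  perf <- compute_metrics(labels, (labels == "nsbvd") * 1, labels)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$auc, 1)
  inv <- compute_metrics(preds, -scores, labels)
  expect_equal(inv$auc, 1 - r$auc, tolerance = 1e-10)
  expect_warning(compute_metrics(rep("nsbvd", 3), 1:3, rep("nsbvd", 3)),
                 "single-class")
})

test_that("confusion-derived metrics match the screening-table identities", {
  r <- metrics_from_confusion(tp = 12, fp = 4, tn = 11, fn = 3)
  expect_equal(r$accuracy, 23 / 30, tolerance = 1e-12)
  expect_equal(r$sensitivity, 0.80)
  expect_equal(r$specificity, 11 / 15, tolerance = 1e-12)
  expect_equal(r$precision, 0.75)
  expect_equal(r$f1, 0.7742, tolerance = 5e-5)
})

test_that("cluster-guided feature extraction yields one feature per ROI channel", {
  co <- tiny_cohort(seed = 19, effects = list(frontal_theta_effect(4)))
  ep <- epoch_cohort(co, "bo_break")
  apriori <- data.frame(condition = "bo_break", roi = "F3+Fz+F4",
                        band_lo_hz = 4, band_hi_hz = 8,
                        window_start_ms = -548, window_end_ms = -302)
  fx <- extract_features(list(bo_break = ep), apriori, reduced_cwt_config())
  expect_equal(dim(fx$X), c(4, 3))
  expect_equal(fx$y, co$groups)
  # identical epochs give identical feature rows
  ep2 <- ep
  ep2$tensor[2, , , ] <- ep2$tensor[1, , , ]
  fx2 <- extract_features(list(bo_break = ep2), apriori, reduced_cwt_config())
  expect_equal(fx2$X[1, ], fx2$X[2, ])
  # no significant clusters: actionable error
  empty <- structure(list(table = data.frame(significant = logical(0))),
                     class = "verge_cluster_result")
  expect_error(extract_features(list(bo_break = ep), empty),
               "a-priori")
})

test_that("feature values increase with the injected effect multiplier", {
  apriori <- data.frame(condition = "bo_break", roi = "Fz",
                        band_lo_hz = 4, band_hi_hz = 8,
                        window_start_ms = -548, window_end_ms = -302)
  med <- vapply(c(1, 2, 4), function(mult) {
    co <- generate_cohort(
      synth_config(n_per_group = 4, seed = 13),
      if (mult > 1) list(frontal_theta_effect(mult)) else list(),
      conditions = "bo_break")
    ep <- epoch_cohort(co, "bo_break")
    fx <- extract_features(list(bo_break = ep), apriori, reduced_cwt_config())
    mean(fx$X[fx$y == "nsbvd", 1])
  }, 0)
  expect_true(all(diff(med) > 0))
})
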