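# Subject-level diagnostic classification: cluster-guided feature
# extraction, nested leave-one-out cross-validation with in-fold z-scoring
# and t-test feature ranking, three deterministic classifiers (linear SVM,
# shrinkage LDA, 3-NN) and the standard screening metric suite. The
# positive class is "nsbvd" throughout.

#' Extract cluster-guided features from epoch sets
#'
#' For every significant cluster (or every row of an a-priori feature
#' table) and every channel of its ROI, one feature per subject: the mean
#' relative power (or mean log absolute power) over the cluster's band x
#' time-window extent.
#'
#' @param epoch_sets named list mapping condition labels to `verge_epochs`
#'   objects covering the same subjects in the same order.
#' @param clusters a `verge_cluster_result`, or a data frame with columns
#'   `condition`, `roi` (labels joined by `+`), `band_lo_hz`, `band_hi_hz`,
#'   `window_start_ms`, `window_end_ms` giving an a-priori feature list.
#' @param cfg a [cwt_config()].
#' @param measure `"ratio"` (relative power) or `"log_power"`.
#' @return A `verge_features`: `X` (subjects x features), `y` (group
#'   labels), feature names encode provenance.
#' @export
extract_features <- function(epoch_sets, clusters, cfg = cwt_config(),
                             measure = c("ratio", "log_power")) {
  measure <- match.arg(measure)
  if (inherits(clusters, "verge_cluster_result")) {
    tab <- clusters$table[clusters$table$significant, , drop = FALSE]
    if (nrow(tab) == 0) {
      stop("no significant clusters to extract features from; ",
           "supply an a-priori feature table (condition/roi/band/window) instead")
    }
  } else {
    tab <- as.data.frame(clusters)
    need <- c("condition", "roi", "band_lo_hz", "band_hi_hz",
              "window_start_ms", "window_end_ms")
    if (!all(need %in% names(tab))) {
      stop("a-priori feature table must have columns: ",
           paste(need, collapse = ", "))
    }
  }
  first <- epoch_sets[[1]]
  n_sub <- dim(first$tensor)[1]
  cols <- list()
  for (ri in seq_len(nrow(tab))) {
    cond <- if ("condition" %in% names(tab)) tab$condition[ri] else
      sub(" .*", "", tab$comparison[ri])
    ep <- epoch_sets[[cond]]
    if (is.null(ep)) stop("no epoch set supplied for condition '", cond, "'")
    chans <- strsplit(tab$roi[ri], "+", fixed = TRUE)[[1]]
    band <- c(tab$band_lo_hz[ri], tab$band_hi_hz[ri])
    win <- c(tab$window_start_ms[ri], tab$window_end_ms[ri])
    for (ch in chans) {
      st <- cohort_tf_stack(ep, ch, cfg)
      fi <- which(st$freqs >= band[1] & st$freqs <= band[2])
      ti <- which(st$times >= win[1] & st$times <= win[2])
      if (length(fi) == 0 || length(ti) == 0) {
        stop("empty band/window extent for feature ", ri, " channel ", ch)
      }
      v <- vapply(seq_len(n_sub), function(si) {
        cell <- mean(st$data[si, fi, ti])
        if (measure == "ratio") cell / mean(st$data[si, , ti]) else log(cell)
      }, 0)
      nm <- sprintf("%s.%s.%g-%gHz.%g-%gms", cond, ch, band[1], band[2],
                    win[1], win[2])
      cols[[nm]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- first$subject_ids
  structure(list(X = X, y = first$groups, subject_ids = first$subject_ids),
            class = "verge_features")
}

#' Fit a z-score scaler on training data
#'
#' Per-feature mean and SD computed on the training rows only.
#' Zero-variance features are dropped with a warning.
#'
#' @param X training matrix (rows = subjects).
#' @return A `verge_zscaler` with `mu`, `sigma` and the retained columns.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need >= 2 training rows to fit a scaler")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  keep <- sigma > 0
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  structure(list(mu = mu[keep], sigma = sigma[keep],
                 columns = colnames(X)[keep]), class = "verge_zscaler")
}

#' Apply a fitted z-score scaler
#'
#' @param scaler a `verge_zscaler` from [zscore_fit()].
#' @param X matrix (or single row) with the same columns as the training set.
#' @return The standardised matrix restricted to the retained features.
#' @export
zscore_apply <- function(scaler, X) {
  X <- as.matrix(X)
  X <- X[, scaler$columns, drop = FALSE]
  sweep(sweep(X, 2, scaler$mu), 2, scaler$sigma, "/")
}

#' Rank features by two-sample t statistic
#'
#' Features are ordered by decreasing `|t|` (pooled-variance two-sample t
#' between the classes); ties are broken by feature-name lexicographic
#' order so the ranking is deterministic.
#'
#' @param X feature matrix (rows = subjects).
#' @param y class labels (two classes).
#' @param k number of features to keep.
#' @return Integer indices of the top `k` features.
#' @export
rank_features <- function(X, y, k) {
  if (k <= 0) stop("k must be positive")
  X <- as.matrix(X)
  k <- min(k, ncol(X))
  cls <- unique(y)
  if (length(cls) != 2) stop("rank_features requires exactly two classes")
  tv <- abs(tstat_between(X, y == cls[1]))
  tv[!is.finite(tv)] <- Inf   # perfectly separated or zero-variance-in-class
  nm <- colnames(X)
  if (is.null(nm)) nm <- sprintf("f%06d", seq_len(ncol(X)))
  ord <- order(-tv, nm)
  ord[seq_len(k)]
}

# --- classifiers ----------------------------------------------------------
# Each fit returns a list with a $score(Xnew) function: higher = more
# nsbvd-like; predicted label is nsbvd when score > threshold (0 for the
# linear models, 0.5 for 3-NN).

fit_svm_linear <- function(X, y, cost = 1) {
  yf <- factor(y, levels = c("control", "nsbvd"))
  m <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                  scale = FALSE, type = "C-classification")
  list(
    score = function(Xn) {
      dv <- attr(stats::predict(m, Xn, decision.values = TRUE),
                 "decision.values")
      s <- dv[, 1]
      # decision value is positive for the class named first in the column
      # header; orient so that higher = nsbvd
      if (grepl("^control/", colnames(dv)[1])) -s else s
    },
    threshold = 0
  )
}

fit_lda_shrink <- function(X, y) {
  X <- as.matrix(X)
  i1 <- y == "nsbvd"
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu0 <- colMeans(X[!i1, , drop = FALSE])
  n1 <- sum(i1); n0 <- sum(!i1); p <- ncol(X)
  S1 <- stats::cov(X[i1, , drop = FALSE])
  S0 <- stats::cov(X[!i1, , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n1 + n0 - 2)
  gamma <- if (p >= n1 + n0) 0.25 else 1e-8
  Sp <- (1 - gamma) * Sp + gamma * mean(diag(Sp)) * diag(p)
  w <- solve(Sp, mu1 - mu0)
  b <- -0.5 * sum((mu1 + mu0) * w) + log(n1 / n0)
  list(score = function(Xn) as.vector(as.matrix(Xn) %*% w) + b,
       threshold = 0)
}

fit_knn3 <- function(X, y, k = 3) {
  X <- as.matrix(X)
  list(
    score = function(Xn) {
      Xn <- as.matrix(Xn)
      apply(Xn, 1, function(row) {
        d <- sqrt(colSums((t(X) - row)^2))
        # distance ties broken by training-subject index (stable order)
        nb <- order(d)[seq_len(min(k, length(d)))]
        mean(y[nb] == "nsbvd")
      })
    },
    threshold = 0.5
  )
}

fit_classifier <- function(X, y, method = c("svm_linear", "lda", "knn3")) {
  method <- match.arg(method)
  switch(method,
         svm_linear = fit_svm_linear(X, y),
         lda = fit_lda_shrink(X, y),
         knn3 = fit_knn3(X, y))
}

#' Nested leave-one-out cross-validation
#'
#' For each held-out subject: the z-score scaler is fitted on the remaining
#' subjects, features are ranked by in-fold t statistics and the top `k`
#' selected, the classifier is trained, and the held-out subject is scored
#' - so scaling, selection and training are all blind to the test subject.
#' Predictions and decision scores are pooled over all folds into one
#' report (scores are comparable across folds after in-fold z-scoring).
#'
#' @param features a `verge_features`, or a plain feature matrix (then `y`
#'   must be given).
#' @param classifier `"svm_linear"`, `"lda"` or `"knn3"`.
#' @param k number of features selected inside each fold (default 10,
#'   capped at the available count).
#' @param y group labels when `features` is a bare matrix.
#' @return A `verge_classification_report` (see [compute_metrics()]) with
#'   per-fold predictions and scores.
#' @export
nested_loocv <- function(features, classifier = c("svm_linear", "lda", "knn3"),
                         k = 10, y = NULL) {
  classifier <- match.arg(classifier)
  if (inherits(features, "verge_features")) {
    X <- features$X; y <- features$y
  } else {
    X <- as.matrix(features)
    if (is.null(y)) stop("y must be supplied with a bare feature matrix")
  }
  n <- nrow(X)
  if (sum(y == "nsbvd") < 2 || sum(y == "control") < 2) {
    stop("need >= 2 subjects per class")
  }
  preds <- character(n); scores <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (length(unique(ytr)) < 2) stop("a class is absent from training fold ", i)
    sc <- suppressWarnings(zscore_fit(Xtr))
    Ztr <- zscore_apply(sc, Xtr)
    sel <- rank_features(Ztr, ytr, min(k, ncol(Ztr)))
    model <- fit_classifier(Ztr[, sel, drop = FALSE], ytr, classifier)
    Zte <- zscore_apply(sc, X[i, , drop = FALSE])[, sel, drop = FALSE]
    s <- model$score(Zte)
    scores[i] <- s
    preds[i] <- if (s > model$threshold) "nsbvd" else "control"
  }
  rep <- compute_metrics(preds, scores, y)
  rep$classifier <- classifier
  rep$k <- k
  rep
}

#' Classification metrics, confusion matrix and ROC/AUC
#'
#' Counts the confusion matrix with `nsbvd` as the positive class and
#' derives accuracy, sensitivity, specificity, precision, F1 and the
#' trapezoidal AUC of the ROC curve obtained by sweeping a threshold over
#' the pooled decision scores.
#'
#' @param predictions character vector of predicted labels.
#' @param scores numeric decision scores (higher = more nsbvd-like).
#' @param labels true labels.
#' @param positive positive class (default `"nsbvd"`).
#' @return A `verge_classification_report`: confusion counts, the metric
#'   set (proportions in `[0, 1]`), `roc` (data frame of FPR/TPR points)
#'   and the per-subject predictions/scores.
#' @export
compute_metrics <- function(predictions, scores, labels, positive = "nsbvd") {
  stopifnot(length(predictions) == length(labels),
            length(scores) == length(labels))
  pos <- labels == positive
  tp <- sum(predictions == positive & pos)
  fn <- sum(predictions != positive & pos)
  tn <- sum(predictions != positive & !pos)
  fp <- sum(predictions == positive & !pos)
  n <- length(labels)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  if (all(pos) || all(!pos)) {
    warning("single-class labels: ROC/AUC undefined")
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
    auc <- NA_real_
  } else {
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    roc <- data.frame(
      fpr = vapply(thr, function(t) sum(scores >= t & !pos) / sum(!pos), 0),
      tpr = vapply(thr, function(t) sum(scores >= t & pos) / sum(pos), 0)
    )
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  }
  structure(list(
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1, auc = auc, roc = roc,
    predictions = predictions, scores = scores, labels = labels,
    positive = positive
  ), class = "verge_classification_report")
}

#' Metrics implied by a confusion matrix
#'
#' @param tp,fp,tn,fn confusion counts (positive class = patients).
#' @return A `verge_classification_report` without ROC/AUC (no scores).
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  labels <- c(rep("nsbvd", tp + fn), rep("control", tn + fp))
  preds <- c(rep("nsbvd", tp), rep("control", fn),
             rep("control", tn), rep("nsbvd", fp))
  out <- suppressWarnings(compute_metrics(preds, rep(0, length(labels)), labels))
  out$auc <- NA_real_
  out$roc <- NULL
  out
}

#' @export
print.verge_classification_report <- function(x, ...) {
  cat("<verge_classification_report>",
      if (!is.null(x$classifier)) paste0(" [", x$classifier, "]"), "\n",
      sep = "")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["TN"], x$confusion["FN"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("  precision %.2f%%  F1 %.4f  AUC %s\n",
              100 * x$precision, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}
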