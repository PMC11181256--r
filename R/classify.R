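#' Train on one fold and score one held-out lesion
#'
#' Features are standardized with the *training* mean and SD only (a feature
#' with zero training SD is centered and passed through with scale 1), then a
#' soft-margin SVM is fit with \pkg{e1071} and the held-out feature vector is
#' scored. The signed decision value is oriented so that positive scores mean
#' the positive class; a score of exactly 0 is called negative.
#'
#' @param train_x numeric matrix, one row per training lesion.
#' @param train_labels vector of class labels; both classes must be present.
#' @param test_x numeric vector (or 1-row matrix) of the held-out lesion.
#' @param positive label of the positive class (GIST).
#' @param standardize z-score features on training statistics (default TRUE).
#' @param kernel,cost SVM kernel and cost; defaults linear, C = 1.
#' @return list with `label` (predicted class) and `score` (signed decision
#'   value, positive = positive class).
#' @export
fit_predict_once <- function(train_x, train_labels, test_x, positive = "GIST",
                             standardize = TRUE, kernel = "linear", cost = 1) {
  train_x <- as.matrix(train_x)
  train_labels <- as.character(train_labels)
  cls <- unique(train_labels)
  if (length(cls) != 2L) stop("training fold must contain exactly two classes")
  if (!positive %in% cls) stop("positive class '", positive, "' absent from fold")
  negative <- setdiff(cls, positive)
  test_x <- matrix(as.numeric(test_x), nrow = 1L)
  if (ncol(test_x) != ncol(train_x)) stop("feature dimension mismatch")
  if (standardize) {
    mu <- colMeans(train_x)
    s <- apply(train_x, 2L, sd)
    s[!is.finite(s) | s == 0] <- 1
    train_x <- sweep(sweep(train_x, 2L, mu), 2L, s, "/")
    test_x <- sweep(sweep(test_x, 2L, mu), 2L, s, "/")
  }
  fit <- e1071::svm(train_x, factor(train_labels, levels = c(negative, positive)),
                    kernel = kernel, cost = cost, scale = FALSE)
  pr <- stats::predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # e1071 orients the decision value towards the class named first in the
  # "A/B" column label; normalize so positive score => positive class
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- if (identical(first, positive)) dv[1L] else -dv[1L]
  list(label = if (score > 0) positive else negative, score = unname(score))
}

#' Leave-one-out cross-validated SVM over a lesion feature table
#'
#' Fits one SVM per lesion on the remaining n - 1 lesions (per-fold
#' standardization, so the held-out lesion never contributes to the scaling
#' statistics) and records the held-out hard prediction and signed decision
#' score. The whole procedure is deterministic given the table; `seed` is
#' accepted for interface symmetry with stochastic classifiers.
#'
#' @param x feature table from [feature_table()] (columns `lesion_id`,
#'   `label`, features), or a numeric matrix with `labels` given separately.
#' @param labels class labels (ignored when `x` is a feature table).
#' @param lesion_ids optional identifiers (ignored when `x` is a table).
#' @param positive label of the positive class.
#' @inheritParams fit_predict_once
#' @param seed unused by the deterministic solver; kept for API stability.
#' @return Object of class `cad_loocv`: list with `predictions` (data.frame
#'   `lesion_id`, `true`, `pred`, `score`), `positive`, `negative`,
#'   `combination_id`, `settings`, `n`.
#' @examples
#' set.seed(1)
#' x <- matrix(c(rnorm(10, 2), rnorm(10, -2)), ncol = 1)
#' fit <- loocv_svm(x, labels = rep(c("GIST", "non-GIST"), each = 10))
#' summary(fit)
#' @export
loocv_svm <- function(x, labels = NULL, lesion_ids = NULL, positive = "GIST",
                      standardize = TRUE, kernel = "linear", cost = 1,
                      seed = NULL) {
  if (is.data.frame(x)) {
    cid <- attr(x, "combination_id")
    parts <- unpack_feature_table(x)
    x <- parts$x; labels <- parts$labels; lesion_ids <- parts$ids
  } else {
    cid <- NULL
    x <- as.matrix(x)
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 lesions")
  if (length(labels) != n) stop("labels/features length mismatch")
  if (any(!is.finite(x))) stop("feature table contains missing values")
  cls <- unique(labels)
  if (length(cls) != 2L) stop("need exactly two classes")
  if (!positive %in% cls) stop("positive class '", positive, "' not present")
  negative <- setdiff(cls, positive)
  if (is.null(lesion_ids)) lesion_ids <- sprintf("lesion_%03d", seq_len(n))
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) != 2L) {
      stop(sprintf("training fold %d contains a single class", i))
    }
    r <- fit_predict_once(x[-i, , drop = FALSE], tr_lab, x[i, ],
                          positive = positive, standardize = standardize,
                          kernel = kernel, cost = cost)
    pred[i] <- r$label; score[i] <- r$score
  }
  structure(
    list(predictions = data.frame(lesion_id = lesion_ids, true = labels,
                                  pred = pred, score = score,
                                  stringsAsFactors = FALSE),
         positive = positive, negative = negative, combination_id = cid,
         settings = list(standardize = standardize, kernel = kernel,
                         cost = cost, seed = seed),
         n = n),
    class = "cad_loocv"
  )
}

#' @export
print.cad_loocv <- function(x, ...) {
  acc <- mean(x$predictions$true == x$predictions$pred)
  cat(sprintf("<cad_loocv> %d folds (%s kernel, C=%g)%s\n", x$n,
              x$settings$kernel, x$settings$cost,
              if (is.null(x$combination_id)) "" else
                paste0("  features=", x$combination_id)))
  cat(sprintf("  LOOCV accuracy %.2f%% (positive class: %s)\n",
              100 * acc, x$positive))
  invisible(x)
}

#' Confusion counts of a LOOCV run
#'
#' @param x a `cad_loocv`.
#' @return named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(x) {
  stopifnot(inherits(x, "cad_loocv"))
  p <- x$predictions
  c(tp = sum(p$true == x$positive & p$pred == x$positive),
    tn = sum(p$true != x$positive & p$pred != x$positive),
    fp = sum(p$true != x$positive & p$pred == x$positive),
    fn = sum(p$true == x$positive & p$pred != x$positive))
}

#' @export
summary.cad_loocv <- function(object, ...) {
  cc <- confusion_counts(object)
  met <- confusion_metrics(tp = cc[["tp"]], tn = cc[["tn"]],
                           fp = cc[["fp"]], fn = cc[["fn"]])
  roc <- roc_auc(object)
  out <- list(counts = cc, metrics = met, roc = roc,
              combination_id = object$combination_id, n = object$n)
  class(out) <- "summary.cad_loocv"
  out
}

#' @export
print.summary.cad_loocv <- function(x, ...) {
  cat(sprintf("LOOCV over %d lesions%s\n", x$n,
              if (is.null(x$combination_id)) "" else
                paste0(" (", x$combination_id, ")")))
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$counts["tp"], x$counts["tn"],
              x$counts["fp"], x$counts["fn"]))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              round2(x$metrics["sensitivity"]), round2(x$metrics["specificity"]),
              round2(x$metrics["accuracy"])))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$roc$auc,
              x$roc$ci95[1L], x$roc$ci95[2L]))
  invisible(x)
}

#' @export
plot.cad_loocv <- function(x, ...) {
  roc <- roc_auc(x)
  plot(roc$curve$fpr, roc$curve$tpr, type = "s",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1),
       main = sprintf("LOOCV ROC%s (AUC = %.2f)",
                      if (is.null(x$combination_id)) "" else
                        paste0(", ", x$combination_id), roc$auc), ...)
  abline(0, 1, lty = 3)
  invisible(roc)
}
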