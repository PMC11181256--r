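# half-up rounding to 2 decimals, the display convention for percent metrics
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' GISTs are the positive class: sensitivity `= 100 tp / (tp + fn)`,
#' specificity `= 100 tn / (tn + fp)`, accuracy `= 100 (tp + tn) / n`.
#' Values are returned at full precision, in percent; display rounding is
#' half-up to 2 decimals.
#'
#' @param tp,tn,fp,fn confusion counts (non-negative integers).
#' @return named numeric: `sensitivity`, `specificity`, `accuracy` (percent).
#' @examples
#' confusion_metrics(tp = 48, fn = 11, tn = 50, fp = 11)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (tp + fn < 1) stop("no positives (tp + fn = 0)")
  if (tn + fp < 1) stop("no negatives (tn + fp = 0)")
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn))
}

#' ROC curve and AUC with DeLong variance
#'
#' AUC is the Mann-Whitney concordance probability over pooled decision
#' scores (ties count 1/2); the variance and the 95% CI come from DeLong's
#' structural components under the normal approximation. Computed through
#' \pkg{pROC}.
#'
#' @param x numeric decision scores (higher = more positive-like), or a
#'   [loocv_svm()] result.
#' @param labels class labels matching `x` (unused for `cad_loocv` input).
#' @param positive positive class label.
#' @param ... unused.
#' @return Object of class `roc_summary`: list with `auc`, `variance`,
#'   `ci95` (length-2), and `curve` (data.frame `fpr`, `tpr` from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(x, ...) UseMethod("roc_auc")

#' @rdname roc_auc
#' @export
roc_auc.cad_loocv <- function(x, ...) {
  roc_auc(x$predictions$score, x$predictions$true, positive = x$positive)
}

#' @rdname roc_auc
#' @export
roc_auc.default <- function(x, labels, positive = "GIST", ...) {
  scores <- as.numeric(x)
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L || !positive %in% cls) {
    stop("need both classes with positive = '", positive, "'")
  }
  r <- build_proc_roc(scores, labels, positive)
  auc <- as.numeric(r$auc)
  v <- suppressWarnings(as.numeric(pROC::var(r, method = "delong")))
  if (!is.finite(v)) v <- 0
  ci <- if (v > 0) {
    as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1L, 3L)]
  } else c(auc, auc)
  ci <- pmin(1, pmax(0, ci))
  fpr <- 1 - r$specificities
  tpr <- r$sensitivities
  o <- order(fpr, tpr)
  structure(list(auc = auc, variance = v, ci95 = ci,
                 curve = data.frame(fpr = fpr[o], tpr = tpr[o])),
            class = "roc_summary")
}

build_proc_roc <- function(scores, labels, positive) {
  negative <- setdiff(unique(labels), positive)
  pROC::roc(response = labels, predictor = scores,
            levels = c(negative, positive), direction = "<", quiet = TRUE)
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.4f (DeLong 95%% CI %.4f-%.4f, var %.3g)\n",
              x$auc, x$ci95[1L], x$ci95[2L], x$variance))
  invisible(x)
}

#' DeLong's paired test for two correlated AUCs
#'
#' Both score lists must come from the same lesions (paired design; e.g. two
#' feature combinations classified on one cohort). The variance of the AUC
#' difference is built from the paired DeLong structural components;
#' `z = (auc_a - auc_b) / sd(diff)` with a two-sided normal p value.
#'
#' @param scores_a,scores_b per-lesion decision scores of the two methods.
#' @param labels shared true labels.
#' @param positive positive class label.
#' @return Object of class `delong_test`: list `auc_a`, `auc_b`, `z`,
#'   `p` (two-sided).
#' @export
delong_paired <- function(scores_a, scores_b, labels, positive = "GIST") {
  scores_a <- as.numeric(scores_a); scores_b <- as.numeric(scores_b)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length (paired design)")
  }
  ra <- build_proc_roc(scores_a, as.character(labels), positive)
  rb <- build_proc_roc(scores_b, as.character(labels), positive)
  auc_a <- as.numeric(ra$auc); auc_b <- as.numeric(rb$auc)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    out <- list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1)
  } else {
    tt <- suppressWarnings(pROC::roc.test(ra, rb, method = "delong",
                                          paired = TRUE))
    z <- unname(tt$statistic); p <- tt$p.value
    if (!is.finite(z)) {
      if (auc_a == auc_b) {
        z <- 0; p <- 1
      } else {
        stop("degenerate paired comparison: zero variance with unequal AUCs")
      }
    }
    out <- list(auc_a = auc_a, auc_b = auc_b, z = z, p = p)
  }
  class(out) <- "delong_test"
  out
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p))
  invisible(x)
}

#' Chi-square comparison of two classification accuracies
#'
#' Pearson chi-square (1 df) on the 2x2 correct/incorrect x method table,
#' without continuity correction by default — the convention used when
#' comparing the CAD system against individual readers.
#'
#' @param correct_a,n_a correct count and total for method A.
#' @param correct_b,n_b correct count and total for method B.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `chi2`, `p` and the underlying 2x2 `table`.
#' @examples
#' compare_accuracy_chi2(98, 120, 84, 120)
#' @export
compare_accuracy_chi2 <- function(correct_a, n_a, correct_b, n_b,
                                  correct = FALSE) {
  stopifnot(n_a >= 1, n_b >= 1, correct_a >= 0, correct_b >= 0,
            correct_a <= n_a, correct_b <= n_b)
  tab <- matrix(c(correct_a, n_a - correct_a, correct_b, n_b - correct_b),
                nrow = 2L, dimnames = list(c("correct", "incorrect"),
                                           c("A", "B")))
  if (correct_a / n_a == correct_b / n_b) {
    return(list(chi2 = 0, p = 1, table = tab))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Reader performance table with mean row
#'
#' Per-reader sensitivity/specificity/accuracy from TP/TN counts against a
#' fixed set of positives and negatives, plus an unweighted mean row across
#' readers — the layout of a presumptive-diagnosis reader study.
#'
#' @param readers data.frame with columns `reader_id`, `tp`, `tn`, `n_pos`,
#'   `n_neg`; `n_pos`/`n_neg` must agree across readers.
#' @return data.frame with columns `reader_id`, `tp`, `tn`, `sensitivity`,
#'   `specificity`, `accuracy` (percent, full precision) and a final `"Mean"`
#'   row holding unweighted column means.
#' @export
reader_table <- function(readers) {
  need <- c("reader_id", "tp", "tn", "n_pos", "n_neg")
  if (!all(need %in% names(readers))) {
    stop("readers needs columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(readers$n_pos)) != 1L || length(unique(readers$n_neg)) != 1L) {
    stop("inconsistent n_pos/n_neg across readers")
  }
  if (any(readers$tp > readers$n_pos) || any(readers$tn > readers$n_neg)) {
    stop("tp/tn exceed class totals")
  }
  met <- t(mapply(function(tp, tn, np, nn) {
    confusion_metrics(tp = tp, tn = tn, fp = nn - tn, fn = np - tp)
  }, readers$tp, readers$tn, readers$n_pos, readers$n_neg))
  out <- data.frame(reader_id = as.character(readers$reader_id),
                    tp = readers$tp, tn = readers$tn, met,
                    stringsAsFactors = FALSE)
  mean_row <- data.frame(reader_id = "Mean", tp = mean(out$tp), tn = mean(out$tn),
                         sensitivity = mean(out$sensitivity),
                         specificity = mean(out$specificity),
                         accuracy = mean(out$accuracy),
                         stringsAsFactors = FALSE)
  rbind(out, mean_row)
}
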