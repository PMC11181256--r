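#' Simulate a cohort to disk
#'
#' Thin pipeline wrapper over [generate_cohort()]: writes images, ROI files
#' and the manifest, plus a `run.json` metadata record (spec, seed, package
#' version) for reproducibility.
#'
#' @param spec a [cohort_spec()], or path to a JSON file holding its fields.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
cad_simulate <- function(spec, dir) {
  if (is.character(spec)) {
    spec <- do.call(cohort_spec, jsonlite::fromJSON(spec))
  }
  stopifnot(inherits(spec, "cohort_spec"))
  res <- generate_cohort(spec, dir = dir)
  meta <- list(stage = "simulate", spec = unclass(spec),
               package = as.character(utils::packageVersion("eustex")))
  jsonlite::write_json(meta, file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(res$manifest_path)
}

#' Extract a feature combination for a whole cohort
#'
#' Loads lesions from a manifest (or takes them in memory), extracts one
#' feature combination per lesion, and returns the feature table. Per-lesion
#' failures are collected, reported as a warning, and attached as attribute
#' `failures`; successful lesions are kept.
#'
#' @param x manifest CSV path, or a list of `eus_lesion` objects.
#' @inheritParams feature_table
#' @param out_csv optional path to write the table via
#'   [write_feature_table()].
#' @return feature table data.frame (attribute `combination_id`; attribute
#'   `failures` is a character vector of failed lesion ids, empty if none).
#' @export
cad_extract <- function(x, combination = c("GGCM15", "GLCM48",
                                           "GLCM48_PLUS_GLOBAL3"),
                        out_csv = NULL, ...) {
  combination <- match.arg(combination)
  lesions <- if (is.character(x)) load_cohort(x) else x
  ok <- list(); failed <- character(0)
  for (l in lesions) {
    f <- tryCatch(extract_features(l, combination, ...), error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, sprintf("%s: %s", l$lesion_id, conditionMessage(f)))
    } else {
      ok[[length(ok) + 1L]] <- l
    }
  }
  if (length(failed)) {
    warning("feature extraction failed for: ", paste(failed, collapse = "; "))
  }
  tab <- feature_table(ok, combination, ...)
  attr(tab, "failures") <- failed
  if (!is.null(out_csv)) write_feature_table(tab, out_csv)
  tab
}

#' Evaluate feature combinations (and optionally readers) on one cohort
#'
#' Runs the leave-one-out SVM per feature table and assembles the evaluation
#' report: per-combination confusion metrics and DeLong AUC with 95% CI,
#' pairwise paired DeLong AUC comparisons between combinations, and — when a
#' reader CSV is supplied — the reader table plus chi-square comparisons of
#' each combination's accuracy against each reader.
#'
#' @param feature_tables named list of feature tables (from [cad_extract()])
#'   or CSV paths; names default to each table's `combination_id`.
#' @param reader_csv optional CSV with columns `reader_id`, `tp`, `tn`,
#'   `n_pos`, `n_neg`.
#' @param positive positive class label.
#' @param ... passed to [loocv_svm()] (kernel, cost, standardize, seed).
#' @return Object of class `cad_evaluation`: list with `metrics`,
#'   `delong` (pairwise comparisons), `fits` (the `cad_loocv` objects),
#'   `readers` and `reader_comparison` (NULL without `reader_csv`).
#' @export
cad_evaluate <- function(feature_tables, reader_csv = NULL, positive = "GIST",
                         ...) {
  if (!is.list(feature_tables) || is.data.frame(feature_tables)) {
    feature_tables <- list(feature_tables)
  }
  feature_tables <- lapply(feature_tables, function(t) {
    if (is.character(t)) read_feature_table(t) else t
  })
  nm <- names(feature_tables)
  ids <- vapply(seq_along(feature_tables), function(i) {
    cid <- attr(feature_tables[[i]], "combination_id")
    if (!is.null(nm) && nzchar(nm[i] %||% "")) nm[i]
    else if (!is.null(cid) && !is.na(cid)) cid
    else sprintf("combination_%d", i)
  }, "")
  names(feature_tables) <- ids
  fits <- lapply(feature_tables, loocv_svm, positive = positive, ...)
  metrics <- do.call(rbind, lapply(ids, function(id) {
    cc <- confusion_counts(fits[[id]])
    met <- confusion_metrics(tp = cc[["tp"]], tn = cc[["tn"]],
                             fp = cc[["fp"]], fn = cc[["fn"]])
    roc <- roc_auc(fits[[id]])
    data.frame(combination = id, tp = cc[["tp"]], tn = cc[["tn"]],
               sensitivity = met[["sensitivity"]],
               specificity = met[["specificity"]],
               accuracy = met[["accuracy"]], auc = roc$auc,
               ci_lo = roc$ci95[1L], ci_hi = roc$ci95[2L],
               stringsAsFactors = FALSE)
  }))
  delong <- NULL
  if (length(ids) >= 2L) {
    pairs <- utils::combn(ids, 2L)
    delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      dt <- delong_paired(fits[[a]]$predictions$score,
                          fits[[b]]$predictions$score,
                          fits[[a]]$predictions$true, positive = positive)
      data.frame(combination_a = a, combination_b = b, auc_a = dt$auc_a,
                 auc_b = dt$auc_b, z = dt$z, p = dt$p,
                 stringsAsFactors = FALSE)
    }))
  }
  readers <- reader_cmp <- NULL
  if (!is.null(reader_csv)) {
    rdf <- read.csv(reader_csv, stringsAsFactors = FALSE)
    readers <- reader_table(rdf)
    per_reader <- readers[readers$reader_id != "Mean", , drop = FALSE]
    n_total <- rdf$n_pos[1L] + rdf$n_neg[1L]
    reader_cmp <- do.call(rbind, lapply(ids, function(id) {
      cc <- confusion_counts(fits[[id]])
      do.call(rbind, lapply(seq_len(nrow(per_reader)), function(r) {
        ch <- compare_accuracy_chi2(cc[["tp"]] + cc[["tn"]], fits[[id]]$n,
                                    per_reader$tp[r] + per_reader$tn[r],
                                    n_total)
        data.frame(combination = id, reader_id = per_reader$reader_id[r],
                   chi2 = ch$chi2, p = ch$p, stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(metrics = metrics, delong = delong, fits = fits,
                 readers = readers, reader_comparison = reader_cmp),
            class = "cad_evaluation")
}

#' @export
print.cad_evaluation <- function(x, ...) {
  cat("Classification performance (LOOCV):\n")
  m <- x$metrics
  m[, c("sensitivity", "specificity", "accuracy")] <-
    round2(m[, c("sensitivity", "specificity", "accuracy")])
  m[, c("auc", "ci_lo", "ci_hi")] <- round(m[, c("auc", "ci_lo", "ci_hi")], 3)
  print(m, row.names = FALSE)
  if (!is.null(x$delong)) {
    cat("\nPairwise DeLong AUC comparisons:\n")
    print(transform(x$delong, z = round(z, 3), p = signif(p, 3)),
          row.names = FALSE)
  }
  if (!is.null(x$readers)) {
    cat("\nReader performance:\n")
    r <- x$readers
    r[, c("sensitivity", "specificity", "accuracy")] <-
      round2(r[, c("sensitivity", "specificity", "accuracy")])
    print(r, row.names = FALSE)
  }
  invisible(x)
}
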