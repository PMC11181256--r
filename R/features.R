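#' Extract one feature combination from a lesion
#'
#' Dispatches to [ggcm_features()] on the lesion's GGCM, [glcm48()] or
#' [glcm51()] according to `combination`.
#'
#' @param x an [lesion()] object.
#' @param combination `"GGCM15"` (15 gray-gradient features, the best
#'   performer), `"GLCM48"` (48 co-occurrence features) or
#'   `"GLCM48_PLUS_GLOBAL3"` (the 48 plus 3 global gray statistics).
#' @param ... passed to the underlying extractor.
#' @return named numeric feature vector with attribute `combination_id`.
#' @export
extract_features <- function(x, combination = c("GGCM15", "GLCM48",
                                                "GLCM48_PLUS_GLOBAL3"), ...) {
  combination <- match.arg(combination)
  switch(combination,
         GGCM15 = ggcm_features(compute_ggcm(x, ...)),
         GLCM48 = glcm48(x, ...),
         GLCM48_PLUS_GLOBAL3 = glcm51(x, ...))
}

#' Build a feature table for a cohort
#'
#' Applies [extract_features()] to every lesion and assembles the tidy table
#' the classifier consumes: one row per lesion, `lesion_id` and `label`
#' columns followed by the feature columns in their canonical order.
#'
#' @param lesions list of `eus_lesion` objects.
#' @inheritParams extract_features
#' @return data.frame with attribute `combination_id`.
#' @export
feature_table <- function(lesions, combination = c("GGCM15", "GLCM48",
                                                   "GLCM48_PLUS_GLOBAL3"), ...) {
  combination <- match.arg(combination)
  rows <- lapply(lesions, function(l) extract_features(l, combination, ...))
  tab <- as.data.frame(do.call(rbind, rows))
  out <- cbind(
    data.frame(lesion_id = vapply(lesions, `[[`, "", "lesion_id"),
               label = vapply(lesions, `[[`, "", "label"),
               stringsAsFactors = FALSE),
    tab
  )
  attr(out, "combination_id") <- combination
  out
}

#' Write / read a feature table CSV
#'
#' Deterministic column order (`lesion_id`, `label`, features); the
#' combination id travels in a `combination_id` column so round-trips keep it.
#'
#' @param tab a feature table from [feature_table()].
#' @param path CSV path.
#' @export
write_feature_table <- function(tab, path) {
  out <- cbind(combination_id = attr(tab, "combination_id") %||% NA_character_,
               tab)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cid <- NULL
  if ("combination_id" %in% names(tab)) {
    cid <- tab$combination_id[1L]
    tab$combination_id <- NULL
  }
  attr(tab, "combination_id") <- cid
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a feature table into (matrix, labels, ids)
unpack_feature_table <- function(tab) {
  meta <- intersect(c("lesion_id", "label"), names(tab))
  x <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, labels = tab$label, ids = tab$lesion_id %||% rownames(tab))
}
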