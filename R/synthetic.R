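#' Specification of a synthetic EUS-like cohort
#'
#' Describes a cohort of speckled, hypoechoic 8-bit lesion textures with a
#' controllable between-class difference. Each lesion is a unit-mean
#' multiplicative gamma speckle field, Gaussian-smoothed with a
#' class-specific correlation length, renormalized to a fixed dispersion,
#' scaled by a lesion-specific echo gain (emulating non-standardized
#' acquisition gain) around a low base intensity, and clipped/rounded to
#' 0-255 inside a randomized radial polygon ROI. The class difference enters
#' only through the smoothing sigma, i.e. through the texture correlation
#' length and hence the gradient statistics, not through mean brightness.
#'
#' @param n_pos,n_neg lesions per class (default 59 GISTs / 61 non-GISTs,
#'   the balance of the clinical cohort the pipeline targets).
#' @param image_size image side in pixels.
#' @param roi_radius_range min/max mean polygon radius in pixels.
#' @param base_intensity mean gray of the lesion before gain (hypoechoic,
#'   default 60).
#' @param speckle_scale dispersion (coefficient of variation) of the speckle
#'   field; gamma shape is `1 / speckle_scale^2`.
#' @param smooth_sigma_pos,smooth_sigma_neg Gaussian smoothing sigma (pixels)
#'   for the positive / negative class; equal sigmas give an exchangeable
#'   null cohort.
#' @param gain_range per-lesion multiplicative gain range, drawn uniformly
#'   and independently of class.
#' @param seed integer RNG seed for the whole cohort.
#' @return object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_pos = 59L, n_neg = 61L, image_size = 160L,
                        roi_radius_range = c(40, 56), base_intensity = 60,
                        speckle_scale = 0.5, smooth_sigma_pos = 10,
                        smooth_sigma_neg = 1, gain_range = c(0.75, 1.25),
                        seed = 1L) {
  stopifnot(n_pos >= 2, n_neg >= 2, image_size >= 32,
            length(roi_radius_range) == 2L,
            roi_radius_range[1L] >= 4, roi_radius_range[2L] <= image_size / 2,
            base_intensity > 0, base_intensity < 255,
            speckle_scale >= 0, smooth_sigma_pos > 0, smooth_sigma_neg > 0,
            length(gain_range) == 2L, gain_range[1L] > 0,
            gain_range[2L] >= gain_range[1L])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 image_size = as.integer(image_size),
                 roi_radius_range = as.numeric(roi_radius_range),
                 base_intensity = base_intensity,
                 speckle_scale = speckle_scale,
                 smooth_sigma_pos = smooth_sigma_pos,
                 smooth_sigma_neg = smooth_sigma_neg,
                 gain_range = as.numeric(gain_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d pos / %d neg, %dpx, base %g, ",
                     "speckle %g, sigma %g/%g, gain [%g, %g], seed %d\n"),
              x$n_pos, x$n_neg, x$image_size, x$base_intensity,
              x$speckle_scale, x$smooth_sigma_pos, x$smooth_sigma_neg,
              x$gain_range[1L], x$gain_range[2L], x$seed))
  invisible(x)
}

#' Generate one synthetic lesion
#'
#' Uses the current RNG state, or seeds it when `seed` is given (same seed =>
#' bit-identical lesion).
#'
#' @param spec a [cohort_spec()].
#' @param label `"GIST"` (positive: smoothing `smooth_sigma_pos`) or
#'   `"non-GIST"` (negative: `smooth_sigma_neg`).
#' @param lesion_id identifier.
#' @param seed optional integer seed.
#' @param min_pixels smallest acceptable ROI (as in [load_lesion()]).
#' @return an `eus_lesion` with an extra attribute `roi_polygon` (the vertex
#'   matrix used, for writing to disk).
#' @export
generate_lesion <- function(spec, label = c("GIST", "non-GIST"),
                            lesion_id = "synthetic", seed = NULL,
                            min_pixels = 64L) {
  stopifnot(inherits(spec, "cohort_spec"))
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  S <- spec$image_size
  s <- spec$speckle_scale
  sigma <- if (label == "GIST") spec$smooth_sigma_pos else spec$smooth_sigma_neg
  gain <- runif(1L, spec$gain_range[1L], spec$gain_range[2L])
  if (s > 1e-8) {
    k <- 1 / s^2
    raw <- matrix(rgamma(S * S, shape = k, rate = k), S, S)
    sm <- as.matrix(EBImage::gblur(raw, sigma = sigma))
    sdev <- sd(as.vector(sm))
    # renormalize to unit mean / dispersion s: the class difference stays in
    # the correlation length, first-order statistics are matched
    field <- if (sdev > 0) 1 + s * (sm - mean(sm)) / sdev else matrix(1, S, S)
  } else {
    field <- matrix(1, S, S)
  }
  px <- pmax(0L, pmin(255L, as.integer(round(spec$base_intensity * gain * field))))
  dim(px) <- c(S, S)
  # randomized radial polygon around a jittered center
  ctr <- S / 2 + runif(2L, -S / 10, S / 10)
  r0 <- runif(1L, spec$roi_radius_range[1L], spec$roi_radius_range[2L])
  nv <- sample(8:14, 1L)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- r0 * runif(nv, 0.85, 1.15)
  poly <- cbind(pmin(S - 2, pmax(1, ctr[1L] + rad * sin(ang))),
                pmin(S - 2, pmax(1, ctr[2L] + rad * cos(ang))))
  rm <- rasterize_polygon(poly, c(S, S))
  if (sum(rm$mask) < min_pixels) {
    stop(sprintf("generated ROI below minimum size (%d px)", sum(rm$mask)))
  }
  out <- lesion(px, rm$mask, label = label, lesion_id = lesion_id)
  attr(out, "roi_polygon") <- poly
  out
}

#' Generate a labeled synthetic cohort
#'
#' Positives then negatives, drawn sequentially from `spec$seed`, fully
#' reproducible from the spec alone. When `dir` is given the cohort is
#' written in the on-disk layout [load_cohort()] consumes: `images/*.png`,
#' `rois/*.json` and `manifest.csv` (columns `lesion_id`, `image_path`,
#' `roi_path`, `label`, paths relative to `dir`).
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @return list with `lesions` (list of `eus_lesion`) and `manifest`
#'   (data.frame); when `dir` is given, also `manifest_path`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ids <- c(sprintf("pos_%03d", seq_len(spec$n_pos)),
           sprintf("neg_%03d", seq_len(spec$n_neg)))
  labs <- rep(c("GIST", "non-GIST"), c(spec$n_pos, spec$n_neg))
  lesions <- mapply(function(id, lb) generate_lesion(spec, lb, lesion_id = id),
                    ids, labs, SIMPLIFY = FALSE)
  manifest <- data.frame(lesion_id = ids,
                         image_path = file.path("images", paste0(ids, ".png")),
                         roi_path = file.path("rois", paste0(ids, ".json")),
                         label = labs, stringsAsFactors = FALSE)
  out <- list(lesions = lesions, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "rois"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(lesions)) {
      write_gray_image(lesions[[i]]$pixels, file.path(dir, manifest$image_path[i]))
      write_roi(attr(lesions[[i]], "roi_polygon"),
                file.path(dir, manifest$roi_path[i]))
    }
    out$manifest_path <- file.path(dir, "manifest.csv")
    write.csv(manifest, out$manifest_path, row.names = FALSE)
  }
  out
}
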