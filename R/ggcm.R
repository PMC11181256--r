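# natural-log Shannon entropy of a (sub)probability vector/matrix
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sobel gradient magnitude over the ROI interior
#'
#' Applies the standard 3x3 Sobel kernels
#' `Gx = [[-1,0,1],[-2,0,2],[-1,0,1]]` (column direction) and its transpose
#' `Gy` (row direction) and returns `sqrt(Gx^2 + Gy^2)`. Only pixels of the
#' interior mask carry a valid gradient: anywhere else the 3x3 window would
#' leave the ROI (or the image), so those pixels are excluded from all
#' gradient statistics.
#'
#' @param x an [lesion()] object with non-empty interior mask and image of at
#'   least 3x3 pixels.
#' @return Object of class `gradient_field`: list with `magnitude` (numeric
#'   matrix, zero outside the computable core) and `support` (logical matrix,
#'   the lesion's interior mask).
#' @export
sobel_gradient <- function(x) {
  stopifnot(inherits(x, "eus_lesion"))
  h <- nrow(x$pixels); w <- ncol(x$pixels)
  if (h < 3L || w < 3L) stop("image must be at least 3x3 for gradients")
  if (!any(x$interior)) stop("empty interior mask")
  p <- x$pixels
  rr <- 2:(h - 1L); cc <- 2:(w - 1L)
  S <- function(dr, dc) p[rr + dr, cc + dc, drop = FALSE]
  gx <- (S(-1L, 1L) + 2 * S(0L, 1L) + S(1L, 1L)) -
        (S(-1L, -1L) + 2 * S(0L, -1L) + S(1L, -1L))
  gy <- (S(1L, -1L) + 2 * S(1L, 0L) + S(1L, 1L)) -
        (S(-1L, -1L) + 2 * S(-1L, 0L) + S(-1L, 1L))
  mag <- matrix(0, h, w)
  mag[rr, cc] <- sqrt(gx^2 + gy^2)
  structure(list(magnitude = mag, support = x$interior),
            class = "gradient_field")
}

#' Quantize a gradient field to discrete levels
#'
#' Per-lesion max scaling: `q = floor(m * levels / gmax)` clipped to
#' `levels - 1`, where `gmax` is the largest magnitude on the support, so the
#' maximum maps to the top level. An all-zero field maps entirely to level 0.
#' Scaling by the per-lesion maximum (rather than a fixed ceiling) removes
#' dependence on absolute echo gain.
#'
#' @param field a `gradient_field`.
#' @param levels number of gradient levels (default 32).
#' @return the field with an added `quantized` integer matrix (valid on
#'   `support`, `NA` elsewhere) and `levels`.
#' @export
quantize_gradient <- function(field, levels = 32L) {
  stopifnot(inherits(field, "gradient_field"), levels >= 2)
  m <- field$magnitude[field$support]
  gmax <- max(m)
  qv <- if (gmax <= 0) rep(0L, length(m)) else
    pmin(as.integer(floor(m * levels / gmax)), levels - 1L)
  q <- matrix(NA_integer_, nrow(field$magnitude), ncol(field$magnitude))
  q[field$support] <- qv
  field$quantized <- q
  field$levels <- as.integer(levels)
  field
}

#' Gray-gradient co-occurrence matrix
#'
#' `counts[i+1, j+1]` is the number of interior-mask pixels whose gray value
#' is `i` (full 256 levels by default, unquantized) and whose quantized Sobel
#' gradient magnitude is `j` (32 levels by default).
#'
#' @param x an [lesion()] object.
#' @param gray_levels gray-axis bins (default 256, i.e. raw intensities).
#' @param gradient_levels gradient-axis bins (default 32).
#' @return Object of class `ggcm`: list with `counts`
#'   (`gray_levels x gradient_levels` integer matrix), `n_pixels`,
#'   `gray_levels`, `gradient_levels`.
#' @export
compute_ggcm <- function(x, gray_levels = 256L, gradient_levels = 32L) {
  gf <- quantize_gradient(sobel_gradient(x), gradient_levels)
  g <- x$pixels[gf$support]
  if (gray_levels != 256L) g <- (g * as.integer(gray_levels)) %/% 256L
  j <- gf$quantized[gf$support]
  counts <- matrix(tabulate(g * gradient_levels + j + 1L,
                            gray_levels * gradient_levels),
                   gray_levels, gradient_levels, byrow = TRUE)
  structure(list(counts = counts, n_pixels = length(g),
                 gray_levels = as.integer(gray_levels),
                 gradient_levels = as.integer(gradient_levels)),
            class = "ggcm")
}

#' @export
print.ggcm <- function(x, ...) {
  cat(sprintf("<ggcm> %d x %d (gray x gradient), %d pixels\n",
              x$gray_levels, x$gradient_levels, x$n_pixels))
  invisible(x)
}

#' The 15 GGCM texture features (feature combination 3)
#'
#' Classical gray-gradient co-occurrence descriptors. With `H` the counts,
#' `T = n_pixels`, `p(i, j) = H(i, j)/T`, gray marginal `p_g`, gradient
#' marginal `p_s`, marginal means/SDs `mu_g, sigma_g, mu_s, sigma_s` and
#' 0-based indices `i` (gray) and `j` (gradient):
#' \enumerate{
#'   \item small-gradient dominance `sum_j H_s(j)/(j+1)^2 / T`
#'   \item large-gradient dominance `sum_j j^2 H_s(j) / T`
#'   \item gray heterogeneity `sum_i H_g(i)^2 / T`
#'   \item gradient heterogeneity `sum_j H_s(j)^2 / T`
#'   \item energy `sum p^2`
#'   \item gray average `mu_g`
#'   \item gradient average `mu_s`
#'   \item gray mean square error `sigma_g`
#'   \item gradient mean square error `sigma_s`
#'   \item correlation `sum (i - mu_g)(j - mu_s) p(i, j)`
#'   \item gray entropy `-sum p_g log p_g`
#'   \item gradient entropy `-sum p_s log p_s`
#'   \item hybrid entropy `-sum p log p`
#'   \item inertia `sum (i - j)^2 p(i, j)`
#'   \item inverse difference moment `sum p(i, j) / (1 + (i - j)^2)`
#' }
#' Entropies use the natural log with `0 log 0 = 0`. `H_g`/`H_s` are the
#' gray/gradient marginal counts.
#'
#' @param H a `ggcm`, or a plain non-negative counts matrix (gray rows x
#'   gradient columns).
#' @return named numeric vector of length 15, ordered as above, with
#'   attribute `combination_id = "GGCM15"`.
#' @export
ggcm_features <- function(H) {
  counts <- if (inherits(H, "ggcm")) H$counts else as.matrix(H)
  if (any(counts < 0)) stop("negative counts")
  T_ <- sum(counts)
  if (T_ < 1) stop("empty GGCM")
  ng <- nrow(counts); ns <- ncol(counts)
  i <- 0:(ng - 1L); j <- 0:(ns - 1L)
  p <- counts / T_
  Hg <- rowSums(counts); Hs <- colSums(counts)
  pg <- Hg / T_; ps <- Hs / T_
  mug <- sum(i * pg); mus <- sum(j * ps)
  sg <- sqrt(max(0, sum(i^2 * pg) - mug^2))
  ss <- sqrt(max(0, sum(j^2 * ps) - mus^2))
  dij <- outer(i, j, "-")
  out <- c(
    small_gradient_dominance  = sum(Hs / (j + 1)^2) / T_,
    large_gradient_dominance  = sum(j^2 * Hs) / T_,
    gray_heterogeneity        = sum(Hg^2) / T_,
    gradient_heterogeneity    = sum(Hs^2) / T_,
    energy                    = sum(p^2),
    gray_average              = mug,
    gradient_average          = mus,
    gray_mean_square_error    = sg,
    gradient_mean_square_error = ss,
    correlation               = as.numeric(t(i - mug) %*% p %*% (j - mus)),
    gray_entropy              = shannon(pg),
    gradient_entropy          = shannon(ps),
    hybrid_entropy            = shannon(p),
    inertia                   = sum(dij^2 * p),
    inverse_difference_moment = sum(p / (1 + dij^2))
  )
  attr(out, "combination_id") <- "GGCM15"
  out
}
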