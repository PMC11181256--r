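# Cached level-difference helper matrices for the descriptor sums; a 256x256
# outer difference is rebuilt thousands of times otherwise.
level_diff2 <- function(levels) {
  key <- paste0("d2_", levels)
  if (is.null(.eustex_cache[[key]])) {
    a <- 0:(levels - 1L)
    .eustex_cache[[key]] <- outer(a, a, "-")^2
  }
  .eustex_cache[[key]]
}
level_homog <- function(levels, kernel) {
  key <- paste0("h_", kernel, "_", levels)
  if (is.null(.eustex_cache[[key]])) {
    a <- 0:(levels - 1L)
    d <- outer(a, a, "-")
    .eustex_cache[[key]] <-
      if (kernel == "abs") 1 / (1 + abs(d)) else 1 / (1 + d^2)
  }
  .eustex_cache[[key]]
}

# displacement (d_row, d_col) for a direction in degrees
angle_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix of a masked ROI
#'
#' Counts ordered pixel pairs (p, q) where q is displaced from p by distance
#' `d` along direction `theta` and *both* pixels lie inside the ROI mask.
#' Direction-to-offset convention (rows grow downward): 0 deg -> (0, +d),
#' 45 deg -> (-d, +d), 90 deg -> (-d, 0), 135 deg -> (-d, -d). The matrix is
#' not symmetrized: one ordered displacement per (d, theta). Gray values are
#' quantized to `levels` bins by `floor(g * levels / 256)` (identity at the
#' default 256).
#'
#' @param x an [lesion()] object.
#' @param d pixel distance, >= 1.
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels (power of two up to 256).
#' @return Object of class `cooc_matrix`: list with `counts`
#'   (`levels x levels` integer matrix, `counts[a+1, b+1]` = pairs with gray
#'   `a` at p and `b` at q), `d`, `theta`, `levels`, `n_pairs`.
#' @examples
#' les <- lesion(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE) * 255)
#' compute_glcm(les, d = 1, theta = 0, levels = 2)$counts
#' @export
compute_glcm <- function(x, d = 1L, theta = 0L, levels = 256L) {
  stopifnot(inherits(x, "eus_lesion"), d >= 1)
  d <- as.integer(d)
  off <- angle_offset(theta, d)
  dr <- off[1L]; dc <- off[2L]
  h <- nrow(x$pixels); w <- ncol(x$pixels)
  r1a <- max(1L, 1L - dr); r1b <- min(h, h - dr)
  c1a <- max(1L, 1L - dc); c1b <- min(w, w - dc)
  if (r1a > r1b || c1a > c1b) {
    stop(sprintf("no valid pixel pairs for d=%d, theta=%d", d, theta))
  }
  rr <- r1a:r1b; cc <- c1a:c1b
  sel <- x$mask[rr, cc, drop = FALSE] & x$mask[rr + dr, cc + dc, drop = FALSE]
  if (!any(sel)) stop(sprintf("no valid pixel pairs for d=%d, theta=%d", d, theta))
  q <- if (levels == 256L) x$pixels else (x$pixels * as.integer(levels)) %/% 256L
  a <- q[rr, cc, drop = FALSE][sel]
  b <- q[rr + dr, cc + dc, drop = FALSE][sel]
  counts <- matrix(tabulate(a * levels + b + 1L, levels * levels),
                   levels, levels, byrow = TRUE)
  structure(list(counts = counts, d = d, theta = as.integer(theta),
                 levels = as.integer(levels), n_pairs = length(a)),
            class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat(sprintf("<cooc_matrix> %d levels, d=%d theta=%d, %d pairs\n",
              x$levels, x$d, x$theta, x$n_pairs))
  invisible(x)
}

#' Haralick-style descriptors of a co-occurrence matrix
#'
#' With `p(a, b) = counts[a, b] / n_pairs`:
#' contrast `= sum (a-b)^2 p`, energy `= sum p^2`, homogeneity
#' `= sum p / (1 + |a-b|)` (or `1/(1+(a-b)^2)` with
#' `kernel = "squared"`; both forms are in common use), and correlation
#' `= sum (a - mu_r)(b - mu_c) p / (sigma_r sigma_c)` with marginal
#' means/SDs, defined as 0 when either marginal SD is zero so that all
#' features stay finite.
#'
#' @param m a `cooc_matrix`.
#' @param kernel homogeneity kernel, `"abs"` (default) or `"squared"`.
#' @return named numeric: `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_descriptors <- function(m, kernel = c("abs", "squared")) {
  stopifnot(inherits(m, "cooc_matrix"), m$n_pairs >= 1)
  kernel <- match.arg(kernel)
  L <- m$levels
  p <- m$counts / m$n_pairs
  contrast <- sum(p * level_diff2(L))
  homogeneity <- sum(p * level_homog(L, kernel))
  energy <- sum(p^2)
  a <- 0:(L - 1L)
  pr <- rowSums(p); pc <- colSums(p)
  mur <- sum(a * pr); muc <- sum(a * pc)
  sr <- sqrt(max(0, sum(a^2 * pr) - mur^2))
  sc <- sqrt(max(0, sum(a^2 * pc) - muc^2))
  correlation <- if (sr * sc <= 0) 0 else
    as.numeric(t(a - mur) %*% p %*% (a - muc)) / (sr * sc)
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' The 48 GLCM features (feature combination 1)
#'
#' One co-occurrence matrix per (distance, direction) pair — 3 distances x
#' 4 directions by default — and four descriptors each: 48 features, ordered
#' distance-major, then direction (0, 45, 90, 135), then
#' (contrast, correlation, energy, homogeneity). Names encode the triple,
#' e.g. `d2_a90_energy`.
#'
#' @inheritParams compute_glcm
#' @param distances integer vector of pixel distances.
#' @param angles directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @param kernel homogeneity kernel, see [glcm_descriptors()].
#' @return named numeric vector with attribute `combination_id = "GLCM48"`.
#' @export
glcm48 <- function(x, distances = c(1L, 2L, 3L), angles = c(0L, 45L, 90L, 135L),
                   levels = 256L, kernel = "abs") {
  out <- numeric(0)
  for (d in distances) {
    for (th in angles) {
      desc <- glcm_descriptors(compute_glcm(x, d = d, theta = th, levels = levels),
                               kernel = kernel)
      names(desc) <- sprintf("d%d_a%d_%s", d, th, names(desc))
      out <- c(out, desc)
    }
  }
  attr(out, "combination_id") <- "GLCM48"
  out
}

#' Global gray statistics of the ROI (the 3 extra features of combination 2)
#'
#' First-order statistics of the in-mask intensity distribution: Shannon
#' entropy of the 256-bin normalized histogram (natural log, `0 log 0 = 0`),
#' mean intensity, and population standard deviation.
#'
#' @param x an `eus_lesion`.
#' @return named numeric: `entropy`, `mean`, `sd`.
#' @export
global_gray_features <- function(x) {
  stopifnot(inherits(x, "eus_lesion"))
  g <- x$pixels[x$mask]
  m <- mean(g)
  s <- sqrt(mean((g - m)^2))
  h <- tabulate(g + 1L, 256L) / length(g)
  h <- h[h > 0]
  c(entropy = -sum(h * log(h)), mean = m, sd = s)
}

#' The 51-feature combination (48 GLCM + 3 global gray features)
#'
#' @inheritParams glcm48
#' @return named numeric vector of length 51 with attribute
#'   `combination_id = "GLCM48_PLUS_GLOBAL3"`; the first 48 entries are
#'   [glcm48()], the last 3 are [global_gray_features()] prefixed `global_`.
#' @export
glcm51 <- function(x, distances = c(1L, 2L, 3L), angles = c(0L, 45L, 90L, 135L),
                   levels = 256L, kernel = "abs") {
  f48 <- glcm48(x, distances, angles, levels, kernel)
  g3 <- global_gray_features(x)
  names(g3) <- paste0("global_", names(g3))
  out <- c(f48, g3)
  attr(out, "combination_id") <- "GLCM48_PLUS_GLOBAL3"
  out
}
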