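# Independent brute-force oracles. Everything here is written as a direct,
# slow transcription of the definitions, deliberately sharing no code with
# the package implementation.

# point-in-polygon: even-odd ray casting on a single point, plus explicit
# on-segment test
oracle_point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    # on-segment?
    d <- abs((px - vx[k]) * (vy[k2] - vy[k]) - (py - vy[k]) * (vx[k2] - vx[k]))
    if (d < 1e-9 &&
        px >= min(vx[k], vx[k2]) - 1e-9 && px <= max(vx[k], vx[k2]) + 1e-9 &&
        py >= min(vy[k], vy[k2]) - 1e-9 && py <= max(vy[k], vy[k2]) + 1e-9) {
      return(TRUE)
    }
  }
  inside <- FALSE
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    if ((vy[k] > py) != (vy[k2] > py)) {
      xint <- (vx[k2] - vx[k]) * (py - vy[k]) / (vy[k2] - vy[k]) + vx[k]
      if (px < xint) inside <- !inside
    }
  }
  inside
}

oracle_rasterize <- function(vertices, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      m[r, c] <- oracle_point_in_polygon(r - 1, c - 1,
                                         vertices[, 1], vertices[, 2])
    }
  }
  m
}

# erosion: a pixel is interior iff its full 3x3 neighborhood exists and is
# in the mask
oracle_erode <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (!mask[r, c]) next
      ok <- r > 1 && r < h && c > 1 && c < w
      if (ok) {
        for (dr in -1:1) for (dc in -1:1) {
          if (!mask[r + dr, c + dc]) ok <- FALSE
        }
      }
      out[r, c] <- ok
    }
  }
  out
}

# GLCM: enumerate every pixel, apply the displacement, count in-mask pairs
oracle_glcm_counts <- function(pixels, mask, d, theta, levels = 256) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  q <- floor(pixels * levels / 256)
  h <- nrow(pixels); w <- ncol(pixels)
  counts <- matrix(0L, levels, levels)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (mask[r, c] && mask[r2, c2]) {
        a <- q[r, c]; b <- q[r2, c2]
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1L
      }
    }
  }
  counts
}

oracle_glcm_descriptors <- function(counts) {
  n <- sum(counts)
  L <- nrow(counts)
  contrast <- energy <- homog <- 0
  mur <- muc <- vr <- vc <- cov <- 0
  p <- counts / n
  for (a in 0:(L - 1)) for (b in 0:(L - 1)) {
    pab <- p[a + 1, b + 1]
    contrast <- contrast + (a - b)^2 * pab
    energy <- energy + pab^2
    homog <- homog + pab / (1 + abs(a - b))
    mur <- mur + a * pab
    muc <- muc + b * pab
  }
  for (a in 0:(L - 1)) for (b in 0:(L - 1)) {
    pab <- p[a + 1, b + 1]
    vr <- vr + (a - mur)^2 * pab
    vc <- vc + (b - muc)^2 * pab
    cov <- cov + (a - mur) * (b - muc) * pab
  }
  corr <- if (sqrt(vr) * sqrt(vc) <= 0) 0 else cov / (sqrt(vr) * sqrt(vc))
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog)
}

# GGCM descriptors by direct double loops over the full grid
oracle_ggcm_features <- function(counts) {
  T_ <- sum(counts)
  ng <- nrow(counts); ns <- ncol(counts)
  Hg <- rowSums(counts); Hs <- colSums(counts)
  pg <- Hg / T_; ps <- Hs / T_
  sgd <- lgd <- 0
  for (j in 0:(ns - 1)) {
    sgd <- sgd + Hs[j + 1] / (j + 1)^2
    lgd <- lgd + j^2 * Hs[j + 1]
  }
  mug <- sum((0:(ng - 1)) * pg); mus <- sum((0:(ns - 1)) * ps)
  sg <- sqrt(sum(((0:(ng - 1)) - mug)^2 * pg))
  ss <- sqrt(sum(((0:(ns - 1)) - mus)^2 * ps))
  energy <- corr <- hyb <- inertia <- idm <- 0
  for (i in 0:(ng - 1)) for (j in 0:(ns - 1)) {
    pij <- counts[i + 1, j + 1] / T_
    energy <- energy + pij^2
    corr <- corr + (i - mug) * (j - mus) * pij
    if (pij > 0) hyb <- hyb - pij * log(pij)
    inertia <- inertia + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
  }
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  c(small_gradient_dominance = sgd / T_,
    large_gradient_dominance = lgd / T_,
    gray_heterogeneity = sum(Hg^2) / T_,
    gradient_heterogeneity = sum(Hs^2) / T_,
    energy = energy, gray_average = mug, gradient_average = mus,
    gray_mean_square_error = sg, gradient_mean_square_error = ss,
    correlation = corr, gray_entropy = ent(pg), gradient_entropy = ent(ps),
    hybrid_entropy = hyb, inertia = inertia,
    inverse_difference_moment = idm)
}

# AUC as the exhaustive fraction of concordant (positive, negative) pairs,
# ties counting one half
oracle_auc <- function(scores, labels, positive = "GIST") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# fast rank-based AUC for bootstrap oracles (independent of pROC)
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# random masked lesion fixture; mask grown until it has enough pairs
random_lesion <- function(h, w, p_mask = 0.7, label = "GIST",
                          id = "rand") {
  px <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
  m <- matrix(runif(h * w) < p_mask, h, w)
  m[sample(h * w, 1)] <- TRUE
  lesion(px, m, label = label, lesion_id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
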