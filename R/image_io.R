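#' Construct an annotated lesion in memory
#'
#' Bundles an 8-bit grayscale pixel grid, a boolean ROI mask and a class label
#' into the container every texture operator consumes. The interior mask (the
#' ROI eroded so that every retained pixel has its full 3x3 neighborhood inside
#' the ROI) is derived here; gradient-based features are supported on it.
#'
#' @param pixels integer matrix, values 0-255.
#' @param mask logical matrix congruent with `pixels`; `NULL` means all-true.
#' @param label class label string; the positive class is `"GIST"` by
#'   convention, but any two labels work downstream.
#' @param lesion_id identifier string.
#' @return An object of class `eus_lesion`: a list with elements `pixels`,
#'   `mask`, `interior` (both logical matrices), `label`, `lesion_id`.
#' @examples
#' les <- lesion(matrix(0:15, 4, 4), label = "GIST")
#' sum(les$mask)      # 16
#' sum(les$interior)  # 4: the 2x2 core of a 4x4 grid
#' @export
lesion <- function(pixels, mask = NULL, label = "GIST", lesion_id = "lesion") {
  pixels <- as.matrix(pixels)
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > 255) ||
      any(pixels != floor(pixels))) {
    stop("pixels must be integers in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  }
  mask <- as.matrix(mask)
  if (!is.logical(mask) || !identical(dim(mask), dim(pixels))) {
    stop("mask must be a logical matrix congruent with pixels")
  }
  if (!any(mask)) stop("mask is empty")
  if (length(label) != 1L || is.na(label)) stop("label must be a single value")
  structure(
    list(pixels = pixels, mask = mask, interior = erode3x3(mask),
         label = as.character(label), lesion_id = as.character(lesion_id)),
    class = "eus_lesion"
  )
}

#' @export
print.eus_lesion <- function(x, ...) {
  cat(sprintf("<eus_lesion> %s  [%d x %d]  label=%s  ROI=%d px (interior %d)\n",
              x$lesion_id, nrow(x$pixels), ncol(x$pixels), x$label,
              sum(x$mask), sum(x$interior)))
  invisible(x)
}

#' Erode a boolean mask by a 3x3 box
#'
#' A pixel survives iff all 8 neighbors and itself are in the mask; pixels on
#' the image border never survive (their neighborhood leaves the image).
#'
#' @param mask logical matrix.
#' @return logical matrix of the same shape.
#' @export
erode3x3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  if (h < 3L || w < 3L) return(out)
  rr <- 2:(h - 1L); cc <- 2:(w - 1L)
  core <- mask[rr, cc, drop = FALSE]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    core <- core & mask[rr + dr, cc + dc, drop = FALSE]
  }
  out[rr, cc] <- core
  out
}

#' Rasterize a polygon ROI to a boolean mask
#'
#' A pixel belongs to the mask iff its center lies strictly inside the polygon
#' under the even-odd rule, or on the polygon boundary. Vertices are
#' `(row, col)` pairs, 0-based, and pixel (r, c) has its center at exactly
#' (r, c); vertices may be fractional.
#'
#' @param vertices numeric matrix with >= 3 rows and 2 columns (row, col),
#'   interpreted as a closed ring (the last vertex connects back to the first).
#' @param shape integer vector `c(height, width)`.
#' @return An object of class `roi_mask`: list with `mask` and `interior`
#'   (the 3x3 erosion of `mask`), both logical `height x width` matrices.
#' @examples
#' m <- rasterize_polygon(rbind(c(3, 2), c(3, 5), c(4, 5), c(4, 2)), c(10, 10))
#' sum(m$mask)  # 8
#' @export
rasterize_polygon <- function(vertices, shape) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    stop("polygon needs at least 3 (row, col) vertices")
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex")
  vy <- vertices[, 1L]; vx <- vertices[, 2L]
  n <- length(vy)
  # shoelace area; zero => degenerate polygon
  area <- abs(sum(vx * vy[c(2:n, 1L)] - vx[c(2:n, 1L)] * vy)) / 2
  if (area <= 0) stop("degenerate polygon (zero area)")
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  py <- matrix(0:(h - 1L), h, w)         # pixel-center rows
  px <- matrix(0:(w - 1L), h, w, byrow = TRUE)  # pixel-center cols
  inside <- matrix(FALSE, h, w)
  on_edge <- matrix(FALSE, h, w)
  tol <- 1e-9 * max(1, max(abs(vertices)))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    y1 <- vy[k]; x1 <- vx[k]; y2 <- vy[k2]; x2 <- vx[k2]
    # boundary: point collinear with the edge and within its bounding box
    cr <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg <- abs(cr) <= tol * max(1, abs(y2 - y1) + abs(x2 - x1)) &
      px >= min(x1, x2) - tol & px <= max(x1, x2) + tol &
      py >= min(y1, y2) - tol & py <= max(y1, y2) + tol
    on_edge <- on_edge | seg
    # even-odd ray cast (ray towards +col); half-open vertex rule
    straddles <- (y1 > py) != (y2 > py)
    xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
    crossing <- straddles & (px < xint)
    crossing[is.na(crossing)] <- FALSE
    inside <- xor(inside, crossing)
  }
  mask <- inside | on_edge
  structure(list(mask = mask, interior = erode3x3(mask)), class = "roi_mask")
}

# ITU-R BT.601 luma, rounded half-up, on 0-255 channels
luma601 <- function(r, g, b) {
  as.integer(floor(0.299 * r + 0.587 * g + 0.114 * b + 0.5))
}

#' Read an 8-bit grayscale image (PNG or BMP)
#'
#' PNG is read through the \pkg{png} package; uncompressed 8-bit palette and
#' 24-bit Windows BMP are read natively. Color inputs are converted to gray by
#' ITU-R BT.601 luma (0.299 R + 0.587 G + 0.114 B), rounded half-up, so the
#' conversion is deterministic and bit-exact.
#'
#' @param path file path; format sniffed from the magic bytes.
#' @return integer matrix of intensities 0-255.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  magic <- readBin(path, "raw", n = 2L)
  if (identical(rawToChar(magic), "BM")) return(read_bmp(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) {
    m <- round(a * 255)
  } else {
    nch <- dim(a)[3L]
    if (nch >= 3L) {
      m <- luma601(round(a[, , 1L] * 255), round(a[, , 2L] * 255),
                   round(a[, , 3L] * 255))
      dim(m) <- dim(a)[1:2]
    } else {
      m <- round(a[, , 1L] * 255)  # gray + alpha
    }
  }
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an 8-bit grayscale image (PNG or BMP)
#'
#' @param pixels integer matrix, values 0-255.
#' @param path output path; `.bmp` selects the native BMP writer (8-bit,
#'   grayscale palette), anything else is written as 8-bit gray PNG.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0 | pixels > 255)) stop("pixels must be in [0, 255]")
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) {
    write_bmp(pixels, path)
  } else {
    png::writePNG(pixels / 255, target = path)
  }
  invisible(path)
}

# ---- minimal Windows BMP codec (uncompressed, BITMAPINFOHEADER) -------------

read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u <- function(off, n) sum(as.double(raw[off + seq_len(n)]) * 256^(seq_len(n) - 1))
  if (u(0, 2) != 0x4d42) stop("not a BMP file: ", path)
  data_off <- u(10, 4)
  hdr <- u(14, 4)
  if (hdr < 40) stop("unsupported BMP header")
  width <- u(18, 4); height <- u(22, 4)
  if (height >= 2^31) height <- height - 2^32  # signed: negative = top-down
  topdown <- height < 0
  height <- abs(height)
  bpp <- u(28, 2); comp <- u(30, 4)
  if (comp != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(8, 24)) stop("only 8-bit and 24-bit BMP supported")
  stride <- 4 * ceiling(width * bpp / 8 / 4)
  out <- matrix(0L, height, width)
  if (bpp == 8) {
    ncol_pal <- u(46, 4); if (ncol_pal == 0) ncol_pal <- 256
    pal <- matrix(as.integer(raw[14 + hdr + seq_len(4 * ncol_pal)]), nrow = 4)
    lut <- luma601(pal[3L, ], pal[2L, ], pal[1L, ])  # entries stored B,G,R,X
    for (sr in seq_len(height)) {
      row <- as.integer(raw[data_off + (sr - 1) * stride + seq_len(width)])
      r <- if (topdown) sr else height - sr + 1L
      out[r, ] <- lut[row + 1L]
    }
  } else {
    for (sr in seq_len(height)) {
      row <- as.integer(raw[data_off + (sr - 1) * stride + seq_len(3 * width)])
      b <- row[seq(1L, by = 3L, length.out = width)]
      g <- row[seq(2L, by = 3L, length.out = width)]
      rch <- row[seq(3L, by = 3L, length.out = width)]
      r <- if (topdown) sr else height - sr + 1L
      out[r, ] <- luma601(rch, g, b)
    }
  }
  out
}

write_bmp <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  stride <- 4L * ((w + 3L) %/% 4L)
  data_size <- stride * h
  off <- 14L + 40L + 1024L
  le <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
  hdr <- c(charToRaw("BM"), le(off + data_size, 4), le(0, 4), le(off, 4),
           le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(8, 2), le(0, 4),
           le(data_size, 4), le(2835, 4), le(2835, 4), le(256, 4), le(0, 4))
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))  # gray B,G,R,X palette
  body <- raw(data_size)
  for (r in seq_len(h)) {
    sr <- h - r + 1L  # bottom-up storage
    body[(sr - 1L) * stride + seq_len(w)] <- as.raw(pixels[r, ])
  }
  writeBin(c(hdr, pal, body), path)
  invisible(path)
}

# ---- ROI polygon files ------------------------------------------------------

#' Read / write a polygon ROI file
#'
#' ROIs are exchanged as a JSON array of `[row, col]` vertex pairs (0-based
#' pixel coordinates, origin top-left), one file per lesion.
#'
#' @param path file path.
#' @return `read_roi`: numeric matrix of vertices, one `(row, col)` per row.
#' @export
read_roi <- function(path) {
  v <- jsonlite::fromJSON(path)
  v <- as.matrix(v)
  if (ncol(v) != 2L || nrow(v) < 3L) stop("ROI file must hold >= 3 [row, col] pairs")
  v
}

#' @rdname read_roi
#' @param vertices numeric matrix of `(row, col)` vertices.
#' @export
write_roi <- function(vertices, path) {
  jsonlite::write_json(unname(as.matrix(vertices)), path, digits = NA)
  invisible(path)
}

#' Load an annotated lesion from disk
#'
#' Reads the image and the ROI polygon, validates the polygon against the
#' image bounds, rasterizes it ([rasterize_polygon()]) and returns the
#' [lesion()] container.
#'
#' @param image_path path to an 8-bit grayscale PNG or BMP.
#' @param roi_path path to the ROI JSON polygon file.
#' @param label class label (positive class is `"GIST"`).
#' @param lesion_id identifier; defaults to the image file name.
#' @param min_pixels smallest acceptable ROI, in pixels. Co-occurrence
#'   statistics on fewer pixels are not meaningful; clinical lesions are
#'   orders of magnitude larger.
#' @return An `eus_lesion`.
#' @export
load_lesion <- function(image_path, roi_path, label,
                        lesion_id = sub("\\.[^.]+$", "", basename(image_path)),
                        min_pixels = 64L) {
  img <- read_gray_image(image_path)
  poly <- read_roi(roi_path)
  h <- nrow(img); w <- ncol(img)
  if (any(poly[, 1L] < 0 | poly[, 1L] > h - 1 | poly[, 2L] < 0 | poly[, 2L] > w - 1)) {
    stop("polygon out of image bounds in ", roi_path)
  }
  rm <- rasterize_polygon(poly, c(h, w))
  if (sum(rm$mask) < min_pixels) {
    stop(sprintf("ROI too small (%d px < %d) in %s", sum(rm$mask), min_pixels, roi_path))
  }
  lesion(img, rm$mask, label = label, lesion_id = lesion_id)
}

#' Enumerate masked pixels
#'
#' @param x an `eus_lesion`.
#' @return data.frame with columns `row`, `col` (0-based) and `intensity`,
#'   one row per in-mask pixel, in row-major order.
#' @export
masked_pixels <- function(x) {
  stopifnot(inherits(x, "eus_lesion"))
  rows <- row(x$mask)[x$mask]; cols <- col(x$mask)[x$mask]
  o <- order(rows, cols)
  data.frame(row = rows[o] - 1L, col = cols[o] - 1L,
             intensity = x$pixels[x$mask][o])
}

#' Load a cohort from a manifest
#'
#' The manifest is a CSV with columns `lesion_id`, `image_path`, `roi_path`,
#' `label`; relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @param min_pixels forwarded to [load_lesion()].
#' @return list of `eus_lesion` objects.
#' @export
load_cohort <- function(manifest_path, min_pixels = 64L) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "image_path", "roi_path", "label")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(man)), function(i) {
    load_lesion(resolve(man$image_path[i]), resolve(man$roi_path[i]),
                label = man$label[i], lesion_id = man$lesion_id[i],
                min_pixels = min_pixels)
  })
}
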