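## Contrast-enhancement and binarization chain applied before tracking.
##
## Images are plain integer matrices (rows = image rows from the top,
## columns = image columns) with gray levels on the 0-255 scale.  All
## public coordinates are image-frame: x = column, y = row from top,
## 0-based, pixel centers at integers, so pixel (x, y) is img[y+1, x+1].

#' Convert a raster to an 8-bit gray matrix
#'
#' Accepts the arrays produced by [tiff::readTIFF()] / [png::readPNG()]
#' (doubles in \[0, 1\], optionally with a channel dimension) as well as
#' integer matrices on the 0-255 or 16-bit scale, and returns a
#' single-channel integer matrix on 0-255.  Multi-channel input is
#' reduced by Rec. 709 luma (equal channels map to their common value);
#' higher bit depths are rescaled linearly so the maximum representable
#' value maps to 255.  An image that is already 8-bit gray passes
#' through unchanged.
#'
#' @param x matrix or array raster.
#' @return integer matrix with values in 0-255.
#' @examples
#' to_gray8(matrix(0.5, 2, 2))       # readPNG-style [0,1] input -> 128
#' @export
to_gray8 <- function(x) {
  if (is.null(x) || length(x) == 0L) stop_invalid("empty raster")
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc == 1L) {
      x <- x[, , 1L]
    } else {
      ## RGB(A): Rec. 709 luma on the first three channels
      w <- c(0.2126, 0.7152, 0.0722)[seq_len(min(nc, 3L))]
      w <- w / sum(w)
      y <- x[, , 1L] * w[1]
      for (k in seq_len(min(nc, 3L))[-1]) y <- y + x[, , k] * w[k]
      x <- y
    }
  }
  if (!is.matrix(x)) stop_invalid("raster must be a matrix or 2/3-d array")
  if (is.double(x) && max(x) <= 1 && min(x) >= 0) {
    out <- round_half_up(x * 255)
  } else if (max(x) > 255) {
    out <- round_half_up(as.numeric(x) * 255 / 65535)
  } else {
    out <- round_half_up(as.numeric(x))
  }
  storage.mode(out) <- "integer"
  matrix(clamp(out, 0L, 255L), nrow = nrow(x), ncol = ncol(x))
}

check_gray8 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid("image must be a numeric matrix")
  if (min(img) < 0 || max(img) > 255)
    stop_invalid("gray levels must lie in [0, 255]")
  invisible(img)
}

#' Histogram equalization
#'
#' Monotone gray-level remapping `v -> round(cdf(v) * 255 / N)` (round
#' half up), where `cdf(v)` is the cumulative count of pixels with level
#' at most `v` and `N` the pixel total.  Flattens the intensity
#' histogram to enhance contrast while preserving the rank order of gray
#' levels.  Single-gray-level images are returned unchanged.
#'
#' @param img integer gray matrix on 0-255.
#' @return equalized integer gray matrix.
#' @examples
#' img <- matrix(c(100, 100, 200, 200), 2)
#' equalize_hist(img)  # levels {100, 200} -> {128, 255}
#' @export
equalize_hist <- function(img) {
  check_gray8(img)
  lv <- as.integer(img)
  counts <- tabulate(lv + 1L, nbins = 256L)
  if (sum(counts > 0L) <= 1L) return(img)  # degenerate histogram
  cdf <- cumsum(counts) / length(lv)
  map <- as.integer(round_half_up(cdf * 255))
  out <- matrix(map[lv + 1L], nrow = nrow(img), ncol = ncol(img))
  out
}

#' Rectangular region of interest
#'
#' Integer pixel rectangle in image coordinates, inclusive on the
#' top/left and half-open on the bottom/right, clipped to the image when
#' applied.  Carrier for the locally applied binarization threshold.
#'
#' @param x0,y0 top-left corner (0-based, inclusive).
#' @param x1,y1 bottom-right corner (exclusive).
#' @return an object of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1) {
  x0 <- floor(x0); y0 <- floor(y0); x1 <- ceiling(x1); y1 <- ceiling(y1)
  if (x1 <= x0 || y1 <= y0) stop_invalid("empty roi")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "roi")
}

clip_roi <- function(r, img) {
  out <- roi(max(r$x0, 0), max(r$y0, 0),
             min(r$x1, ncol(img)), min(r$y1, nrow(img)))
  if (out$x1 <= out$x0 || out$y1 <= out$y0) stop_invalid("roi outside image")
  out
}

roi_full <- function(img) roi(0, 0, ncol(img), nrow(img))

#' Local threshold binarization
#'
#' Inside the region of interest, pixels with gray level `>= threshold`
#' become 255 and the rest 0; everything outside the region is 0.  The
#' threshold is treated as a local characteristic of the observed cell,
#' so the region is typically the tracked kernel's dilated bounding box.
#'
#' @param img integer gray matrix on 0-255.
#' @param threshold scalar threshold on the 0-255 scale.
#' @param roi a [roi()]; defaults to the whole image.
#' @return binary image with values in \{0, 255\}.
#' @examples
#' binarize(matrix(c(199, 200), 1), 200)  # 0 255
#' @export
binarize <- function(img, threshold, roi = roi_full(img)) {
  check_gray8(img)
  if (!is.finite(threshold) || threshold < 0 || threshold > 255)
    stop_invalid("threshold must lie in [0, 255]")
  r <- clip_roi(roi, img)
  out <- matrix(0L, nrow = nrow(img), ncol = ncol(img))
  rows <- (r$y0 + 1L):r$y1
  cols <- (r$x0 + 1L):r$x1
  out[rows, cols] <- ifelse(img[rows, cols] >= threshold, 255L, 0L)
  out
}

#' Gray-level inversion
#'
#' Maps every pixel to `255 - g`, the exact involution that turns dark
#' tracking into bright tracking.
#'
#' @param img integer gray matrix on 0-255.
#' @return inverted image.
#' @export
invert_gray <- function(img) {
  check_gray8(img)
  out <- 255L - img
  storage.mode(out) <- "integer"
  out
}
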