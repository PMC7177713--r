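## Intensity-weighted mean shift with the dual eight-sector kernel.
##
## Per frame: equalize, binarize inside the kernel's dilated bounding
## box, iterate the combined white/black mean until the shift is below
## tolerance, then recompute every sector radius from the distance of
## that sector's foreground weight center to the kernel center.

#' Tracker configuration
#'
#' Collects every scalar knob of the tracking chain.  The defaults are
#' the working constants of the method: initial sector radius 16 px,
#' radius gain `k = 1.55`, smoothing weight `beta = 0.05`, binarization
#' threshold 200 on the equalized image, core fraction `f = 0.5` and
#' equal mean-combination weights.
#'
#' @param initial_radius starting value for all eight white radii (px).
#' @param k dimensionless gain of the radius update
#'   `rw[i] <- k * (beta * d_bar + (1 - beta) * d[i])`.
#' @param beta smoothing weight in \[0, 1\] mixing each sector distance
#'   with the mean distance over sectors.
#' @param f core fraction in (0, 1); black radii are `f * rw`.
#' @param threshold binarization threshold on the 0-255 scale, applied
#'   to the equalized frame inside the local region of interest.
#' @param w1,w2 weights combining the white (bright) and black (dark)
#'   layer means.
#' @param epsilon convergence tolerance on the mean-shift displacement
#'   (px).
#' @param max_iter iteration cap per frame.
#' @param r_min,r_max clamps on the white sector radii (px).
#' @param roi_dilation factor dilating the kernel bounding box into the
#'   local-threshold region.
#' @param polarity `"dark"` tracks a dark core with bright halo (the
#'   phase-contrast pattern); `"bright"` inverts each frame up front and
#'   runs the identical chain, which is how a bright-core target is
#'   tracked.
#' @param use_gray_weights if `TRUE`, the layer means weight pixel
#'   positions by the equalized gray levels instead of the binary mask.
#' @param annulus_white if `TRUE`, the white-layer mean excludes the
#'   black-layer support (annulus variant); the default uses the full
#'   white octagon.
#' @param equalize_roi if `TRUE`, equalization is computed inside the
#'   region of interest instead of over the whole frame.
#' @return an object of class `tracker_config`.
#' @examples
#' cfg <- tracker_config()
#' c(cfg$threshold, cfg$initial_radius, cfg$k, cfg$beta)
#' @export
tracker_config <- function(initial_radius = 16, k = 1.55, beta = 0.05,
                           f = 0.5, threshold = 200, w1 = 0.5, w2 = 0.5,
                           epsilon = 0.05, max_iter = 100L,
                           r_min = 2, r_max = 4 * initial_radius,
                           roi_dilation = 2,
                           polarity = c("dark", "bright"),
                           use_gray_weights = FALSE,
                           annulus_white = FALSE,
                           equalize_roi = FALSE) {
  polarity <- match.arg(polarity)
  if (initial_radius <= 0) stop_invalid("initial_radius must be positive")
  if (beta < 0 || beta > 1) stop_invalid("beta must lie in [0, 1]")
  if (f <= 0 || f >= 1) stop_invalid("f must lie strictly in (0, 1)")
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop_invalid("w1, w2 must be nonnegative with positive sum")
  if (r_min <= 0 || r_max < r_min) stop_invalid("need 0 < r_min <= r_max")
  if (roi_dilation < 1) stop_invalid("roi_dilation must be >= 1")
  structure(list(
    initial_radius = initial_radius, k = k, beta = beta, f = f,
    threshold = threshold, w1 = w1, w2 = w2, epsilon = epsilon,
    max_iter = as.integer(max_iter), r_min = r_min, r_max = r_max,
    roi_dilation = roi_dilation, polarity = polarity,
    use_gray_weights = isTRUE(use_gray_weights),
    annulus_white = isTRUE(annulus_white),
    equalize_roi = isTRUE(equalize_roi)
  ), class = "tracker_config")
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("Tracker configuration\n")
  cat(sprintf("  initial radius %g px, k = %g, beta = %g, f = %g\n",
              x$initial_radius, x$k, x$beta, x$f))
  cat(sprintf("  threshold %g, weights (w1, w2) = (%g, %g), polarity %s\n",
              x$threshold, x$w1, x$w2, x$polarity))
  cat(sprintf("  epsilon %g px, max_iter %d, radius clamps [%g, %g]\n",
              x$epsilon, x$max_iter, x$r_min, x$r_max))
  invisible(x)
}

#' Unweighted mean over a disc kernel
#'
#' The basic mean-shift step for a point sample: the mean of the sample
#' positions whose distance from the center is at most `radius` (the
#' indicator kernel includes the boundary).
#'
#' @param points n x 2 matrix of sample positions.
#' @param center length-2 disc center.
#' @param radius disc radius.
#' @return length-2 mean position, or `NULL` when no sample falls inside
#'   the disc (no-support signal).
#' @export
uniform_mean <- function(points, center, radius) {
  points <- matrix(as.numeric(points), ncol = 2L)
  d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2
  keep <- d2 <= radius^2
  if (!any(keep)) return(NULL)
  colMeans(points[keep, , drop = FALSE])
}

## Support pixels of one layer with their gray values; out-of-bounds
## pixels are skipped (absent, not zero-valued).
layer_pixels <- function(img, kernel, layer) {
  sup <- kernel_support(kernel, layer)
  keep <- sup[, "x"] >= 0L & sup[, "x"] < ncol(img) &
          sup[, "y"] >= 0L & sup[, "y"] < nrow(img)
  sup <- sup[keep, , drop = FALSE]
  g <- img[cbind(sup[, "y"] + 1L, sup[, "x"] + 1L)]
  list(x = sup[, "x"], y = sup[, "y"], sector = sup[, "sector"], g = g)
}

#' Gray-weighted mean over one kernel layer
#'
#' Weighted centroid of the pixel positions under the chosen layer's
#' support, with weights `g(p)` for bright polarity and `255 - g(p)` for
#' dark polarity, i.e. the discrete form of
#' \deqn{m(x) = \sum_p K(p-x) g(p) p / \sum_p K(p-x) g(p).}
#'
#' @param img integer gray matrix (typically the preprocessed frame).
#' @param kernel a [sector_kernel()].
#' @param layer `"white"` or `"black"`.
#' @param polarity `"bright"` or `"dark"`.
#' @param exclude optional second kernel layer whose support is removed
#'   (the annulus variant).
#' @return length-2 weighted mean position, or `NULL` when every weight
#'   is zero (no-support signal; the caller keeps the previous center).
#' @export
kernel_weighted_mean <- function(img, kernel, layer = c("white", "black"),
                                 polarity = c("bright", "dark"),
                                 exclude = NULL) {
  layer <- match.arg(layer)
  polarity <- match.arg(polarity)
  lp <- layer_pixels(img, kernel, layer)
  if (!is.null(exclude)) {
    ex <- layer_pixels(img, kernel, exclude)
    drop <- paste(lp$x, lp$y) %in% paste(ex$x, ex$y)
    lp <- lapply(lp, function(v) v[!drop])
  }
  if (length(lp$x) == 0L) return(NULL)
  w <- if (polarity == "bright") lp$g else 255L - lp$g
  sw <- sum(as.numeric(w))
  if (sw <= 0) return(NULL)
  c(sum(w * lp$x), sum(w * lp$y)) / sw
}

#' Combine the white and black layer means
#'
#' Weighted combination `(w1 * m1 + w2 * m2) / (w1 + w2)`; with equal
#' weights this is the midpoint used to lock onto the border between the
#' bright halo and the dark body.
#'
#' @param m1,m2 length-2 means of the white and black layers.
#' @param w1,w2 nonnegative weights, `w1 + w2 > 0`.
#' @return length-2 combined mean.
#' @export
combined_mean <- function(m1, m2, w1 = 0.5, w2 = 0.5) {
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop_invalid("weights must be nonnegative with positive sum")
  (w1 * m1 + w2 * m2) / (w1 + w2)
}

## Preprocess one frame for a kernel position: optional up-front
## inversion (bright-target chain), equalization, local binarization.
## Returns the image the means run on plus the binary mask for the
## sector weight centers.
preprocess_frame <- function(img, kernel, cfg) {
  check_gray8(img)
  if (cfg$polarity == "bright") img <- invert_gray(img)
  R <- max(kernel$rw) / cos(THETA)
  half <- cfg$roi_dilation * R
  r <- clip_roi(roi(kernel$center[1] - half, kernel$center[2] - half,
                    kernel$center[1] + half + 1, kernel$center[2] + half + 1),
                img)
  eq <- if (cfg$equalize_roi) {
    out <- img
    rows <- (r$y0 + 1L):r$y1; cols <- (r$x0 + 1L):r$x1
    out[rows, cols] <- equalize_hist(img[rows, cols, drop = FALSE])
    out
  } else equalize_hist(img)
  bin <- binarize(eq, cfg$threshold, r)
  ## dark mask: the same chain on the reversed gray image, so the black
  ## layer is attracted to the darkest zone (the cell body), not to
  ## arbitrary background
  bin_dark <- binarize(invert_gray(eq), cfg$threshold, r)
  list(eq = eq, bin = bin, bin_dark = bin_dark, roi = r)
}

#' Run the mean-shift iteration to convergence on one frame
#'
#' Repeatedly replaces the kernel center with the combination of the
#' white-layer bright mean and the black-layer dark mean computed on the
#' preprocessed frame, until the displacement falls below
#' `cfg$epsilon` or `cfg$max_iter` is reached.  The white (halo) layer
#' losing all support marks the frame as lost and the last valid center
#' is kept.
#'
#' @param img raw gray frame (preprocessing is applied internally).
#' @param kernel a [sector_kernel()] positioned at the starting center.
#' @param cfg a [tracker_config()].
#' @return list with `center`, `iterations`, `lost`, and the
#'   preprocessed images (`eq`, `bin`) for reuse by the radius update.
#' @export
mean_shift <- function(img, kernel, cfg = tracker_config()) {
  pp <- preprocess_frame(img, kernel, cfg)
  center <- kernel$center
  lost <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    k <- kernel; k$center <- center
    if (cfg$use_gray_weights) {
      m1 <- kernel_weighted_mean(pp$eq, k, "white", "bright",
                                 exclude = if (cfg$annulus_white) "black")
      m2 <- kernel_weighted_mean(pp$eq, k, "black", "dark")
    } else {
      m1 <- kernel_weighted_mean(pp$bin, k, "white", "bright",
                                 exclude = if (cfg$annulus_white) "black")
      ## bin_dark already encodes darkness as foreground
      m2 <- kernel_weighted_mean(pp$bin_dark, k, "black", "bright")
    }
    if (is.null(m1)) { lost <- TRUE; break }
    m <- if (is.null(m2)) m1 else combined_mean(m1, m2, kernel$w1, kernel$w2)
    shift <- sqrt(sum((m - center)^2))
    center <- m
    if (shift < cfg$epsilon || iter >= cfg$max_iter) break
  }
  list(center = center, iterations = iter, lost = lost,
       eq = pp$eq, bin = pp$bin, roi = pp$roi)
}

#' Per-sector foreground weight centers
#'
#' Centroid of the binarized foreground pixels inside each white sector,
#' the distance `d[i]` from each centroid to the kernel center, and the
#' mean distance `d_bar` over the sectors that contain foreground.
#' Empty sectors yield `NA` entries and are excluded from `d_bar`.
#'
#' @param bin binary image (values 0/255) after local thresholding.
#' @param kernel a [sector_kernel()] at its converged position.
#' @return list with `centroids` (8 x 2, `NA` rows for empty sectors),
#'   `d` (8 distances) and `d_bar`.
#' @export
sector_weight_centers <- function(bin, kernel) {
  lp <- layer_pixels(bin, kernel, "white")
  fg <- lp$g == 255L
  centroids <- matrix(NA_real_, 8L, 2L)
  d <- rep(NA_real_, 8L)
  for (i in 1:8) {
    sel <- fg & lp$sector == i
    if (any(sel)) {
      cx <- mean(lp$x[sel]); cy <- mean(lp$y[sel])
      centroids[i, ] <- c(cx, cy)
      d[i] <- sqrt((cx - kernel$center[1])^2 + (cy - kernel$center[2])^2)
    }
  }
  list(centroids = centroids, d = d,
       d_bar = if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE))
}

#' Adapt the sector radii from the weight-center distances
#'
#' Applies the update `rw[i](t+1) = k * (beta * d_bar(t) +
#' (1 - beta) * d[i](t))` to every sector with a defined weight center,
#' clamps the result to `[r_min, r_max]`, keeps the previous radius for
#' empty sectors, and rescales the black layer through `rb = f * rw`.
#'
#' @param kernel a [sector_kernel()].
#' @param stats result of [sector_weight_centers()].
#' @param cfg a [tracker_config()].
#' @return the kernel with updated radii.
#' @examples
#' k <- sector_kernel(c(0, 0), rw = 16)
#' st <- list(d = rep(10, 8), d_bar = 10)
#' update_radii(k, st, tracker_config())$rw  # all 15.5
#' @export
update_radii <- function(kernel, stats, cfg = tracker_config()) {
  if (all(is.na(stats$d))) return(kernel)
  new_r <- cfg$k * (cfg$beta * stats$d_bar + (1 - cfg$beta) * stats$d)
  new_r <- clamp(new_r, cfg$r_min, cfg$r_max)
  kernel$rw <- ifelse(is.na(stats$d), kernel$rw, new_r)
  kernel$rb <- kernel$f * kernel$rw
  kernel
}

#' Track one frame from a previous state
#'
#' Preprocesses the frame, runs the mean shift from the previous center,
#' computes the sector weight centers on the binarized frame and adapts
#' the radii.  A lost frame (no halo foreground) freezes the geometry so
#' tracking can recover when the cell reappears inside the search box.
#'
#' @param img raw gray frame.
#' @param state list with `kernel` (a [sector_kernel()]) and optionally
#'   `frame`; as returned by a previous call.
#' @param cfg a [tracker_config()].
#' @return list with the updated `kernel`, `center`, `iterations`,
#'   `lost`, `stats` and `frame` index.
#' @export
track_frame <- function(img, state, cfg = tracker_config()) {
  kernel <- state$kernel
  ms <- mean_shift(img, kernel, cfg)
  if (ms$lost) {
    return(list(kernel = kernel, center = kernel$center,
                iterations = ms$iterations, lost = TRUE,
                stats = NULL,
                frame = (state$frame %||% -1L) + 1L))
  }
  kernel$center <- ms$center
  stats <- sector_weight_centers(ms$bin, kernel)
  kernel <- update_radii(kernel, stats, cfg)
  list(kernel = kernel, center = ms$center, iterations = ms$iterations,
       lost = FALSE, stats = stats, frame = (state$frame %||% -1L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track a cell through an image sequence
#'
#' The main entry point: initializes the dual eight-sector kernel at the
#' seed point with all white radii equal to `cfg$initial_radius` and
#' folds [track_frame()] over the frames.  The whole chain is
#' deterministic given the frames, the seed point and the
#' configuration.
#'
#' @param frames list of gray frames (integer matrices 0-255, or
#'   anything [to_gray8()] accepts), all of equal size.
#' @param seed_point length-2 starting center (x = column, y = row from
#'   top, 0-based) inside the first frame.
#' @param cfg a [tracker_config()].
#' @param init_rounds initialization refinement: the converge-and-adapt
#'   cycle is repeated on the first frame up to this many times (until
#'   the center moves less than `cfg$epsilon` between rounds), so that a
#'   rough seed point and radius lock onto the cell before
#'   frame-to-frame tracking starts.  Set to 1 to disable.
#' @return an object of class `cell_track`: a per-frame trajectory with
#'   centers, iteration counts, lost flags and the 8 + 8 sector radii,
#'   plus the configuration and final kernel.
#' @examples
#' seq <- generate_sequence(scene_config(n_frames = 3, noise_sd = 0))
#' trk <- track_cells(seq$frames, seed_point = c(34, 33))
#' trk
#' @export
track_cells <- function(frames, seed_point, cfg = tracker_config(),
                        init_rounds = 10L) {
  if (length(frames) == 0L) stop_invalid("empty frame sequence")
  frames <- lapply(frames, to_gray8)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("frames have inconsistent dimensions")
  seed_point <- as.numeric(seed_point)
  if (seed_point[1] < 0 || seed_point[1] >= ncol(frames[[1]]) ||
      seed_point[2] < 0 || seed_point[2] >= nrow(frames[[1]]))
    stop_invalid("seed point outside the first frame")
  kernel <- sector_kernel(seed_point, rw = cfg$initial_radius, f = cfg$f,
                          w1 = cfg$w1, w2 = cfg$w2)
  state <- list(kernel = kernel, frame = -1L)
  ## initialization: let the kernel settle on the first frame before
  ## tracking starts (the seed is a rough guess, the initial radius a
  ## single scalar for all sectors)
  for (round in seq_len(max(0L, init_rounds - 1L))) {
    trial <- track_frame(frames[[1L]], state, cfg)
    moved <- sqrt(sum((trial$kernel$center - state$kernel$center)^2))
    state <- list(kernel = trial$kernel, frame = -1L)
    if (trial$lost || moved < cfg$epsilon) break
  }
  rows <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    state <- track_frame(frames[[t]], state, cfg)
    k <- state$kernel
    rows[[t]] <- data.frame(
      frame = state$frame, x = state$center[1], y = state$center[2],
      iterations = state$iterations, lost = as.integer(state$lost),
      t(stats::setNames(k$rw, paste0("rw", 1:8))),
      t(stats::setNames(k$rb, paste0("rb", 1:8))))
  }
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  structure(list(trajectory = traj, config = cfg, kernel = state$kernel,
                 seed_point = seed_point,
                 dim = dim(frames[[1]])),
            class = "cell_track")
}
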