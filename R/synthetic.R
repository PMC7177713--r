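## Seeded generator of phase-contrast-like single-cell sequences with
## exact ground truth: a dark circular core surrounded by a bright halo
## on a mid-gray noisy background, translating and shrinking over
## frames.  Every tracker property is testable against the returned
## truth without any external data.

#' Synthetic scene configuration
#'
#' Describes a single shrinking, drifting cell rendered as a radial
#' intensity profile: `core_level` inside the core radius
#' `rho(t) = max(rho0 - shrink * t, 1)`, a smooth cosine ramp up to
#' `halo_peak` and back down to `background` across the halo annulus of
#' width `halo_width`, and `background` outside, plus clipped additive
#' Gaussian noise.  The defaults emulate a tracking crop around one
#' cell: the halo occupies a substantial share of the intensity ranks,
#' the regime a fixed threshold of 200 on the equalized image
#' presupposes.
#'
#' @param width,height frame size in pixels.
#' @param background background gray level (0-255).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param core_level gray level of the dark cell body; must be below
#'   `background`.
#' @param halo_peak peak gray level of the halo; must exceed
#'   `background`.
#' @param halo_width radial width of the halo annulus (px).
#' @param rho0 initial core radius (px).
#' @param shrink core shrink rate (px/frame).
#' @param center0 length-2 starting center (x, y, 0-based).
#' @param velocity length-2 drift (px/frame); the path must keep the
#'   cell at least `rho + halo_width` away from the borders.
#' @param n_frames number of frames.
#' @param seed integer seed for the noise generator.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(width = 64, height = 64, background = 128,
                         noise_sd = 8, core_level = 32, halo_peak = 224,
                         halo_width = 14, rho0 = 8, shrink = 0.4,
                         center0 = c(width / 2, height / 2),
                         velocity = c(0.5, 0.25), n_frames = 12,
                         seed = 11) {
  if (!(core_level < background && background < halo_peak))
    stop_invalid("need core_level < background < halo_peak")
  if (rho0 <= 0 || halo_width <= 0) stop_invalid("radii must be positive")
  if (n_frames < 1) stop_invalid("need at least one frame")
  sc <- structure(list(
    width = as.integer(width), height = as.integer(height),
    background = background, noise_sd = noise_sd,
    core_level = core_level, halo_peak = halo_peak,
    halo_width = halo_width, rho0 = rho0, shrink = shrink,
    center0 = as.numeric(center0), velocity = as.numeric(velocity),
    n_frames = as.integer(n_frames), seed = as.integer(seed)
  ), class = "scene_config")
  for (t in c(0L, sc$n_frames - 1L)) {
    ctr <- scene_center(sc, t)
    reach <- scene_rho(sc, t) + halo_width
    if (ctr[1] < reach || ctr[2] < reach ||
        ctr[1] > width - 1 - reach || ctr[2] > height - 1 - reach)
      stop_invalid("cell path comes within rho + halo_width of a border")
  }
  sc
}

scene_rho <- function(scene, t) pmax(scene$rho0 - scene$shrink * t, 1)

scene_center <- function(scene, t) scene$center0 + scene$velocity * t

## radial profile: core plateau, then the halo annulus — a sharp cosine
## rise from the core level to the peak over the inner quarter of the
## halo width (phase halos abut the object edge) and a slow cosine
## decay back to the background over the outer three quarters —
## background plateau outside
radial_profile <- function(r, rho, scene) {
  w_up <- scene$halo_width / 4
  w_dn <- scene$halo_width - w_up
  lvl <- numeric(length(r))
  core <- r <= rho
  rise <- r > rho & r <= rho + w_up
  fall <- r > rho + w_up & r <= rho + scene$halo_width
  lvl[core] <- scene$core_level
  u <- (r[rise] - rho) / w_up
  lvl[rise] <- scene$core_level +
    (scene$halo_peak - scene$core_level) * (1 - cos(pi * u)) / 2
  u <- (r[fall] - rho - w_up) / w_dn
  lvl[fall] <- scene$background +
    (scene$halo_peak - scene$background) * (1 + cos(pi * u)) / 2
  lvl[r > rho + scene$halo_width] <- scene$background
  lvl
}

#' Render one synthetic frame with its ground truth
#'
#' @param scene a [scene_config()].
#' @param t frame index, 0-based, `t < n_frames`.
#' @return list with `img` (integer gray matrix), `center` (true cell
#'   center) and `rho` (true core radius).  Frames are bit-reproducible:
#'   the noise stream is seeded per frame from the scene seed.
#' @export
render_frame <- function(scene, t) {
  stopifnot(inherits(scene, "scene_config"))
  if (t < 0 || t >= scene$n_frames) stop_invalid("frame index out of range")
  ctr <- scene_center(scene, t)
  rho <- scene_rho(scene, t)
  xs <- 0:(scene$width - 1L)
  ys <- 0:(scene$height - 1L)
  r <- sqrt(outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`))
  lvl <- matrix(radial_profile(as.vector(r), rho, scene),
                nrow = scene$height)
  if (scene$noise_sd > 0) {
    noise <- with_seed(scene$seed * 131L + t, {
      matrix(stats::rnorm(length(lvl), 0, scene$noise_sd),
             nrow = scene$height)
    })
    lvl <- lvl + noise
  }
  img <- matrix(as.integer(clamp(round_half_up(lvl), 0, 255)),
                nrow = scene$height)
  list(img = img, center = ctr, rho = rho)
}

#' Generate a full synthetic sequence with ground truth
#'
#' @param scene a [scene_config()].
#' @param path optional file stem: frames are written as a multi-page
#'   TIFF at `<path>.tif` and the truth table at `<path>_truth.csv`.
#' @return list with `frames` (list of integer gray matrices) and
#'   `truth` (data frame `frame`, `x`, `y`, `rho`, frame 0-based).
#' @examples
#' seq <- generate_sequence(scene_config(n_frames = 2, noise_sd = 0))
#' seq$truth
#' @export
generate_sequence <- function(scene, path = NULL) {
  frames <- vector("list", scene$n_frames)
  truth <- data.frame(frame = 0:(scene$n_frames - 1L), x = NA_real_,
                      y = NA_real_, rho = NA_real_)
  for (t in 0:(scene$n_frames - 1L)) {
    fr <- render_frame(scene, t)
    frames[[t + 1L]] <- fr$img
    truth[t + 1L, c("x", "y", "rho")] <- c(fr$center, fr$rho)
  }
  if (!is.null(path)) {
    tiff::writeTIFF(lapply(frames, function(m) m / 255),
                    paste0(path, ".tif"), bits.per.sample = 8L)
    utils::write.csv(truth, paste0(path, "_truth.csv"), row.names = FALSE)
  }
  list(frames = frames, truth = truth)
}
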