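#' @export
print.cell_track <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Cell track: %d frames, seed (%g, %g), %d lost\n",
              nrow(tr), x$seed_point[1], x$seed_point[2], sum(tr$lost)))
  cat(sprintf("  final center (%.2f, %.2f), mean white radius %.2f px\n",
              tr$x[nrow(tr)], tr$y[nrow(tr)],
              mean(as.numeric(tr[nrow(tr), paste0("rw", 1:8)]))))
  invisible(x)
}

#' @export
summary.cell_track <- function(object, ...) {
  tr <- object$trajectory
  rw <- as.matrix(tr[, paste0("rw", 1:8)])
  out <- list(
    n_frames = nrow(tr),
    n_lost = sum(tr$lost),
    iterations = summary(tr$iterations),
    path_length = sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)),
    mean_rw = rowMeans(rw),
    final_center = c(x = tr$x[nrow(tr)], y = tr$y[nrow(tr)])
  )
  class(out) <- "summary.cell_track"
  out
}

#' @export
print.summary.cell_track <- function(x, ...) {
  cat(sprintf("Cell track over %d frames (%d lost)\n", x$n_frames, x$n_lost))
  cat(sprintf("  path length %.2f px, final center (%.2f, %.2f)\n",
              x$path_length, x$final_center[1], x$final_center[2]))
  cat("  mean white radius per frame:\n")
  print(round(x$mean_rw, 2))
  cat("  mean-shift iterations:\n")
  print(x$iterations)
  invisible(x)
}

#' @export
as.data.frame.cell_track <- function(x, ...) x$trajectory

#' Plot a tracked trajectory
#'
#' Draws the center path in image coordinates (y axis pointing down, as
#' in the raster) and, in a second panel, the mean white and black
#' radii per frame.
#'
#' @param x a `cell_track`.
#' @param ... passed to [plot.default()].
#' @export
plot.cell_track <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(tr$x, tr$y, type = "o", pch = 16, xlab = "x (px)", ylab = "y (px)",
       ylim = rev(range(tr$y)), main = "center path", ...)
  rw <- rowMeans(as.matrix(tr[, paste0("rw", 1:8)]))
  rb <- rowMeans(as.matrix(tr[, paste0("rb", 1:8)]))
  plot(tr$frame, rw, type = "l", xlab = "frame", ylab = "radius (px)",
       ylim = range(c(rw, rb)), main = "mean sector radii")
  graphics::lines(tr$frame, rb, lty = 2)
  graphics::legend("topright", legend = c("white", "black"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Per-frame tracking error against a ground-truth trajectory
#'
#' @param track a `cell_track`.
#' @param truth data frame with columns `frame`, `x`, `y` and optionally
#'   `rho` (as written by [generate_sequence()]).
#' @return data frame with per-frame Euclidean center error and, when
#'   `rho` is present, the mean black radius for comparison with the
#'   true core radius.
#' @export
track_errors <- function(track, truth) {
  tr <- as.data.frame(track)
  m <- merge(tr, truth, by = "frame", suffixes = c("", ".true"))
  out <- data.frame(
    frame = m$frame,
    error = sqrt((m$x - m$x.true)^2 + (m$y - m$y.true)^2),
    lost = m$lost
  )
  if ("rho" %in% names(m)) {
    out$rho <- m$rho
    out$mean_rb <- rowMeans(as.matrix(m[, paste0("rb", 1:8)]))
    out$mean_rw <- rowMeans(as.matrix(m[, paste0("rw", 1:8)]))
  }
  out[order(out$frame), ]
}
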