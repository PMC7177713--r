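## Readers and writers: multi-page TIFF / PNG frame sequences in,
## trajectory CSV and overlay TIFF out, plus the declarative run
## configuration consumed by the command-line interface.

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    "jpg" = ,
    "jpeg" = stop_invalid("JPEG input is not supported; convert frames ",
                          "to PNG or TIFF"),
    stop_invalid("unsupported image format: ", ext)
  )
  to_gray8(raw)
}

#' Read an image sequence
#'
#' Accepts a multi-page TIFF or a directory of PNG/TIFF frames taken in
#' lexicographic name order.  Every frame is converted to 8-bit gray;
#' all frames must share the same dimensions.
#'
#' @param path multi-page TIFF file or frame directory.
#' @return list of integer gray matrices.
#' @export
read_sequence <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop_invalid("no image frames in ", path)
    frames <- lapply(files, read_gray)
  } else {
    if (!file.exists(path)) stop_invalid("no such file: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray8)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_invalid("frames have inconsistent dimensions")
  message(sprintf("read %d frame(s) of %d x %d px", length(frames),
                  dims[2, 1], dims[1, 1]))
  frames
}

#' Write / read a trajectory table
#'
#' CSV with header `frame,x,y,iterations,lost,rw1..rw8,rb1..rb8`;
#' coordinates are image-frame (x = column, y = row from top, 0-based)
#' and floats are written at 3 decimals.
#'
#' @param track a `cell_track` or its trajectory data frame.
#' @param path output file.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` the trajectory data frame.
#' @export
write_trajectory <- function(track, path) {
  tr <- if (inherits(track, "cell_track")) track$trajectory else track
  if (nrow(tr) == 0L) stop_invalid("empty trajectory")
  num <- setdiff(names(tr), c("frame", "iterations", "lost"))
  tr[num] <- lapply(tr[num], function(v) sprintf("%.3f", v))
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path)
}

## integer pixel chain along a segment (dense enough for thin outlines)
segment_pixels <- function(p1, p2) {
  n <- max(2L, ceiling(2 * sqrt(sum((p2 - p1)^2))) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(round_half_up(p1[1] + t * (p2[1] - p1[1])),
        round_half_up(p1[2] + t * (p2[2] - p1[2])))
}

draw_polygon <- function(img, verts, value) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(verts))) {
    j <- if (i == nrow(verts)) 1L else i + 1L
    px <- segment_pixels(verts[i, ], verts[j, ])
    keep <- px[, 1] >= 0 & px[, 1] < w & px[, 2] >= 0 & px[, 2] < h
    img[cbind(px[keep, 2] + 1L, px[keep, 1] + 1L)] <- value
  }
  img
}

#' Render kernel overlays onto a tracked sequence
#'
#' Draws, per frame, the kernel center marker (a small black square)
#' and the white- and black-layer sector polygons (white and black
#' outlines) at that frame's converged geometry.
#'
#' @param frames list of gray frames.
#' @param track a `cell_track` with one state per frame.
#' @param path optional multi-page TIFF output path.
#' @return list of annotated frames, invisibly when `path` is given.
#' @export
render_overlay <- function(frames, track, path = NULL) {
  tr <- if (inherits(track, "cell_track")) track$trajectory else track
  if (length(frames) != nrow(tr))
    stop_invalid("frame count and trajectory length differ")
  out <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    img <- to_gray8(frames[[t]])
    ctr <- c(tr$x[t], tr$y[t])
    for (layer in c("rw", "rb")) {
      radii <- as.numeric(tr[t, paste0(layer, 1:8)])
      v <- sector_vertices(radii)
      verts <- cbind(ctr[1] + v[, 1], ctr[2] - v[, 2])
      img <- draw_polygon(img, verts, if (layer == "rw") 255L else 0L)
    }
    cx <- round_half_up(ctr[1]); cy <- round_half_up(ctr[2])
    for (dx in -1:1) for (dy in -1:1) {
      x <- cx + dx; y <- cy + dy
      if (x >= 0 && x < ncol(img) && y >= 0 && y < nrow(img))
        img[y + 1L, x + 1L] <- 0L
    }
    out[[t]] <- img
  }
  if (!is.null(path)) {
    tiff::writeTIFF(lapply(out, function(m) m / 255), path,
                    bits.per.sample = 8L)
    return(invisible(out))
  }
  out
}

#' Read a declarative run configuration
#'
#' YAML (or JSON) file with optional blocks `tracker` (arguments of
#' [tracker_config()]) and `scene` (arguments of [scene_config()]) plus
#' free top-level fields (`input`, `seed_point`, `output`, ...).
#'
#' @param path configuration file.
#' @return list with `tracker` and `scene` instantiated and the
#'   remaining fields passed through.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  out <- cfg
  out$tracker <- do.call(tracker_config, as.list(cfg$tracker))
  out$scene <- if (!is.null(cfg$scene))
    do.call(scene_config, as.list(cfg$scene))
  out
}
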