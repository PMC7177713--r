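## Eight-sector dual-kernel geometry.
##
## The tracking kernel is a pair of concentric octagonal supports built
## from eight triangular sectors: a "white" layer of apothem-like radii
## rw[i] attracted to the bright halo and a "black" layer rb[i] = f * rw[i]
## attracted to the dark cell body.  All geometry lives in a kernel-local
## Cartesian frame (x right, y up, origin at the kernel center); image
## pixels map through (col, row) = (x0 + x, y0 - y).

THETA <- pi / 8  # sector half-angle; eight sectors of angular width pi/4

#' Construct an eight-sector dual kernel
#'
#' The kernel consists of two concentric eight-sector polygons: the white
#' layer with per-sector radii `rw` (distance from the center to the
#' midpoint of each sector's outer edge) and the black layer scaled by the
#' core fraction `f`, so `rb[i] = f * rw[i]`.  Sectors are numbered
#' counter-clockwise starting from the lower octant of the first quadrant.
#'
#' @param center numeric length-2, kernel center in image coordinates
#'   (x = column, y = row from top, 0-based, pixel centers at integers).
#' @param rw numeric, white-layer sector radii in pixels; a scalar is
#'   recycled to all eight sectors.
#' @param f core fraction in (0, 1): black radii are `f * rw`.
#' @param w1,w2 nonnegative weights combining the white and black layer
#'   means during mean shift; `w1 + w2` must be positive.
#' @return an object of class `sector_kernel` with fields `center`, `rw`,
#'   `rb`, `f`, `w1`, `w2`.
#' @examples
#' k <- sector_kernel(c(32, 32), rw = 16)
#' k$rb   # half the white radii with the default core fraction 0.5
#' @export
sector_kernel <- function(center, rw = 16, f = 0.5, w1 = 0.5, w2 = 0.5) {
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center)))
    stop_invalid("`center` must be two finite coordinates")
  if (length(rw) == 1L) rw <- rep(as.numeric(rw), 8L)
  rw <- as.numeric(rw)
  if (length(rw) != 8L || any(!is.finite(rw)) || any(rw <= 0))
    stop_invalid("`rw` must be 8 positive sector radii")
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop_invalid("core fraction `f` must lie strictly in (0, 1)")
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop_invalid("weights must be nonnegative with w1 + w2 > 0")
  structure(
    list(center = center, rw = rw, rb = f * rw, f = f, w1 = w1, w2 = w2),
    class = "sector_kernel"
  )
}

#' @export
print.sector_kernel <- function(x, ...) {
  cat("Eight-sector dual kernel\n")
  cat("  center: (", format(x$center[1]), ",", format(x$center[2]), ")\n")
  cat("  rw:", paste(format(x$rw, digits = 4), collapse = " "), "\n")
  cat("  f:", x$f, "  (rb = f * rw)   weights w1 =", x$w1, "w2 =", x$w2, "\n")
  invisible(x)
}

## Outer boundary vertices of the eight-sector polygon, one per boundary
## ray at angles j*pi/4, j = 0..7.  The vertex on the ray between sectors
## i and i+1 is placed at distance r_i / cos(pi/8) using the lower-index
## sector's radius (the wrap ray at angle 0, between sectors 8 and 1, uses
## r_1).  For equal radii every vertex sits at r / cos(pi/8) and the union
## is the regular octagon of apothem r.
sector_vertices <- function(radii) {
  if (length(radii) == 1L) radii <- rep(radii, 8L)
  if (length(radii) != 8L || any(!is.finite(radii)) || any(radii <= 0))
    stop_invalid("need 8 positive sector radii")
  ray_r <- c(radii[1L], radii[1:7])      # ray j = 0 uses r1, ray j uses r_j
  ang <- (0:7) * pi / 4
  cbind(x = ray_r / cos(THETA) * cos(ang),
        y = ray_r / cos(THETA) * sin(ang))
}

#' Decompose the eight-sector kernel into its sector triangles
#'
#' Each sector i spans polar angles \eqn{[(i-1)\pi/4, i\pi/4)} and is the
#' triangle with one vertex at the origin and the other two on the
#' bounding rays at distance \eqn{r/\cos(\pi/8)}.  For the first-quadrant
#' pair this reproduces the closed forms
#' \eqn{n_x = r\sin(\pi/8)}, \eqn{n_y = r\cos(\pi/8)},
#' \eqn{c_y = r/\cos(\pi/8)}, \eqn{b_x = 2n_x}, \eqn{b_y = 2n_y - c_y},
#' \eqn{a_x = r/\cos(\pi/8)}; the remaining sectors follow by reflection
#' in the axes.  A vertex shared by two sectors with unequal radii is
#' computed from the lower-index sector's radius so the polygon closes.
#'
#' @param radii numeric, 8 positive sector radii (a scalar is recycled).
#' @return a list of 8 matrices, each 3 x 2 with rows O, V1, V2 giving
#'   the triangle vertices in the kernel-local frame.
#' @examples
#' tr <- sector_triangles(1)
#' tr[[2]]  # upper octant of quadrant I: O, B on the 45-degree line, C
#' @export
sector_triangles <- function(radii) {
  v <- sector_vertices(radii)
  lapply(1:8, function(i) {
    a <- v[i, ]
    b <- v[if (i == 8L) 1L else i + 1L, ]
    rbind(O = c(0, 0), V1 = a, V2 = b)
  })
}

#' Even-odd ray-casting point-in-triangle test
#'
#' Casts a horizontal ray rightwards from each query point and counts
#' crossings with the triangle's sides; an odd count means inside.  The
#' half-open edge rule is used for degeneracies: an edge is crossed iff
#' exactly one endpoint lies strictly above the ray (the other on or
#' below) and the intersection is strictly to the right of the point.
#'
#' @param px,py numeric vectors of query coordinates (recycled to a
#'   common length).
#' @param tri 3 x 2 matrix of triangle vertices.
#' @return logical vector of membership verdicts.
#' @examples
#' tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
#' point_in_triangle(c(0.5, 2), c(0.5, 2), tri)  # TRUE FALSE
#' @export
point_in_triangle <- function(px, py, tri) {
  tri <- as.matrix(tri)
  if (!all(dim(tri) == c(3L, 2L)) || any(!is.finite(tri)))
    stop_invalid("`tri` must be a finite 3 x 2 vertex matrix")
  n <- max(length(px), length(py))
  px <- rep_len(as.numeric(px), n)
  py <- rep_len(as.numeric(py), n)
  inside <- rep(FALSE, n)
  for (e in 1:3) {
    p1 <- tri[e, ]
    p2 <- tri[if (e == 3L) 1L else e + 1L, ]
    ## half-open rule: one endpoint strictly above, the other on-or-below
    straddles <- (p1[2] > py) != (p2[2] > py)
    if (any(straddles)) {
      xint <- p1[1] + (py - p1[2]) / (p2[2] - p1[2]) * (p2[1] - p1[1])
      cross <- straddles & (xint > px)
      inside <- xor(inside, cross)
    }
  }
  inside
}

#' Enumerate the pixel support of one kernel layer
#'
#' Scans the axis-aligned bounding rectangle framing the chosen layer
#' (half-extent equal to the largest outer-vertex distance
#' \eqn{\max_i r_i/\cos(\pi/8)}) and keeps the integer pixel centers that
#' fall inside some sector triangle.  Pixels on a boundary shared by two
#' sectors are assigned to the lowest containing sector index.
#'
#' @param kernel a [sector_kernel()].
#' @param layer `"white"` or `"black"` — which concentric layer to
#'   enumerate.
#' @return integer matrix with columns `x`, `y` (absolute image
#'   coordinates of pixel centers) and `sector` (1-8).
#' @examples
#' k <- sector_kernel(c(0, 0), rw = 1, f = 0.5)
#' kernel_support(k, "black")  # only the center pixel
#' @export
kernel_support <- function(kernel, layer = c("white", "black")) {
  stopifnot(inherits(kernel, "sector_kernel"))
  layer <- match.arg(layer)
  radii <- if (layer == "white") kernel$rw else kernel$rb
  tris <- sector_triangles(radii)
  R <- max(radii) / cos(THETA)
  x0 <- kernel$center[1]; y0 <- kernel$center[2]
  xs <- seq.int(floor(x0 - R), ceiling(x0 + R))
  ys <- seq.int(floor(y0 - R), ceiling(y0 + R))
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  ## kernel-local frame: x right, y up
  lx <- g$x - x0
  ly <- y0 - g$y
  sec <- integer(nrow(g))
  for (i in 1:8) {
    hit <- sec == 0L & point_in_triangle(lx, ly, tris[[i]])
    sec[hit] <- i
  }
  keep <- sec > 0L
  cbind(x = as.integer(g$x[keep]), y = as.integer(g$y[keep]),
        sector = sec[keep])
}

#' Area of the assembled eight-sector polygon
#'
#' Shoelace area of the boundary polygon through the eight outer
#' vertices.  For equal radii r this is the regular octagon of apothem r
#' with area \eqn{8 r^2 \tan(\pi/8)}.
#'
#' @param radii numeric, 8 positive sector radii (scalar recycled).
#' @return polygon area in square pixels.
#' @examples
#' kernel_area(1)            # 8 * tan(pi/8) = 3.3137085
#' @export
kernel_area <- function(radii) {
  v <- sector_vertices(radii)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}
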