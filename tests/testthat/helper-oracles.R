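# Independent oracles and small fixture builders used across the suite.

# barycentric-coordinate containment oracle (independent of ray casting)
barycentric_inside <- function(px, py, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
  l1 <- ((b[2] - c[2]) * (px - c[1]) + (c[1] - b[1]) * (py - c[2])) / det
  l2 <- ((c[2] - a[2]) * (px - c[1]) + (a[1] - c[1]) * (py - c[2])) / det
  l3 <- 1 - l1 - l2
  l1 >= 0 & l2 >= 0 & l3 >= 0
}

# distance from points to a segment
point_segment_dist <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  t <- ((px - p1[1]) * vx + (py - p1[2]) * vy) / (vx^2 + vy^2)
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
}

min_edge_dist <- function(px, py, tri) {
  pmin(point_segment_dist(px, py, tri[1, ], tri[2, ]),
       point_segment_dist(px, py, tri[2, ], tri[3, ]),
       point_segment_dist(px, py, tri[3, ], tri[1, ]))
}

# shoelace area of a polygon given as an n x 2 matrix (independent of
# kernel_area's internals: different accumulation order)
shoelace <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(s) / 2
}

# logical disc / ellipse masks on a pixel grid
disc_mask <- function(n, cx, cy, r) {
  outer(0:(n - 1), 0:(n - 1),
        function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

ellipse_mask <- function(n, cx, cy, a, b, phi = 0) {
  outer(0:(n - 1), 0:(n - 1), function(y, x) {
    xr <- (x - cx) * cos(phi) + (y - cy) * sin(phi)
    yr <- -(x - cx) * sin(phi) + (y - cy) * cos(phi)
    (xr / a)^2 + (yr / b)^2 <= 1
  })
}

flat_gray <- function(n, value = 128L) matrix(as.integer(value), n, n)
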