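static_scene <- function(noise_sd = 0, n_frames = 3, seed = 11) {
  scene_config(noise_sd = noise_sd, shrink = 0, velocity = c(0, 0),
               n_frames = n_frames, seed = seed)
}

test_that("tracker defaults carry the method's working constants", {
  cfg <- tracker_config()
  expect_identical(cfg$threshold, 200)
  expect_identical(cfg$initial_radius, 16)
  expect_identical(cfg$k, 1.55)
  expect_identical(cfg$beta, 0.05)
  expect_identical(cfg$f, 0.5)
  expect_identical(c(cfg$w1, cfg$w2), c(0.5, 0.5))
  expect_error(tracker_config(beta = 1.5), "beta")
  expect_error(tracker_config(f = 0), "f must")
})

test_that("uniform disc mean includes the boundary and signals empty support", {
  pts <- rbind(c(0, 0), c(2, 0))
  expect_equal(uniform_mean(pts, c(1, 0), 1.5), c(1, 0))
  # boundary sample at distance exactly r is included
  expect_equal(uniform_mean(rbind(c(5, 0)), c(0, 0), 5), c(5, 0))
  expect_null(uniform_mean(pts, c(100, 100), 3))
})

test_that("gray-weighted kernel mean is the weighted centroid of the support", {
  img <- flat_gray(9, 0L)
  img[3, 1] <- 100L  # pixel (x=0, y=2), weight 100
  img[3, 5] <- 200L  # pixel (x=4, y=2), weight 200
  k <- sector_kernel(c(2, 2), rw = 8)
  m <- kernel_weighted_mean(img, k, "white", "bright")
  expect_equal(m, c(8 / 3, 2), tolerance = 1e-12)
  # constant image: geometric centroid of the support = kernel center
  m0 <- kernel_weighted_mean(flat_gray(33, 77L),
                             sector_kernel(c(16, 16), rw = 10),
                             "white", "bright")
  # boundary pixels enter on one side only (half-open edge rule), so the
  # discrete centroid sits a few hundredths of a pixel off center
  expect_equal(m0, c(16, 16), tolerance = 0.01)
  # dark polarity on img equals bright polarity on the inverted image
  set.seed(13)
  img <- matrix(sample.int(256, 33^2, replace = TRUE) - 1L, 33, 33)
  k <- sector_kernel(c(16, 16), rw = 6)
  expect_identical(kernel_weighted_mean(img, k, "white", "dark"),
                   kernel_weighted_mean(invert_gray(img), k, "white", "bright"))
  # all-zero weights signal no support
  expect_null(kernel_weighted_mean(flat_gray(33, 0L), k, "white", "bright"))
})

test_that("combined mean is the weighted convex combination", {
  expect_equal(combined_mean(c(1, 0), c(3, 0), 1, 3), c(2.5, 0))
  expect_equal(combined_mean(c(1, 2), c(5, 6)), c(3, 4))  # midpoint
  expect_equal(combined_mean(c(1, 2), c(9, 9), 1, 0), c(1, 2))
  expect_error(combined_mean(c(0, 0), c(1, 1), 0, 0), "weights")
})

test_that("mean shift fixes the center of a symmetric cell immediately", {
  seqd <- generate_sequence(static_scene(noise_sd = 0, n_frames = 1))
  k <- sector_kernel(c(32, 32), rw = 16)
  ms <- mean_shift(seqd$frames[[1]], k)
  expect_identical(ms$iterations, 1L)
  expect_equal(ms$center, c(32, 32), tolerance = 1e-9)
  expect_false(ms$lost)
})

test_that("mean shift recovers the center from an offset start", {
  seqd <- generate_sequence(scene_config(seed = 7))
  k <- sector_kernel(c(32 + 8, 32), rw = 16)
  ms <- mean_shift(seqd$frames[[1]], k)
  expect_false(ms$lost)
  # single cold run lands close; the tracker's init refinement finishes the job
  expect_lt(sqrt(sum((ms$center - c(32, 32))^2)), 6)
})

test_that("uniform background loses the track", {
  k <- sector_kernel(c(32, 32), rw = 16)
  ms <- mean_shift(flat_gray(64, 128L), k)
  expect_true(ms$lost)
  expect_equal(ms$center, c(32, 32))
})

test_that("sector weight centers measure foreground distances per sector", {
  # analytic ring of foreground at radius 10 about the kernel center
  n <- 41L; ctr <- c(20, 20)
  r <- sqrt(outer((0:(n - 1) - ctr[2])^2, (0:(n - 1) - ctr[1])^2, `+`))
  bin <- matrix(0L, n, n); bin[abs(r - 10) <= 0.5] <- 255L
  k <- sector_kernel(ctr, rw = 16)
  st <- sector_weight_centers(bin, k)
  expect_true(all(abs(st$d - 10) < 0.6))
  expect_equal(st$d_bar, 10, tolerance = 0.06)
  # single foreground pixel: its sector centroid is that pixel
  bin1 <- matrix(0L, n, n); bin1[21, 27] <- 255L  # (x=26, y=20): offset (6, 0)
  st1 <- sector_weight_centers(bin1, k)
  hit <- which(!is.na(st1$d))
  expect_length(hit, 1L)
  expect_equal(unname(st1$centroids[hit, ]), c(26, 20))
  expect_equal(st1$d[hit], 6)
  # foreground confined to one quadrant leaves the others undefined
  binq <- matrix(0L, n, n)
  binq[15:19, 25:29] <- 255L  # up-right of center in image coords
  stq <- sector_weight_centers(binq, k)
  expect_true(any(is.na(stq$d)))
  expect_true(all(which(!is.na(stq$d)) %in% 1:2))
})

test_that("radius update follows the adaptation rule exactly", {
  cfg <- tracker_config()  # k = 1.55, beta = 0.05
  k <- sector_kernel(c(0, 0), rw = 16)
  st <- list(d = rep(10, 8), d_bar = 10)
  up <- update_radii(k, st, cfg)
  expect_identical(up$rw, rep(1.55 * (0.05 * 10 + 0.95 * 10), 8))
  expect_identical(up$rw, rep(15.5, 8))
  expect_identical(up$rb, up$f * up$rw)
})

test_that("radius update is homogeneous before clamping and clamps after", {
  cfg <- tracker_config(r_min = 1e-9, r_max = 1e9)
  k <- sector_kernel(c(0, 0), rw = 16)
  d <- c(4, 6, 8, 10, 12, 9, 7, 5)
  st <- list(d = d, d_bar = mean(d))
  up1 <- update_radii(k, st, cfg)
  s <- 3.7
  st2 <- list(d = s * d, d_bar = s * mean(d))
  up2 <- update_radii(k, st2, cfg)
  expect_equal(up2$rw, s * up1$rw, tolerance = 1e-12)
  # clamp floor when all distances collapse
  cfg2 <- tracker_config()
  st0 <- list(d = rep(0, 8), d_bar = 0)
  expect_identical(update_radii(k, st0, cfg2)$rw, rep(cfg2$r_min, 8))
  # empty sectors keep their previous radius
  stp <- list(d = c(10, rep(NA, 7)), d_bar = 10)
  upp <- update_radii(k, stp, cfg2)
  expect_identical(upp$rw[2:8], rep(16, 7))
  expect_equal(upp$rw[1], 15.5)
})

test_that("static cells stay put and shrinking cells shrink the kernel", {
  seqd <- generate_sequence(static_scene(noise_sd = 8, n_frames = 10))
  trk <- track_cells(seqd$frames, c(32, 32))
  tr <- trk$trajectory
  drift <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_true(all(drift < 0.5))
  # shrinking cell: mean white radius decreases after a 3-frame burn-in
  seqs <- generate_sequence(scene_config())
  trks <- track_cells(seqs$frames, c(32, 32))
  rw <- rowMeans(as.matrix(trks$trajectory[, paste0("rw", 1:8)]))
  expect_true(all(diff(rw[4:12]) < 0))
})

test_that("a blank frame is lost with frozen geometry and recovery follows", {
  seqd <- generate_sequence(static_scene(noise_sd = 0, n_frames = 3))
  frames <- seqd$frames
  frames[[2]] <- flat_gray(64, 128L)
  trk <- track_cells(frames, c(32, 32))
  tr <- trk$trajectory
  expect_identical(tr$lost, c(0L, 1L, 0L))
  # frozen coordinates during the lost frame
  expect_identical(tr$x[2], tr$x[1])
  expect_identical(unlist(tr[2, paste0("rw", 1:8)]),
                   unlist(tr[1, paste0("rw", 1:8)]))
  expect_lt(abs(tr$x[3] - 32), 1)
})

test_that("tracking is deterministic and respects the fold contract", {
  seqd <- generate_sequence(static_scene(noise_sd = 8, n_frames = 4))
  # identical repeated frames give identical states from frame 2 onward
  frames <- rep(seqd$frames[1], 4)
  trk <- track_cells(frames, c(30, 30))
  tr <- trk$trajectory
  for (col in c("x", "y", paste0("rw", 1:8)))
    expect_true(all(abs(diff(tr[[col]][2:4])) < 1e-12))
  # single frame equals the fold base case
  trk1 <- track_cells(frames[1], c(30, 30))
  expect_identical(nrow(trk1$trajectory), 1L)
  # byte-level determinism of repeated runs
  trk2 <- track_cells(frames, c(30, 30))
  expect_identical(trk$trajectory, trk2$trajectory)
  expect_error(track_cells(list(), c(1, 1)), "empty")
  expect_error(track_cells(frames, c(999, 1)), "seed point")
})

test_that("inversion duality holds end to end, bit-identically", {
  seqd <- generate_sequence(scene_config())
  seed <- c(38, 40)
  trk <- track_cells(seqd$frames, seed)
  inv <- lapply(seqd$frames, invert_gray)
  trk_inv <- track_cells(inv, seed, tracker_config(polarity = "bright"))
  expect_identical(trk$trajectory, trk_inv$trajectory)
})

test_that("core-radius estimates track the true shrinking core", {
  seqd <- generate_sequence(scene_config())
  trk <- track_cells(seqd$frames, c(38, 40))
  err <- track_errors(trk, seqd$truth)
  b <- err$frame >= 3
  expect_gte(stats::cor(err$mean_rb[b], err$rho[b], method = "spearman"), 0.9)
})
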