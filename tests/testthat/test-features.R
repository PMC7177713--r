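test_that("histogram block is normalized and discriminates gray content", {
  set.seed(2)
  img <- matrix(sample.int(256, 1024, replace = TRUE) - 1L, 32, 32)
  f <- extract_features(img, mask = disc_mask(32, 16, 16, 8))
  expect_equal(sum(f[paste0("h", 1:64)]), 1, tolerance = 1e-9)
  expect_length(f, 64 + 12)
})

test_that("a rasterized disc is circular and nearly isotropic", {
  mask <- disc_mask(64, 32, 32, 20)
  f <- extract_features(flat_gray(64), mask)
  expect_gte(f[["circularity"]], 0.95)
  expect_lte(f[["circularity"]], 1.05)
  expect_lt(f[["eccentricity"]], 0.1)
  expect_equal(f[["area"]], sum(mask))
})

test_that("ellipse eccentricity matches the analytic second-moment value", {
  # 2:1 axis ratio: e = sqrt(1 - 1/4)
  mask <- ellipse_mask(96, 48, 48, 30, 15)
  f <- extract_features(flat_gray(96), mask)
  expect_equal(f[["eccentricity"]], sqrt(1 - 1 / 4), tolerance = 0.01)
  # orientation follows the major axis
  mask45 <- ellipse_mask(96, 48, 48, 30, 15, phi = pi / 4)
  f45 <- extract_features(flat_gray(96), mask45)
  expect_equal(abs(f45[["orientation"]]), pi / 4, tolerance = 0.05)
})

test_that("shape descriptors are translation invariant", {
  m1 <- ellipse_mask(128, 40, 44, 22, 11, phi = 0.3)
  m2 <- ellipse_mask(128, 50, 54, 22, 11, phi = 0.3)
  img <- flat_gray(128)
  f1 <- extract_features(img, m1)
  f2 <- extract_features(img, m2)
  keep <- c("area", "perimeter", "circularity", "eccentricity",
            "orientation", paste0("hu", 1:7))
  expect_equal(f1[keep], f2[keep], tolerance = 1e-6)
})

test_that("Hu invariants are stable under rotation of the mask", {
  m0 <- ellipse_mask(128, 64, 64, 24, 12, phi = 0)
  m1 <- ellipse_mask(128, 64, 64, 24, 12, phi = pi / 3)
  f0 <- extract_features(flat_gray(128), m0)
  f1 <- extract_features(flat_gray(128), m1)
  # leading invariants are far from zero; compare relatively
  for (h in paste0("hu", 1:2))
    expect_equal(f0[[h]], f1[[h]], tolerance = 0.02)
})

test_that("an empty mask flags the shape block but keeps the histogram", {
  f <- extract_features(flat_gray(16), matrix(FALSE, 16, 16))
  expect_false(attr(f, "shape_defined"))
  expect_true(all(is.na(f[c("area", "circularity")])))
  expect_equal(sum(f[paste0("h", 1:64)]), 1, tolerance = 1e-9)
})

test_that("weighted Euclidean distance satisfies the metric axioms", {
  set.seed(17)
  p <- 20L
  idx <- structure(list(ids = letters[1:3],
                        features = matrix(rnorm(3 * p), 3),
                        weights = runif(p, 0.2, 5),
                        cov = diag(p)),
                   class = "image_index")
  bad_sym <- 0L; bad_tri <- 0L; bad_neg <- 0L
  for (i in 1:1e4) {
    a <- rnorm(p); b <- rnorm(p); c <- rnorm(p)
    dab <- feature_distance(a, b, index = idx)
    dba <- feature_distance(b, a, index = idx)
    dac <- feature_distance(a, c, index = idx)
    dcb <- feature_distance(c, b, index = idx)
    if (dab < 0) bad_neg <- bad_neg + 1L
    if (!identical(dab, dba)) bad_sym <- bad_sym + 1L
    if (dab > dac + dcb + 1e-12) bad_tri <- bad_tri + 1L
  }
  expect_identical(bad_neg, 0L)
  expect_identical(bad_sym, 0L)
  expect_identical(bad_tri, 0L)
  expect_identical(feature_distance(a, a, index = idx), 0)
  # unit weights reduce to the plain Euclidean distance
  expect_equal(feature_distance(a, b), sqrt(sum((a - b)^2)))
  expect_error(feature_distance(1:3, 1:4), "dimension")
})

test_that("mahalanobis mode uses the index covariance", {
  set.seed(23)
  feats <- matrix(rnorm(200), 20)
  idx <- structure(list(ids = sprintf("i%02d", 1:20), features = feats,
                        weights = rep(1, 10), cov = stats::cov(feats)),
                   class = "image_index")
  a <- feats[1, ]; b <- feats[2, ]
  d <- feature_distance(a, b, mode = "mahalanobis", index = idx)
  expect_gt(d, 0)
  expect_equal(feature_distance(a, a, mode = "mahalanobis", index = idx), 0)
  expect_equal(d, feature_distance(b, a, mode = "mahalanobis", index = idx))
})

test_that("self-query is rank 1 at distance 0 with deterministic ranking", {
  set.seed(31)
  sc <- scene_config(noise_sd = 5, velocity = c(0, 0), shrink = 0.4,
                     n_frames = 6)
  imgs <- generate_sequence(sc)$frames
  names(imgs) <- sprintf("frame%02d", seq_along(imgs))
  idx <- build_index(imgs)
  hits <- query_index(idx, imgs[[3]], top_k = 10)
  expect_identical(hits$id[1], "frame03")
  expect_identical(hits$rank[1], 1L)
  expect_equal(hits$distance[1], 0)
  expect_true(all(diff(hits$distance) >= 0))
  # top_k larger than the index clamps to the full ranking
  expect_identical(nrow(hits), 6L)
  # cutoff 0 keeps only exact duplicates
  expect_identical(nrow(query_index(idx, imgs[[3]], cutoff = 0)), 1L)
})

test_that("index persistence round-trips through JSON", {
  sc <- scene_config(noise_sd = 5, velocity = c(0, 0), n_frames = 3)
  imgs <- generate_sequence(sc)$frames
  names(imgs) <- c("a", "b", "c")
  idx <- build_index(imgs)
  path <- withr::local_tempfile(fileext = ".json")
  write_index(idx, path)
  idx2 <- read_index(path)
  expect_identical(idx2$ids, idx$ids)
  expect_equal(idx2$features, idx$features, tolerance = 1e-12)
  hits <- query_index(idx2, imgs[["b"]])
  expect_identical(hits$id[1], "b")
})
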