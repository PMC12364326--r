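# Windowing, moment centring, ROI geometry, pseudo-colour encoding, edge
# extraction and label pyramids.

test_that("HU windowing maps floor/level/ceiling to 0 / 0.5 / 1 and is monotone", {
  spec <- window_spec()  # level -600, width 1200 -> HU in [-1200, 0]
  expect_equal(window_hu(-600, spec), 0.5)
  expect_equal(window_hu(-2000, spec), 0.0)
  expect_equal(window_hu(-1200, spec), 0.0)
  expect_equal(window_hu(0, spec), 1.0)
  expect_equal(window_hu(500, spec), 1.0)
  hu <- seq(-2000, 500, by = 7)
  expect_true(all(diff(window_hu(hu, spec)) >= 0))
  expect_error(window_spec(width = 0), "positive")
})

test_that("mask centroid equals the raw-moment centroid", {
  m <- matrix(0L, 32, 32)
  m[10, 20] <- 1L
  expect_equal(unname(mask_moment_center(m)), c(10, 20))
  m2 <- matrix(0L, 32, 32)
  m2[8:11, 8:11] <- 1L
  expect_equal(unname(mask_moment_center(m2)), c(9.5, 9.5))
  # L-shaped mask: brute-force average of coordinates
  m3 <- matrix(0L, 16, 16)
  px <- rbind(c(1, 1), c(1, 2), c(2, 1))
  m3[px] <- 1L
  expect_equal(unname(mask_moment_center(m3)),
               c(mean(px[, 1]), mean(px[, 2])))
  expect_error(mask_moment_center(matrix(0L, 4, 4)), "empty")
})

test_that("ROI extraction crops, pads, and re-centres consistently", {
  sl <- matrix(rnorm(64 * 64), 64, 64)
  # centred crop: no padding
  crop <- extract_roi(sl, c(32.5, 32.5), 32L)
  expect_equal(crop, sl[17:48, 17:48])
  # corner centre: zero padding on two sides
  corner <- extract_roi(sl, c(1, 1), 32L)
  expect_true(all(corner[1:15, ] == 0))
  expect_true(all(corner[, 1:15] == 0))
  expect_equal(corner[16:32, 16:32], sl[1:17, 1:17])
  expect_error(extract_roi(sl, c(32, 32), 31L), "even")
  # self-consistency: re-centroid of the cropped mask sits at the ROI centre
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(0L, 200, 200)
    r0 <- sample(40:160, 1); c0 <- sample(40:160, 1); rad <- sample(3:10, 1)
    rows <- matrix(seq_len(200), 200, 200)
    cols <- t(rows)
    m[(rows - r0)^2 + (cols - c0)^2 <= rad^2] <- 1L
    ctr <- mask_moment_center(m)
    crop <- extract_roi(m, ctr, 128L)
    ctr2 <- mask_moment_center(crop)
    expect_lt(max(abs(ctr2 - c(64.5, 64.5))), 1)
  }
})

test_that("pseudo-colour encoding places prev/cur/next into R/G/B", {
  vol <- array(0, c(5, 64, 64))
  vol[2, , ] <- 0.3; vol[3, , ] <- 0.5; vol[4, , ] <- 0.7
  pc <- encode_pseudocolor(vol, 3L, c(32.5, 32.5), 32L)
  expect_equal(unique(as.vector(pc[, , 1])), 0.3)
  expect_equal(unique(as.vector(pc[, , 2])), 0.5)
  expect_equal(unique(as.vector(pc[, , 3])), 0.7)
  # identical slices -> identical channels
  vol2 <- array(rep(vol[3, , ], each = 5), c(5, 64, 64))
  pc2 <- encode_pseudocolor(vol2, 3L, c(32.5, 32.5), 32L)
  expect_equal(pc2[, , 1], pc2[, , 2])
  expect_equal(pc2[, , 2], pc2[, , 3])
  # structure on the current slice only -> nonzero only in G there
  vol3 <- array(0, c(5, 64, 64))
  vol3[3, 30:34, 30:34] <- 1
  pc3 <- encode_pseudocolor(vol3, 3L, c(32, 32), 32L)
  expect_true(all(pc3[, , 1] == 0) && all(pc3[, , 3] == 0))
  expect_gt(sum(pc3[, , 2]), 0)
  # boundary slices replicate the missing neighbour
  pc4 <- encode_pseudocolor(vol, 1L, c(32.5, 32.5), 32L)
  expect_equal(pc4[, , 1], pc4[, , 2])
})

test_that("phantom vessels are bright in all three channels along their track", {
  ph <- generate_phantom(tiny_phantom_config(seed = 31L))
  vol01 <- window_hu(ph$volume)
  cs <- ph$nodule_center[["slice"]]
  ctr <- mask_moment_center(ph$mask_volume[cs, , ])
  pc <- encode_pseudocolor(vol01, cs, ctr, 32L)
  # vessel voxels present on all three encoded slices
  v_prev <- extract_roi(ph$vessel_volume[cs - 1, , ], ctr, 32L)
  v_cur <- extract_roi(ph$vessel_volume[cs, , ], ctr, 32L)
  v_next <- extract_roi(ph$vessel_volume[cs + 1, , ], ctr, 32L)
  track <- v_prev == 1 & v_cur == 1 & v_next == 1
  skip_if(sum(track) == 0)  # vessel may fall outside this ROI
  ch_min <- pmin(pc[, , 1], pc[, , 2], pc[, , 3])
  expect_true(all(ch_min[track] > 0))
})

test_that("edge maps are exact 1-pixel boundaries", {
  sq <- matrix(0L, 16, 16)
  sq[6:10, 6:10] <- 1L
  e <- extract_edge_map(sq)
  expect_equal(sum(e), 16)  # 5x5 square has a 16-pixel perimeter ring
  expect_true(all(e[7:9, 7:9] == 0))
  single <- matrix(0L, 8, 8); single[4, 5] <- 1L
  expect_equal(extract_edge_map(single), single)
  expect_equal(sum(extract_edge_map(matrix(0L, 8, 8))), 0)
  # disc of radius 8: boundary length close to the circumference
  m <- matrix(0L, 32, 32)
  rows <- matrix(seq_len(32), 32, 32); cols <- t(rows)
  m[(rows - 16)^2 + (cols - 16)^2 <= 64] <- 1L
  n_edge <- sum(extract_edge_map(m))
  expect_lt(abs(n_edge - 2 * pi * 8) / (2 * pi * 8), 0.2)
})

test_that("canny mode produces a ring on a disc", {
  m <- matrix(0, 64, 64)
  rows <- matrix(seq_len(64), 64, 64); cols <- t(rows)
  m[(rows - 32)^2 + (cols - 32)^2 <= 100] <- 1
  e <- extract_edge_map(m, method = "canny")
  expect_gt(sum(e), 0.5 * 2 * pi * 10)
  expect_lt(sum(e), 2.5 * 2 * pi * 10)
  # edge pixels hug the true boundary
  d <- sqrt((rows - 32)^2 + (cols - 32)^2)
  expect_true(all(abs(d[e == 1] - 10) < 3))
})

test_that("max-pool pyramids preserve structure and match a block oracle", {
  z <- matrix(0L, 128, 128)
  expect_true(all(vapply(build_pyramid(z)$levels, sum, numeric(1)) == 0))
  s <- matrix(0L, 128, 128); s[37, 91] <- 1L
  expect_true(all(vapply(build_pyramid(s)$levels, sum, numeric(1)) == 1))
  # disc radius 16: level-4 equals the brute-force 8x8 block max
  m <- matrix(0L, 128, 128)
  rows <- matrix(seq_len(128), 128, 128); cols <- t(rows)
  m[(rows - 64)^2 + (cols - 64)^2 <= 256] <- 1L
  l4 <- build_pyramid(m)$levels[[4]]
  oracle <- matrix(0L, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- max(m[(8 * i - 7):(8 * i), (8 * j - 7):(8 * j)])
  expect_identical(l4, oracle)
  expect_error(build_pyramid(matrix(0L, 100, 100)), "divisible")
})

test_that("windowing commutes with interior ROI cropping", {
  ph <- generate_phantom(tiny_phantom_config(seed = 13L))
  sl <- ph$volume[3, , ]
  ctr <- c(24, 24)  # interior: no padding involved
  a <- window_hu(extract_roi(sl, ctr, 16L))
  b <- extract_roi(window_hu(sl), ctr, 16L)
  expect_equal(a, b)
})

test_that("preprocess_sample assembles a complete composite", {
  ph <- generate_phantom(tiny_phantom_config(seed = 17L))
  cs <- preprocess_sample(ph$volume, ph$mask_volume, size = 32L)
  expect_equal(dim(cs$image), c(32, 32, 3))
  expect_true(all(cs$image >= 0 & cs$image <= 1))
  expect_true(all(cs$mask %in% c(0L, 1L)))
  expect_equal(length(cs$y_d$levels), 4)
  expect_equal(cs$y_d$kind, "mask")
  expect_equal(cs$y_g$kind, "edge")
  expect_equal(vapply(cs$y_d$levels, nrow, integer(1)), c(32L, 16L, 8L, 4L))
  # level 1 of the mask pyramid is the mask itself
  expect_identical(cs$y_d$levels[[1]], cs$mask)
})
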