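test_that("U-phantom geometry is validated and the raster is binary", {
  expect_error(make_u_phantom(128, 128, wall_thickness = 0),
               "invalid geometry")
  expect_error(make_u_phantom(32, 32), "invalid geometry")
  expect_error(make_u_phantom(128, 128, wall_thickness = 80,
                              cavity_width = 80), "invalid geometry")
  p <- small_phantom()
  expect_setequal(unique(as.vector(p$binary)), c(0, 1))
  expect_true(all(p$frame >= 0 & p$frame <= 1))
  expect_gt(sum(p$wall_mask), 0)
})

test_that("mask area matches brute-force enumeration of the U region", {
  p <- small_phantom()
  g <- p$geometry
  # direct pixel loop over the analytic region definition
  count <- 0L
  for (r in seq_len(g$height)) for (c in seq_len(g$width)) {
    dx <- abs(c - g$cx)
    in_limb <- r >= g$top && r <= g$r0 && dx >= g$a && dx <= g$b
    d <- sqrt((r - g$r0)^2 + (c - g$cx)^2)
    in_base <- r > g$r0 && d >= g$a && d <= g$b
    if (in_limb || in_base) count <- count + 1L
  }
  expect_identical(sum(p$wall_mask), count)
})

test_that("wall mask is U-shaped: row support connected, open cavity at top", {
  p <- small_phantom()
  rows_with_wall <- which(rowSums(p$wall_mask) > 0)
  expect_identical(rows_with_wall, min(rows_with_wall):max(rows_with_wall))
  g <- p$geometry
  # cavity interior empty, open upward
  expect_true(all(!p$wall_mask[seq_len(g$r0), round(g$cx)]))
})

test_that("affine contraction stores the prescribed ground truth", {
  p <- small_phantom()
  gp <- affine_contract(p, 2, -2, 1)
  g <- p$geometry
  left <- round(c((g$top + g$r0) / 2, g$cx - g$a - g$wall_thickness / 2))
  right <- round(c((g$top + g$r0) / 2, g$cx + g$a + g$wall_thickness / 2))
  expect_equal(gp$gt_flow$u[left[1], left[2]], 2)
  expect_equal(gp$gt_flow$v[left[1], left[2]], 1)
  expect_equal(gp$gt_flow$u[right[1], right[2]], -2)
  expect_equal(gp$gt_flow$v[right[1], right[2]], 1)
  expect_true(all(is.finite(gp$gt_flow$u)), all(is.finite(gp$gt_flow$v)))
})

test_that("zero motion is the identity and background flow is zero", {
  p <- small_phantom()
  gp0 <- affine_contract(p, 0, 0, 0)
  expect_equal(gp0$frame2, gp0$frame1, tolerance = 1e-12)
  expect_true(all(gp0$gt_flow$u == 0) && all(gp0$gt_flow$v == 0))
  gp <- affine_contract(p, 2, -2, 1)
  far <- !comflow:::mask_dilate(p$wall_mask, 4L)
  expect_true(all(gp$gt_flow$u[far] == 0))
  expect_true(all(gp$gt_flow$v[far] == 0))
})

test_that("motion that would collide limbs or exceed geometry errors", {
  p <- small_phantom()
  expect_error(affine_contract(p, 20, -20, 0), "invalid motion")
  expect_error(affine_contract(p, 0, 0, 60), "invalid motion")
})

test_that("frame2 is consistent with the ground-truth flow by backward warp", {
  p <- small_phantom()
  gp <- affine_contract(p, 2, -2, 1)
  rewarped <- warp_image(gp$frame2, gp$gt_flow)$image
  err <- abs(rewarped - gp$frame1)
  expect_lt(mean(err[gp$roi]), 0.02)
})

test_that("mask area is conserved under pure translation (within 2%)", {
  p <- small_phantom()
  gp <- affine_contract(p, 1, 1, 1)  # rigid translation of everything
  expect_lt(abs(sum(gp$mask2) - sum(gp$mask1)) / sum(gp$mask1), 0.02)
})

test_that("shadow attenuates exactly inside the ellipse", {
  p <- small_phantom()
  f <- p$frame
  out0 <- add_shadow(f, c(64, 80), c(20, 12), 0)
  expect_equal(out0$frame, f)
  out1 <- add_shadow(f, c(64, 80), c(20, 12), 1)
  expect_true(all(out1$frame[out1$region] == 0))
  expect_equal(out1$frame[!out1$region], f[!out1$region])
  att <- 0.7
  out <- add_shadow(f, c(64, 80), c(20, 12), att)
  # pixel-sum oracle: mean inside region scales by (1 - attenuation)
  expect_equal(mean(out$frame[out$region]),
               (1 - att) * mean(f[out$region]), tolerance = 1e-12)
  expect_error(add_shadow(f, c(64, 80), c(20, 12), 1.5), "attenuation")
  expect_error(add_shadow(f, c(-500, -500), c(5, 5), 0.5), "intersect")
})

test_that("speckle is reproducible, clipped, and sigma = 0 is identity", {
  p <- small_phantom()
  expect_identical(add_speckle(p$frame, 0), p$frame)
  a <- add_speckle(p$frame, 0.5, seed = 7)
  b <- add_speckle(p$frame, 0.5, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, add_speckle(p$frame, 0.5, seed = 8)))
  big <- add_speckle(p$frame, 5, seed = 7)
  expect_true(all(big >= 0 & big <= 1))
  # generator state is restored
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1); invisible(add_speckle(p$frame, 0.3, seed = 99))
  expect_identical(stats::runif(1), x1)
})

test_that("synthetic cycle returns to baseline and single step reduces to affine pair", {
  p <- small_phantom()
  cyc <- synth_cycle(p, n_frames = 8, peak_left_dx = 2, peak_right_dx = -2,
                     peak_dy = 1)
  expect_length(cyc$seq$frames, 8)
  expect_length(cyc$flows, 7)
  # cumulative ground-truth displacement returns to ~0 at cycle end
  expect_equal(cyc$schedule$amplitude[1], 0)
  expect_lt(abs(cyc$schedule$amplitude[8]), 1e-12)
  expect_equal(cyc$seq$frames[[8]], cyc$seq$frames[[1]], tolerance = 1e-9)
  # two cycles concatenate periods
  cyc2 <- synth_cycle(p, n_frames = 8, n_cycles = 2)
  expect_length(cyc2$seq$frames, 15)
  # n_frames = 2 with peaks reduces to nothing moving (sin(0)=sin(pi)=0)
  expect_error(synth_cycle(p, n_frames = 1), "n_frames")
})

test_that("cycle ground-truth flows are consistent frame to frame", {
  p <- small_phantom()
  cyc <- synth_cycle(p, n_frames = 6, peak_left_dx = 2, peak_right_dx = -2,
                     peak_dy = 1)
  for (k in c(2, 4)) {
    rewarped <- warp_image(cyc$seq$frames[[k + 1]], cyc$flows[[k]])$image
    roi <- comflow:::mask_erode(cyc$masks[[k]], 2L)
    expect_lt(mean(abs(rewarped - cyc$seq$frames[[k]])[roi]), 0.02)
  }
})
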