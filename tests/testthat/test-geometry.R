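test_that("phantom contour is a valid landmarked polyline", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  expect_s3_class(ct, "wall_contour")
  expect_identical(ct$base_left_index, 1L)
  expect_identical(ct$base_right_index, nrow(ct$endo_points))
  expect_gt(ct$apex_index, 1)
  expect_lt(ct$apex_index, nrow(ct$endo_points))
  # apex is the deepest endocardial point
  expect_equal(ct$endo_points[ct$apex_index, 1], max(ct$endo_points[, 1]),
               tolerance = 1)
})

test_that("six segments partition the endocardium and wall mask", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  segs <- split_six(ct, p$wall_mask)
  expect_length(segs, 6)
  cum <- comflow:::arc_lengths(ct$endo_points)
  total <- cum[length(cum)]
  span_len <- vapply(segs, function(s) cum[s$span[2]] - cum[s$span[1]],
                     numeric(1))
  expect_equal(sum(span_len), total, tolerance = 1e-9 * total)
  # masks are disjoint and tile the wall exactly
  stack <- Reduce(`+`, lapply(segs, function(s) s$roi_mask + 0))
  expect_true(all(stack[p$wall_mask] == 1))
  expect_true(all(stack[!p$wall_mask] == 0))
  expect_true(all(vapply(segs, function(s) sum(s$roi_mask) > 0, logical(1))))
})

test_that("a symmetric contour yields mirror-symmetric segment boundaries", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  segs <- split_six(ct, p$wall_mask)
  cum <- comflow:::arc_lengths(ct$endo_points)
  total <- cum[length(cum)]
  lens <- vapply(segs, function(s) cum[s$span[2]] - cum[s$span[1]], numeric(1))
  expect_equal(lens[1:3], rev(lens[4:6]), tolerance = 0.05 * total / 6)
  # segment ROI areas mirror too
  areas <- vapply(segs, function(s) sum(s$roi_mask), numeric(1))
  expect_equal(areas[1:3], rev(areas[4:6]), tolerance = 0.02 * sum(areas))
})

test_that("subdivision yields 12 segments that nest in their parents", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  segs <- split_six(ct, p$wall_mask)
  subs <- subdivide(segs, ct)
  expect_length(subs, 12)
  cum <- comflow:::arc_lengths(ct$endo_points)
  for (j in 1:6) {
    kids <- subs[(2 * j - 1):(2 * j)]
    # children partition the parent span and mask
    expect_identical(kids[[1]]$span[1], segs[[j]]$span[1])
    expect_identical(kids[[2]]$span[2], segs[[j]]$span[2])
    expect_identical(kids[[1]]$span[2], kids[[2]]$span[1])
    u <- kids[[1]]$roi_mask | kids[[2]]$roi_mask
    expect_identical(u, segs[[j]]$roi_mask)
    expect_false(any(kids[[1]]$roi_mask & kids[[2]]$roi_mask))
    # equal arc halves within one vertex spacing
    l1 <- cum[kids[[1]]$span[2]] - cum[kids[[1]]$span[1]]
    l2 <- cum[kids[[2]]$span[2]] - cum[kids[[2]]$span[1]]
    spacing <- max(diff(cum[segs[[j]]$span[1]:segs[[j]]$span[2]]))
    expect_lt(abs(l1 - l2), 2 * spacing)
  }
  expect_true(all(grepl("-(upper|lower)$",
                        vapply(subs, `[[`, character(1), "label"))))
})

test_that("segment center: straight span gives the chord midpoint", {
  # vertical straight polyline: chord midpoint lies on the line
  pts <- cbind(seq(10, 30, by = 1), 5)
  epi <- cbind(seq(10, 30, by = 1), 2)
  ct <- wall_contour(pts, epi, apex_index = 11L)
  ctr <- segment_center(c(1L, 21L), ct)
  expect_equal(ctr, c(20, 5), tolerance = 1e-9)
})

test_that("segment center on a circular arc matches circle geometry", {
  # semicircular apex cap of radius R centered at (50, 50)
  th <- seq(0, pi, length.out = 181)
  R <- 20
  pts <- cbind(50 + R * sin(th), 50 - R * cos(th))
  ct <- wall_contour(pts, pts + c(5, 0), apex_index = 91L)
  ctr <- segment_center(c(1L, 181L), ct)
  # chord joins the two ends (row 50 both): midpoint (50, 50); horizontal
  # march hits the circle at row 50 -> analytic intersection (50, 50 ± R)
  expect_equal(ctr[1], 50, tolerance = 1e-9)
  expect_equal(abs(ctr[2] - 50), R, tolerance = 0.01)
})

test_that("segment center falls back to arc midpoint for horizontal spans", {
  pts <- cbind(10, seq(5, 25, by = 1))   # constant row: no horizontal hit
  ct <- wall_contour(pts, cbind(7, seq(5, 25, by = 1)), apex_index = 11L)
  ctr <- segment_center(c(1L, 21L), ct)
  expect_equal(ctr, c(10, 15), tolerance = 1e-9)
})

test_that("tangent/normal: unit, orthogonal, cavity-directed", {
  # collinear horizontal travel
  tn <- tangent_normal(c(5, 1), c(5, 2), c(5, 3), toward = c(10, 2))
  expect_equal(tn$tangent, c(0, 1), tolerance = 1e-12)
  expect_equal(tn$normal, c(1, 0), tolerance = 1e-12)  # toward larger row

  # three consecutive points on a unit circle: tangent perpendicular to radius
  th <- c(0.4, 0.5, 0.6)
  pts <- cbind(sin(th), cos(th))
  tn <- tangent_normal(pts[1, ], pts[2, ], pts[3, ], toward = c(0, 0))
  expect_lt(abs(sum(tn$tangent * pts[2, ])), 1e-6)
  expect_lt(sum(tn$normal * pts[2, ]), 0)  # points inward

  # random non-degenerate triples: orthonormal basis
  set.seed(3)
  for (i in 1:20) {
    v <- matrix(stats::runif(6, -5, 5), 3, 2)
    if (min(sum((v[2, ] - v[1, ])^2), sum((v[3, ] - v[2, ])^2)) < 1e-6) next
    tn <- tryCatch(tangent_normal(v[1, ], v[2, ], v[3, ], toward = c(0, 0)),
                   error = function(e) NULL)
    if (is.null(tn)) next  # opposing directions are a declared degeneracy
    expect_equal(sum(tn$tangent^2), 1, tolerance = 1e-12)
    expect_equal(sum(tn$normal^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(tn$tangent * tn$normal)), 1e-12)
  }
  expect_error(tangent_normal(c(1, 1), c(1, 1), c(1, 1), c(0, 0)),
               "degenerate")
})

test_that("all phantom segment normals point into the cavity", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  segs <- split_six(ct, p$wall_mask)
  cavity <- colMeans(ct$endo_points)
  for (s in segs) {
    expect_equal(sum(s$tangent^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(s$tangent * s$normal)), 1e-12)
    expect_gt(sum(s$normal * (cavity - s$center)), 0)
  }
})

test_that("decomposition conserves energy and inverts exactly", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  segs <- split_six(ct, p$wall_mask)
  set.seed(4)
  u <- matrix(stats::rnorm(128 * 128), 128, 128)
  v <- matrix(stats::rnorm(128 * 128), 128, 128)
  w <- flow_field(u, v)
  for (s in segs[c(1, 3, 5)]) {
    d <- decompose(w, s)
    expect_equal(d$radial^2 + d$circumferential^2, u^2 + v^2,
                 tolerance = 1e-12)
    # reconstruct: radial * normal + circumferential * tangent
    u_rec <- d$radial * s$normal[2] + d$circumferential * s$tangent[2]
    v_rec <- d$radial * s$normal[1] + d$circumferential * s$tangent[1]
    expect_equal(u_rec, u, tolerance = 1e-12)
    expect_equal(v_rec, v, tolerance = 1e-12)
  }
  # axis-aligned hand check
  seg <- segs[[1]]
  seg$tangent <- c(0, 1); seg$normal <- c(1, 0)
  d <- decompose(flow_field(matrix(1, 2, 2), matrix(1, 2, 2)), seg)
  expect_true(all(d$circumferential == 1))
  expect_true(all(d$radial == 1))
})

test_that("flow along the normal gives unit radial, zero circumferential", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  seg <- split_six(ct, p$wall_mask)[[2]]
  n <- seg$normal
  w <- flow_field(matrix(n[2], 4, 4), matrix(n[1], 4, 4))
  d <- decompose(w, seg)
  expect_equal(d$radial, matrix(1, 4, 4), tolerance = 1e-12)
  expect_equal(d$circumferential, matrix(0, 4, 4), tolerance = 1e-12)
})

test_that("degenerate contours are rejected", {
  pts <- cbind(seq(1, 10), 5)
  expect_error(wall_contour(pts, pts, apex_index = 1L), "apex")
  expect_error(wall_contour(pts[c(1, 1, 2:10), ], pts, apex_index = 5L),
               "repeated")
})

test_that("contour rasterization matches the phantom wall closely", {
  p <- small_phantom()
  ct <- phantom_contour(p)
  m <- comflow:::contour_mask(ct, dim(p$frame))
  agree <- sum(m & p$wall_mask) / sum(m | p$wall_mask)
  expect_gt(agree, 0.9)
})
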