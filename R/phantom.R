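# U-shaped ventricular-wall phantom with exact ground-truth motion.
#
# The wall is defined analytically: two vertical limbs joined by a half
# annulus (the apex cap), opening upward. Because the geometry is analytic,
# moved frames are rasterized from exactly inverted coordinates and the
# ground-truth flow is known per pixel, which makes the phantom the
# reference input for all accuracy experiments.

#' Construct a U-shaped ventricular wall phantom
#'
#' Builds a binary U-shaped wall (two vertical limbs plus a half-annular
#' apex cap) on a black background, optionally Gaussian-smoothed, together
#' with its exact pixel mask and the analytic geometry. The smoothed frame
#' is what flow estimators see; the binary raster and mask stay exact.
#'
#' @param height,width image size in pixels (>= 64).
#' @param wall_thickness myocardial wall thickness in pixels (> 0).
#' @param cavity_width inner cavity width in pixels (> 0).
#' @param smooth_sigma Gaussian smoothing of the rendered frame, in pixels;
#'   0 keeps the frame binary.
#' @return an object of class `phantom`: list with `frame` (intensities in
#'   [0,1]), `binary` (pre-smoothing raster, values exactly 0/1),
#'   `wall_mask` (logical), and `geometry`.
#' @examples
#' p <- make_u_phantom(128, 128, wall_thickness = 10, cavity_width = 30)
#' sum(p$wall_mask) > 0
#' @export
make_u_phantom <- function(height = 256L, width = 256L, wall_thickness = 20,
                           cavity_width = 60, smooth_sigma = 1) {
  if (height < 64 || width < 64)
    stop("invalid geometry: image must be at least 64 x 64")
  if (wall_thickness <= 0 || cavity_width <= 0)
    stop("invalid geometry: wall_thickness and cavity_width must be positive")
  cx <- (width + 1) / 2
  a <- cavity_width / 2
  b <- a + wall_thickness
  top <- max(4, round(0.12 * height))
  r0 <- height - max(6, round(0.10 * height)) - b
  if (2 * b > width - 8 || r0 - top < 8)
    stop("invalid geometry: wall does not fit inside the image")
  geom <- list(height = height, width = width, wall_thickness = wall_thickness,
               cavity_width = cavity_width, cx = cx, a = a, b = b,
               top = top, r0 = r0, smooth_sigma = smooth_sigma)
  rr <- matrix(rep.int(seq_len(height), width), height, width)
  cc <- matrix(rep(seq_len(width), each = height), height, width)
  binary <- matrix(as.numeric(u_indicator(rr, cc, geom)), height, width)
  frame <- gauss_blur(binary, smooth_sigma)
  frame <- pmin(pmax(frame, 0), 1)
  structure(list(frame = frame, binary = binary, wall_mask = binary == 1,
                 geometry = geom), class = "phantom")
}

# Analytic wall indicator at continuous original coordinates
u_indicator <- function(r, c, geom) {
  dx <- abs(c - geom$cx)
  limb <- r >= geom$top & r <= geom$r0 & dx >= geom$a & dx <= geom$b
  d <- sqrt((r - geom$r0)^2 + (c - geom$cx)^2)
  base <- r > geom$r0 & d >= geom$a & d <= geom$b
  limb | base
}

#' @export
print.phantom <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("U-wall phantom %d x %d px, wall %.0f px, cavity %.0f px\n",
              g$height, g$width, g$wall_thickness, g$cavity_width))
  cat(sprintf("  wall mask: %d px (%.1f%% of image)\n", sum(x$wall_mask),
              100 * mean(x$wall_mask)))
  invisible(x)
}

# Horizontal displacement of an original column: left limb moves by
# left_dx, right limb by right_dx, blended linearly across the cavity span
# of the apex cap so the field is continuous.
blend_dx <- function(c0, geom, left_dx, right_dx) {
  lo <- geom$cx - geom$a
  hi <- geom$cx + geom$a
  t <- pmin(pmax((c0 - lo) / (hi - lo), 0), 1)
  left_dx + (right_dx - left_dx) * t
}

# Exact inverse of c0 + blend_dx(c0): original column that lands on column c
invert_col <- function(c, geom, left_dx, right_dx) {
  lo <- geom$cx - geom$a
  hi <- geom$cx + geom$a
  slope <- (right_dx - left_dx) / (hi - lo)
  mid <- (c - left_dx + slope * lo) / (1 + slope)
  out <- ifelse(c <= lo + left_dx, c - left_dx,
                ifelse(c >= hi + right_dx, c - right_dx, mid))
  out
}

#' Apply the affine contraction motion to a phantom
#'
#' Moves the left limb horizontally by `left_dx` pixels, the right limb by
#' `right_dx`, blends the horizontal displacement linearly across the apex
#' cap, and shifts the whole wall down by `global_dy`. The second frame is
#' rendered by bilinear sampling of the first frame at the exactly inverted
#' coordinates, so the prescribed displacement field is the ground truth by
#' construction. Positive `left_dx` with negative `right_dx` contracts the
#' cavity.
#'
#' @param p a [make_u_phantom] phantom.
#' @param left_dx,right_dx,global_dy displacements in pixels (u = +columns
#'   rightward, v = +rows downward).
#' @return an object of class `gt_pair`: `frame1`, `frame2`, `gt_flow`
#'   (a [flow_field], zero outside the dilated wall), `roi` (wall mask
#'   eroded by 1 px, where errors are evaluated), `mask1`, `mask2`.
#' @examples
#' p <- make_u_phantom(128, 128, 10, 30)
#' gp <- affine_contract(p, 2, -2, 1)
#' range(gp$gt_flow$u)
#' @export
affine_contract <- function(p, left_dx = 2, right_dx = -2, global_dy = 1) {
  stopifnot(inherits(p, "phantom"))
  g <- p$geometry
  lim <- g$wall_thickness + g$cavity_width
  if (max(abs(c(left_dx, right_dx, global_dy))) >= lim)
    stop("invalid motion: displacement exceeds wall_thickness + cavity_width")
  if (left_dx - right_dx >= g$cavity_width)
    stop("invalid motion: limbs would collide")
  h <- g$height; w <- g$width
  rr <- matrix(rep.int(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  c0 <- invert_col(cc, g, left_dx, right_dx)
  r0 <- rr - global_dy
  frame2 <- matrix(bilinear_sample(p$frame, as.vector(r0),
                                   as.vector(c0))$values, h, w)
  mask2 <- u_indicator(r0, c0, g)
  u <- blend_dx(cc, g, left_dx, right_dx)
  v <- matrix(global_dy, h, w)
  maxmove <- ceiling(max(abs(c(left_dx, right_dx, global_dy)))) + 1L
  support <- mask_dilate(p$wall_mask, maxmove)
  u[!support] <- 0
  v[!support] <- 0
  structure(list(frame1 = p$frame, frame2 = frame2,
                 gt_flow = flow_field(u, v),
                 roi = mask_erode(p$wall_mask, 1L),
                 mask1 = p$wall_mask, mask2 = mask2,
                 motion = c(left_dx = left_dx, right_dx = right_dx,
                            global_dy = global_dy)),
            class = "gt_pair")
}

#' Multiply intensities inside an elliptical region (acoustic shadow)
#'
#' Emulates an acoustic shadow: intensities inside the ellipse are
#' multiplied by `1 - attenuation`; pixels outside are unchanged.
#'
#' @param frame numeric matrix.
#' @param center (row, col) of the ellipse center.
#' @param axes (row semi-axis, col semi-axis) in pixels.
#' @param attenuation fraction of intensity removed, in [0, 1].
#' @return list with `frame` (attenuated raster) and `region` (logical
#'   matrix of the shadowed pixels).
#' @export
add_shadow <- function(frame, center, axes, attenuation = 0.8) {
  if (attenuation < 0 || attenuation > 1)
    stop("add_shadow: attenuation must be in [0, 1]")
  nr <- nrow(frame); nc <- ncol(frame)
  rr <- matrix(rep.int(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  region <- ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
  if (!any(region))
    stop("add_shadow: ellipse does not intersect the image")
  out <- frame
  out[region] <- out[region] * (1 - attenuation)
  list(frame = out, region = region)
}

#' Add reproducible speckle noise to a frame
#'
#' Multiplicative Gaussian-derived texture, `frame * (1 + sigma * N(0,1))`,
#' clipped to [0, 1]. The generator state is saved and restored, so the
#' result is a pure function of the inputs and seed.
#'
#' @param frame numeric matrix with values in [0, 1].
#' @param sigma noise standard deviation (intensity units, >= 0).
#' @param seed integer seed.
#' @return numeric matrix in [0, 1].
#' @export
add_speckle <- function(frame, sigma, seed = 1L) {
  if (sigma < 0) stop("add_speckle: sigma must be >= 0")
  if (sigma == 0) return(frame)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(frame), 0, sigma), nrow(frame), ncol(frame))
  pmin(pmax(frame * (1 + noise), 0), 1)
}

#' Standard affine-contraction phantom experiment
#'
#' Builds the reference ground-truth pair used throughout the accuracy
#' experiments: a 256 x 256 U-wall phantom whose left limb moves 2 px to
#' the right, right limb 2 px to the left, and whole wall 1 px down, with
#' an optional acoustic shadow (0.8 attenuation) over the right wall
#' applied to both frames at a fixed image position, and optional speckle
#' texture applied to the wall before the motion (so it moves with the
#' tissue).
#'
#' @param shadow add the static elliptical shadow over the right wall.
#' @param speckle_sigma multiplicative speckle level on the base frame
#'   (0 = the plain smoothed binary wall).
#' @param seed seed for the speckle texture.
#' @param height,width,wall_thickness,cavity_width,smooth_sigma phantom
#'   geometry, passed to [make_u_phantom].
#' @param attenuation shadow strength passed to [add_shadow].
#' @return a `gt_pair` (see [affine_contract]); when `shadow = TRUE` it
#'   carries the logical shadow region as element `shadow_region`.
#' @export
phantom_experiment <- function(shadow = TRUE, speckle_sigma = 0, seed = 1L,
                               height = 256L, width = 256L,
                               wall_thickness = 20, cavity_width = 60,
                               smooth_sigma = 1, attenuation = 0.8) {
  p <- make_u_phantom(height, width, wall_thickness, cavity_width,
                      smooth_sigma)
  if (speckle_sigma > 0)
    p$frame <- gauss_blur(add_speckle(p$frame, speckle_sigma, seed), 0.8)
  gp <- affine_contract(p, left_dx = 2, right_dx = -2, global_dy = 1)
  if (shadow) {
    g <- p$geometry
    center <- c((g$top + g$r0) / 2, g$cx + (g$a + g$b) / 2)
    axes <- c(0.16 * height, 0.1 * width)
    sh1 <- add_shadow(gp$frame1, center, axes, attenuation)
    gp$frame1 <- sh1$frame
    gp$frame2 <- add_shadow(gp$frame2, center, axes, attenuation)$frame
    gp$shadow_region <- sh1$region
  }
  gp
}

#' Simulate a contraction-relaxation cycle with ground-truth flows
#'
#' Generates `n_frames` frames per cycle following a half-sine schedule of
#' the cumulative displacement: zero at the first frame, peaking mid-cycle
#' at (`peak_left_dx`, `peak_right_dx`, `peak_dy`), back to zero at the
#' last frame. With `n_cycles = 2` the contraction-relaxation process runs
#' twice back to back. Each frame and each per-frame-pair incremental
#' ground-truth flow is derived from the analytic geometry.
#'
#' @param p a [make_u_phantom] phantom.
#' @param n_frames frames per cycle (>= 2).
#' @param peak_left_dx,peak_right_dx,peak_dy peak cumulative displacements
#'   in pixels.
#' @param n_cycles number of consecutive cycles.
#' @param mm_per_px,frame_interval spatial and temporal calibration
#'   attached to the returned sequence.
#' @return list of class `phantom_cycle`: `seq` (an `image_sequence`),
#'   `flows` (list of incremental [flow_field]s, one per frame pair),
#'   `masks` (per-frame wall masks), `schedule` (cumulative displacement
#'   per frame).
#' @export
synth_cycle <- function(p, n_frames = 12L, peak_left_dx = 2,
                        peak_right_dx = -2, peak_dy = 1, n_cycles = 1L,
                        mm_per_px = 1, frame_interval = 0.02) {
  stopifnot(inherits(p, "phantom"), n_frames >= 2)
  g <- p$geometry
  amp1 <- sin(pi * (seq_len(n_frames) - 1) / (n_frames - 1))
  amp <- amp1
  if (n_cycles > 1)
    for (i in seq_len(n_cycles - 1)) amp <- c(amp, amp1[-1])
  nf <- length(amp)
  h <- g$height; w <- g$width
  rr <- matrix(rep.int(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  frames <- vector("list", nf)
  masks <- vector("list", nf)
  orig_cols <- vector("list", nf)  # original column per frame-k pixel
  for (k in seq_len(nf)) {
    L <- peak_left_dx * amp[k]; R <- peak_right_dx * amp[k]
    D <- peak_dy * amp[k]
    c0 <- invert_col(cc, g, L, R)
    r0 <- rr - D
    frames[[k]] <- matrix(bilinear_sample(p$frame, as.vector(r0),
                                          as.vector(c0))$values, h, w)
    masks[[k]] <- u_indicator(r0, c0, g)
    orig_cols[[k]] <- c0
  }
  maxmove <- ceiling(max(abs(c(peak_left_dx, peak_right_dx, peak_dy)))) + 1L
  flows <- vector("list", nf - 1L)
  for (k in seq_len(nf - 1L)) {
    c0 <- orig_cols[[k]]
    u <- blend_dx(c0, g, peak_left_dx * amp[k + 1], peak_right_dx * amp[k + 1]) -
         blend_dx(c0, g, peak_left_dx * amp[k], peak_right_dx * amp[k])
    v <- matrix(peak_dy * (amp[k + 1] - amp[k]), h, w)
    support <- mask_dilate(masks[[k]], maxmove)
    u[!support] <- 0
    v[!support] <- 0
    flows[[k]] <- flow_field(u, v)
  }
  seq <- image_sequence(frames, mm_per_px = mm_per_px,
                        frame_interval = frame_interval)
  structure(list(seq = seq, flows = flows, masks = masks,
                 schedule = data.frame(frame = seq_len(nf), amplitude = amp)),
            class = "phantom_cycle")
}
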