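# Shared fixtures, built in code. Small sizes keep the default run fast;
# the headline-accuracy experiments live in test-acceptance.R at full size.

# Smooth random texture in [0,1]; dense gradients everywhere.
texture_image <- function(n = 64, sigma = 2, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- comflow:::gauss_blur(m, sigma)
  (m - min(m)) / diff(range(m))
}

# Integer-translate an image (replicated border), returning the pair for a
# known forward flow (dx cols, dy rows).
translate_pair <- function(img, dx, dy) {
  n <- nrow(img)
  w_inv <- flow_field(matrix(-dx, n, ncol(img)), matrix(-dy, n, ncol(img)))
  list(I1 = img, I2 = warp_image(img, w_inv)$image,
       gt = flow_field(matrix(dx, n, ncol(img)), matrix(dy, n, ncol(img))))
}

interior_mask <- function(n, margin) {
  m <- matrix(FALSE, n, n)
  m[(margin + 1):(n - margin), (margin + 1):(n - margin)] <- TRUE
  m
}

small_phantom <- function(...) {
  make_u_phantom(128, 128, wall_thickness = 10, cavity_width = 32,
                 smooth_sigma = 1, ...)
}

# Fast solver settings for small fixtures (overridable)
test_params <- function(...) {
  args <- utils::modifyList(list(inner_iters = 200L, stop_tol = 0),
                            list(...))
  do.call(solver_params, args)
}
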