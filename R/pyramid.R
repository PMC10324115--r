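# Confidence-optimized multiresolution (COM) optical flow.
#
# Coarse-to-fine warping pyramid with an exponential (geometric) scale
# schedule. At each level the accumulated flow is upsampled, the second
# frame is warped toward the first ("image correction"), the residual
# increment (du, dv) is solved, and the level's flow is formed as
#
#   u <- u + s * du,   v <- v + s * dv,
#
# where s in [0,1] is a per-pixel confidence map: the min-max-normalized
# level-1 wavelet approximation reconstruction of that level's first frame.
# Low-information regions (acoustic shadows, dropout) get small s, damping
# unreliable updates so the smoothness term fills in motion from reliable
# neighbors instead.

#' Pyramid specification for coarse-to-fine flow estimation
#'
#' Levels follow a geometric schedule of linear scale factors from
#' `top_fraction` (coarsest) up to 1 (original resolution). A top size of
#' 30% of the original image is the default operating point.
#'
#' @param n_levels number of pyramid levels (>= 1).
#' @param top_fraction linear size of the coarsest level as a fraction of
#'   the original, in (0, 1].
#' @return a list of class `pyramid_spec` with the per-level `scales`.
#' @export
pyramid_spec <- function(n_levels = 4L, top_fraction = 0.3) {
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 1, top_fraction > 0, top_fraction <= 1)
  scales <- if (n_levels == 1L) 1 else
    top_fraction^(1 - (seq_len(n_levels) - 1) / (n_levels - 1))
  structure(list(n_levels = n_levels, top_fraction = top_fraction,
                 scales = scales), class = "pyramid_spec")
}

#' Build an image pyramid (coarsest to finest)
#'
#' Each level is the original image anti-alias filtered (Gaussian, standard
#' deviation matched to the downsampling factor) and resampled bilinearly
#' to `round(dim * scale)`. The finest level is the original image
#' unchanged.
#'
#' @param img numeric matrix.
#' @param spec a [pyramid_spec].
#' @return list of matrices, coarsest first.
#' @export
build_pyramid <- function(img, spec = pyramid_spec()) {
  dims <- vapply(spec$scales,
                 function(s) as.integer(pmax(round(dim(img) * s), 1)),
                 integer(2))
  if (any(dims[, 1] < 16))
    stop("build_pyramid: coarsest level below 16 px per side; ",
         "raise top_fraction or use a larger image")
  lapply(seq_along(spec$scales), function(k) {
    s <- spec$scales[k]
    if (s >= 1) return(img)
    smoothed <- gauss_blur(img, sigma = 0.6 * sqrt(1 / s^2 - 1))
    resample_bilinear(smoothed, dims[, k])
  })
}

#' Wavelet-approximation confidence map
#'
#' Computes the level-1 two-dimensional wavelet decomposition of the image,
#' zeroes the detail bands, reconstructs to the image size (the "first
#' layer reconstruction approximation"), then min-max normalizes to [0, 1].
#' The result weights the incremental flow update in [com_flow]: near-zero
#' where the image carries little signal, near one where it is bright and
#' structured. A constant image (zero range) returns all ones.
#'
#' @param img numeric matrix, at least 16 x 16.
#' @param wavelet `"haar"` (alias `"db1"`) or `"db2"`.
#' @return numeric matrix of weights in [0, 1], the shape of `img`.
#' @export
confidence_map <- function(img, wavelet = "haar") {
  if (nrow(img) < 16 || ncol(img) < 16)
    stop("confidence_map: image smaller than 16 x 16")
  approx <- dwt2_approx(img, wavelet)
  rng <- range(approx)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(matrix(1, nrow(img), ncol(img)))
  (approx - rng[1]) / diff(rng)
}

# Orthonormal scaling (lowpass) filters
wavelet_filter <- function(wavelet) {
  switch(tolower(wavelet),
    haar = ,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    stop("confidence_map: unsupported wavelet '", wavelet, "'")
  )
}

# Level-1 separable DWT approximation band, reconstructed to the original
# size with detail bands zeroed. Periodic extension; odd lengths are padded
# by edge replication to even before the transform and cropped after.
dwt2_approx <- function(img, wavelet = "haar") {
  h <- wavelet_filter(wavelet)
  nr <- nrow(img); nc <- ncol(img)
  pr <- nr %% 2L; pc <- nc %% 2L
  if (pr) img <- rbind(img, img[nr, ])
  if (pc) img <- cbind(img, img[, nc])
  a <- apply(img, 2, dwt1_approx_recon, h = h)
  a <- t(apply(a, 1, dwt1_approx_recon, h = h))
  a[seq_len(nr), seq_len(nc), drop = FALSE]
}

# 1-D analysis (lowpass + downsample) then synthesis with zeroed details,
# periodic boundary handling. Returns a vector of the input length (even).
dwt1_approx_recon <- function(x, h) {
  n <- length(x)
  L <- length(h)
  # analysis: a_k = sum_j h_j x_{2k - 1 + j - 1 mod n}, k = 1..n/2
  idx <- outer(2 * seq_len(n %/% 2) - 1, seq_len(L) - 1, `+`)
  idx <- (idx - 1) %% n + 1
  a <- as.vector(matrix(x[idx], ncol = L) %*% h)
  # synthesis: upsample a by 2 and convolve with the time-reversed filter
  up <- numeric(n)
  up[seq(1, n, by = 2)] <- a
  y <- numeric(n)
  for (j in seq_len(L)) {
    shift <- j - 1
    y <- y + h[j] * up[((seq_len(n) - 1 - shift) %% n) + 1]
  }
  y
}

#' Confidence-optimized multiresolution optical flow
#'
#' Coarse-to-fine warping flow with per-level confidence reweighting of the
#' incremental update. Starting from zero flow at the coarsest level, each
#' level upsamples the accumulated flow (displacements scaled by the exact
#' inter-level size ratio per axis), warps the second frame toward the
#' first, solves for the residual increment, and accumulates
#' `u <- u + s * du`, `v <- v + s * dv`, down to the original resolution.
#'
#' The confidence map `s` is recomputed at every level from that level's
#' first-frame image: the normalized level-1 wavelet approximation
#' (`confidence_source = "wavelet"`, the default), the min-max-normalized
#' gray values themselves (`"gray"`, a comparison variant), or identically
#' one when `use_confidence = FALSE` (the plain pyramid warping flow).
#'
#' @param I1,I2 numeric matrices of equal shape (frame pair, frame 1 first).
#' @param spec a [pyramid_spec].
#' @param params a [solver_params].
#' @param use_confidence logical; `FALSE` sets s = 1 at every level.
#' @param confidence_source `"wavelet"` or `"gray"`.
#' @param wavelet wavelet name passed to [confidence_map].
#' @return a [flow_field] at the original resolution.
#' @examples
#' I <- matrix(runif(64 * 64), 64, 64)
#' w <- com_flow(I, I, spec = pyramid_spec(2, 0.5))
#' max(abs(w$u))  # ~0 for identical frames
#' @export
com_flow <- function(I1, I2, spec = pyramid_spec(), params = solver_params(),
                     use_confidence = TRUE,
                     confidence_source = c("wavelet", "gray"),
                     wavelet = "haar") {
  if (!all(dim(I1) == dim(I2))) stop("com_flow: frame shapes differ")
  confidence_source <- match.arg(confidence_source)
  pyr1 <- build_pyramid(I1, spec)
  pyr2 <- build_pyramid(I2, spec)
  u <- v <- matrix(0, nrow(pyr1[[1]]), ncol(pyr1[[1]]))
  for (k in seq_len(spec$n_levels)) {
    L1 <- pyr1[[k]]; L2 <- pyr2[[k]]
    if (k > 1L) {
      ratio_c <- ncol(L1) / ncol(u)
      ratio_r <- nrow(L1) / nrow(u)
      u <- resample_bilinear(u, dim(L1)) * ratio_c
      v <- resample_bilinear(v, dim(L1)) * ratio_r
    }
    s <- if (!use_confidence) NULL
         else if (confidence_source == "wavelet") confidence_map(L1, wavelet)
         else minmax_norm(L1)
    # tensor integration window scales with the level so it covers a fixed
    # image-plane extent
    params_k <- params
    params_k$rho <- params$rho * spec$scales[k]
    w <- warp_solve(L1, L2, flow_field(u, v), params_k, s = s)
    u <- w$u; v <- w$v
  }
  flow_field(u, v)
}

minmax_norm <- function(img) {
  rng <- range(img)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(matrix(1, nrow(img), ncol(img)))
  (img - rng[1]) / diff(rng)
}
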