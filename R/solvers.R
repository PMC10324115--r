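# Variational flow solvers.
#
# The per-level increment minimizes the linearized brightness-constancy
# energy with a quadratic first-order smoothness penalty. The data term is
# local-global (CLG): the outer products of the linearized constraint are
# integrated over a Gaussian window of scale rho before entering the
# energy,
#
#   E(du, dv) = sum_p (du dv 1) J_rho(p) (du dv 1)^T
#             + alpha * sum_{(p,q) 4-neighbors} (du_p - du_q)^2 + (dv_p - dv_q)^2,
#
# with J_rho = G_rho * [Ix; Iy; It][Ix; Iy; It]^T. rho = 0 is classic
# pointwise Horn-Schunck; rho > 0 carries edge evidence into adjacent
# textureless regions (myocardial wall interiors are nearly uniform in the
# phantom and in low-gain echo), which stabilizes the aperture problem
# there. The normal equations are a symmetric positive-definite system
# solved by Jacobi-preconditioned conjugate gradients: CG minimizes the
# quadratic over growing Krylov subspaces, so E is non-increasing iteration
# by iteration, and it propagates motion evidence across large featureless
# regions in tractably few iterations.

# 4-neighbor sum with zero padding outside the raster
neighbor_sum <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  S <- matrix(0, nr, nc)
  S[-nr, ] <- S[-nr, ] + M[-1, ]
  S[-1, ] <- S[-1, ] + M[-nr, ]
  S[, -nc] <- S[, -nc] + M[, -1]
  S[, -1] <- S[, -1] + M[, -nc]
  S
}

neighbor_count <- function(nr, nc) {
  n <- matrix(4, nr, nc)
  n[1, ] <- n[1, ] - 1; n[nr, ] <- n[nr, ] - 1
  n[, 1] <- n[, 1] - 1; n[, nc] <- n[, nc] - 1
  n
}

# Gaussian-integrated structure tensor of the linearized constraint; an
# optional per-pixel weight (the confidence map) scales each pixel's
# evidence before integration so unreliable pixels do not export
# constraints into their neighborhood.
motion_tensor <- function(Ix, Iy, It, rho, weight = NULL) {
  w <- if (is.null(weight)) 1 else weight
  sm <- function(M) gauss_blur(M, rho)
  if (rho <= 0) sm <- identity
  list(xx = sm(w * Ix^2), xy = sm(w * Ix * Iy), yy = sm(w * Iy^2),
       xt = sm(w * Ix * It), yt = sm(w * Iy * It), tt = sm(w * It^2))
}

# Energy of the linearized model; used by the monotonicity property test.
flow_energy <- function(Ix, Iy, It, du, dv, alpha, rho = 0, weight = NULL) {
  J <- motion_tensor(Ix, Iy, It, rho, weight)
  data <- sum(J$xx * du^2 + J$yy * dv^2 + 2 * J$xy * du * dv +
                2 * J$xt * du + 2 * J$yt * dv + J$tt)
  dx_u <- du[, -1, drop = FALSE] - du[, -ncol(du), drop = FALSE]
  dy_u <- du[-1, , drop = FALSE] - du[-nrow(du), , drop = FALSE]
  dx_v <- dv[, -1, drop = FALSE] - dv[, -ncol(dv), drop = FALSE]
  dy_v <- dv[-1, , drop = FALSE] - dv[-nrow(dv), , drop = FALSE]
  data + alpha * (sum(dx_u^2) + sum(dy_u^2) + sum(dx_v^2) + sum(dy_v^2))
}

#' Single-level flow increment from a linearized frame pair
#'
#' Solves for the small flow increment (du, dv) between `I1` and `I2`,
#' assuming `I2` has already been warped by any accumulated flow so the
#' residual motion is small (about a pixel or less). The linearized
#' brightness-constancy energy (local-global motion tensor at scale
#' `params$rho`, optionally evidence-weighted) with quadratic smoothness is
#' minimized by Jacobi-preconditioned conjugate gradients; iteration stops
#' after `params$inner_iters` iterations or when the mean absolute update
#' falls below `params$stop_tol`.
#'
#' @param weight optional per-pixel evidence weight in [0, 1] (a
#'   confidence map), applied to the motion tensor before integration.
#'
#' Intensities are rescaled internally to the conventional 8-bit range
#' (multiplied by 255) before differentiation, so the default smoothness
#' weight `alpha` carries its classic Horn-Schunck meaning for images in
#' [0, 1].
#'
#' @param I1,I2 numeric matrices of equal shape, finite.
#' @param params a [solver_params] list.
#' @return a [flow_field] holding the increment (u = du, v = dv).
#' @export
solve_level <- function(I1, I2, params = solver_params(), weight = NULL) {
  if (!all(dim(I1) == dim(I2))) stop("solve_level: shapes differ")
  if (!all(is.finite(I1)) || !all(is.finite(I2)))
    stop("solve_level: non-finite input")
  g <- gradients(I1 * 255, I2 * 255)
  relax_flow(g$Ix, g$Iy, g$It, params, weight)
}

relax_flow <- function(Ix, Iy, It, params, weight = NULL) {
  nr <- nrow(Ix); nc <- ncol(Ix)
  alpha <- params$alpha
  J <- motion_tensor(Ix, Iy, It, params$rho, weight)
  n <- neighbor_count(nr, nc)
  Dxx <- J$xx + alpha * n       # diagonal blocks (Jacobi preconditioner)
  Dyy <- J$yy + alpha * n
  amul <- function(pu, pv) list(
    u = J$xx * pu + J$xy * pv + alpha * (n * pu - neighbor_sum(pu)),
    v = J$xy * pu + J$yy * pv + alpha * (n * pv - neighbor_sum(pv)))
  bu <- -J$xt
  bv <- -J$yt
  du <- matrix(0, nr, nc); dv <- matrix(0, nr, nc)
  ru <- bu; rv <- bv
  zu <- ru / Dxx; zv <- rv / Dyy
  pu <- zu; pv <- zv
  rz <- sum(ru * zu) + sum(rv * zv)
  if (rz == 0) return(flow_field(du, dv))
  for (it in seq_len(params$inner_iters)) {
    Ap <- amul(pu, pv)
    pAp <- sum(pu * Ap$u) + sum(pv * Ap$v)
    if (pAp <= 0) break
    step <- rz / pAp
    du <- du + step * pu
    dv <- dv + step * pv
    ru <- ru - step * Ap$u
    rv <- rv - step * Ap$v
    if (mean(abs(step * pu)) + mean(abs(step * pv)) < params$stop_tol) break
    zu <- ru / Dxx; zv <- rv / Dyy
    rz_new <- sum(ru * zu) + sum(rv * zv)
    beta <- rz_new / rz
    rz <- rz_new
    pu <- zu + beta * pu
    pv <- zv + beta * pv
  }
  flow_field(du, dv)
}

# Level solver: repeatedly warp I2 by the accumulated flow, solve for the
# re-linearized increment, and accumulate u <- u + s*du, v <- v + s*dv.
# The confidence map s damps updates where the image carries little
# information, and additionally weights each pixel's evidence in the data
# term (see motion_tensor) so unreliable regions are filled by the
# smoothness prior rather than by their own corrupted constraints. With
# s = 1 (or s = NULL) this IS the plain pyramid warping flow.
warp_solve <- function(I1, I2, init, params, s = NULL) {
  u <- init$u; v <- init$v
  for (k in seq_len(params$outer_iters)) {
    I2w <- warp_image(I2, flow_field(u, v))$image
    inc <- solve_level(I1, I2w, params, weight = s)
    if (is.null(s)) {
      u <- u + inc$u
      v <- v + inc$v
    } else {
      u <- u + s * inc$u
      v <- v + s * inc$v
    }
  }
  flow_field(u, v)
}

#' Horn-Schunck optical flow (single level)
#'
#' Classic Horn-Schunck estimation at full resolution: one linearization of
#' the brightness-constancy constraint (pointwise data term, `rho = 0`),
#' relaxed globally with a quadratic smoothness term. No pyramid and no
#' warping, so displacements well beyond one pixel are underestimated; kept
#' as a comparison baseline with its conventional untuned parameters.
#'
#' @param I1,I2 numeric matrices of equal shape.
#' @param params a [solver_params]; only `alpha`, `rho`, `inner_iters` and
#'   `stop_tol` are used.
#' @return a [flow_field].
#' @export
hs_flow <- function(I1, I2,
                    params = solver_params(alpha = 15, rho = 0,
                                           inner_iters = 500L,
                                           stop_tol = 1e-4)) {
  solve_level(I1, I2, params)
}

#' Lucas-Kanade optical flow (single level)
#'
#' Local least-squares flow over a square window per pixel. Pixels whose
#' structure tensor is ill-conditioned (smaller eigenvalue below `tau`)
#' receive zero flow and are flagged.
#'
#' @param I1,I2 numeric matrices of equal shape.
#' @param window odd window side length in pixels (>= 3).
#' @param tau threshold on the smaller structure-tensor eigenvalue below
#'   which a pixel is declared ill-conditioned.
#' @return a [flow_field] with attribute `ill_conditioned` (logical matrix).
#' @export
lk_flow <- function(I1, I2, window = 15L, tau = 1e-4) {
  if (!all(dim(I1) == dim(I2))) stop("lk_flow: shapes differ")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("lk_flow: window must be odd and >= 3")
  g <- gradients(I1, I2)
  r <- (window - 1L) %/% 2L
  Sxx <- box_sum(g$Ix * g$Ix, r)
  Sxy <- box_sum(g$Ix * g$Iy, r)
  Syy <- box_sum(g$Iy * g$Iy, r)
  Sxt <- box_sum(g$Ix * g$It, r)
  Syt <- box_sum(g$Iy * g$It, r)
  tr <- Sxx + Syy
  det <- Sxx * Syy - Sxy^2
  lam_min <- tr / 2 - sqrt(pmax(tr^2 / 4 - det, 0))
  bad <- lam_min < tau | det <= 0
  det[bad] <- 1
  u <- -(Syy * Sxt - Sxy * Syt) / det
  v <- -(Sxx * Syt - Sxy * Sxt) / det
  u[bad] <- 0; v[bad] <- 0
  out <- flow_field(u, v)
  attr(out, "ill_conditioned") <- bad
  out
}

# Box-filter sum over a (2r+1)^2 window, replicated borders, via cumsums.
box_sum <- function(M, r) {
  nr <- nrow(M); nc <- ncol(M)
  ridx <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  cidx <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  P <- M[ridx, cidx, drop = FALSE]
  cs <- apply(P, 2, cumsum)
  rows <- cs[(2L * r + 1L):nrow(P), , drop = FALSE]
  rows[-1, ] <- rows[-1, , drop = FALSE] -
    cs[seq_len(nrow(P) - 2L * r - 1L), , drop = FALSE]
  cs2 <- t(apply(rows, 1, cumsum))
  out <- cs2[, (2L * r + 1L):ncol(P), drop = FALSE]
  out[, -1] <- out[, -1, drop = FALSE] -
    cs2[, seq_len(ncol(P) - 2L * r - 1L), drop = FALSE]
  out
}
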