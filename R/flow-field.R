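#' Dense optical-flow field
#'
#' Container for a dense per-pixel displacement field between two frames.
#' `u` is the horizontal (column) displacement and `v` the vertical (row)
#' displacement, both in pixels, as matrices of the image shape. The field
#' is a forward map from frame 1 to frame 2 and is applied by backward
#' sampling (see [warp_image]).
#'
#' @param u,v numeric matrices of equal shape; finite.
#' @return an object of class `flow_field`: a list with elements `u`, `v`.
#' @examples
#' w <- flow_field(matrix(1, 4, 4), matrix(0, 4, 4))
#' print(w)
#' @export
flow_field <- function(u, v) {
  stopifnot(is.matrix(u), is.matrix(v))
  if (!all(dim(u) == dim(v))) stop("flow_field: u and v shapes differ")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("flow_field: non-finite displacement values")
  structure(list(u = u, v = v), class = "flow_field")
}

as_flow_field <- function(x) {
  if (inherits(x, "flow_field")) return(x)
  if (is.list(x) && !is.null(x$u) && !is.null(x$v)) return(flow_field(x$u, x$v))
  stop("cannot coerce to flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("flow_field: %d x %d px\n", nrow(x$u), ncol(x$u)))
  cat(sprintf("  |w|: mean %.4f, max %.4f px\n", mean(mag), max(mag)))
  cat(sprintf("  u in [%.3f, %.3f], v in [%.3f, %.3f]\n",
              min(x$u), max(x$u), min(x$v), max(x$v)))
  invisible(x)
}

#' @export
dim.flow_field <- function(x) dim(x$u)

#' Quiver plot of a flow field
#'
#' Draws the displacement field as arrows on a subsampled grid, in image
#' orientation (row 1 at the top).
#'
#' @param x a [flow_field].
#' @param step grid spacing in pixels between plotted arrows.
#' @param scale arrow length multiplier.
#' @param ... passed to [graphics::arrows].
#' @export
plot.flow_field <- function(x, step = 8L, scale = 1, ...) {
  nr <- nrow(x$u); nc <- ncol(x$u)
  rs <- seq(1L, nr, by = step); cs <- seq(1L, nc, by = step)
  g <- expand.grid(r = rs, c = cs)
  u <- x$u[cbind(g$r, g$c)] * scale
  v <- x$v[cbind(g$r, g$c)] * scale
  graphics::plot(NA, xlim = c(1, nc), ylim = c(nr, 1), asp = 1,
                 xlab = "column", ylab = "row", main = "flow field")
  keep <- sqrt(u^2 + v^2) > 1e-6
  if (any(keep))
    graphics::arrows(g$c[keep], g$r[keep], g$c[keep] + u[keep],
                     g$r[keep] + v[keep], length = 0.04, ...)
  invisible(x)
}

#' Solver parameters for the variational flow estimators
#'
#' Defaults for `alpha` and `rho` were fixed once by the root-mean-square
#' error experiment on the affine-motion phantom (see the methods
#' vignette), mirroring how relaxation parameters are conventionally tuned
#' for this estimator family; `rho = 0` recovers the classic pointwise
#' Horn-Schunck data term.
#'
#' @param alpha smoothness weight (dimensionless, > 0). Larger values give
#'   smoother fields. Scaled for image intensities in the 8-bit range,
#'   which the solvers apply internally.
#' @param rho local-global integration scale of the motion tensor, in
#'   pixels (>= 0): the linearized-constraint outer products are averaged
#'   over a Gaussian window of this standard deviation, spreading edge
#'   evidence into adjacent textureless regions.
#' @param outer_iters warping (re-linearization) iterations per pyramid
#'   level.
#' @param inner_iters conjugate-gradient iterations of the linear solver
#'   per warp.
#' @param stop_tol early-stop threshold on the mean absolute flow update
#'   per iteration, in pixels.
#' @return a list of class `solver_params`.
#' @export
solver_params <- function(alpha = 3000, rho = 12, outer_iters = 3L,
                          inner_iters = 400L, stop_tol = 1e-4) {
  stopifnot(alpha > 0, rho >= 0, outer_iters >= 1, inner_iters >= 1,
            stop_tol >= 0)
  structure(list(alpha = alpha, rho = rho,
                 outer_iters = as.integer(outer_iters),
                 inner_iters = as.integer(inner_iters), stop_tol = stop_tol),
            class = "solver_params")
}
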