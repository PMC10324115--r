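# Flow accuracy metrics and the method-comparison harness.
#
# RMSE is the root-mean-square endpoint error over the evaluation ROI:
#   sqrt( mean_i [ (u_g - u_e)^2 + (v_g - v_e)^2 ] ).
# AE is the mean space-time angular error (Barron convention): the angle
# between the homogeneous vectors (u, v, 1), which stays defined for zero
# flow and weights angular deviations of small vectors less.

#' Root-mean-square endpoint error between two flow fields
#'
#' @param est,gt estimated and ground-truth [flow_field]s of equal shape.
#' @param roi logical matrix; pixels over which the error is evaluated.
#' @return RMSE in pixels.
#' @export
flow_rmse <- function(est, gt, roi) {
  est <- as_flow_field(est); gt <- as_flow_field(gt)
  if (!all(dim(est$u) == dim(gt$u)) || !all(dim(roi) == dim(est$u)))
    stop("flow_rmse: shapes differ")
  if (!any(roi)) stop("flow_rmse: empty roi")
  sqrt(mean((gt$u[roi] - est$u[roi])^2 + (gt$v[roi] - est$v[roi])^2))
}

#' Mean angular error between two flow fields (degrees)
#'
#' Space-time angular error: mean over the ROI of
#' `arccos((u_g u_e + v_g v_e + 1) / sqrt((u_g^2+v_g^2+1)(u_e^2+v_e^2+1)))`.
#'
#' @inheritParams flow_rmse
#' @return mean angular error in degrees.
#' @export
angular_error <- function(est, gt, roi) {
  est <- as_flow_field(est); gt <- as_flow_field(gt)
  if (!all(dim(est$u) == dim(gt$u)) || !all(dim(roi) == dim(est$u)))
    stop("angular_error: shapes differ")
  if (!any(roi)) stop("angular_error: empty roi")
  ue <- est$u[roi]; ve <- est$v[roi]
  ug <- gt$u[roi]; vg <- gt$v[roi]
  cosang <- (ug * ue + vg * ve + 1) /
    sqrt((ug^2 + vg^2 + 1) * (ue^2 + ve^2 + 1))
  mean(acos(pmin(pmax(cosang, -1), 1))) * 180 / pi
}

#' Run several flow methods on a ground-truth pair and report errors
#'
#' Estimates the flow of `pair` with each requested method and evaluates
#' both metrics over the pair's evaluation ROI. Methods: `"hs"`
#' (single-level Horn-Schunck), `"lk"` (single-level Lucas-Kanade),
#' `"pyramid"` (warping pyramid, confidence off), `"com-gray"` (pyramid
#' with gray-value confidence), `"com-wavelet"` (pyramid with
#' wavelet-approximation confidence).
#'
#' @param pair a `gt_pair` (see [affine_contract]), or any list with
#'   `frame1`, `frame2`, `gt_flow`, `roi`.
#' @param methods character vector of method labels.
#' @param spec a [pyramid_spec] for the pyramid-based methods.
#' @param params a [solver_params].
#' @param lk_window Lucas-Kanade window size.
#' @return data.frame with columns `method`, `rmse_px`, `ae_deg`,
#'   `n_pixels`, sorted by RMSE; the flows are attached as attribute
#'   `flows`.
#' @export
run_comparison <- function(pair,
                           methods = c("hs", "lk", "pyramid", "com-gray",
                                       "com-wavelet"),
                           spec = pyramid_spec(), params = solver_params(),
                           lk_window = 15L) {
  known <- c("hs", "lk", "pyramid", "com-gray", "com-wavelet")
  if (!all(methods %in% known))
    stop("run_comparison: unknown method label(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  I1 <- pair$frame1; I2 <- pair$frame2
  flows <- lapply(methods, function(m) {
    switch(m,
      "hs" = hs_flow(I1, I2),
      "lk" = lk_flow(I1, I2, window = lk_window),
      "pyramid" = com_flow(I1, I2, spec, params, use_confidence = FALSE),
      "com-gray" = com_flow(I1, I2, spec, params,
                            confidence_source = "gray"),
      "com-wavelet" = com_flow(I1, I2, spec, params,
                               confidence_source = "wavelet"))
  })
  names(flows) <- methods
  out <- data.frame(
    method = methods,
    rmse_px = vapply(flows, flow_rmse, numeric(1), gt = pair$gt_flow,
                     roi = pair$roi),
    ae_deg = vapply(flows, angular_error, numeric(1), gt = pair$gt_flow,
                    roi = pair$roi),
    n_pixels = sum(pair$roi),
    row.names = NULL)
  out <- out[order(out$rmse_px), ]
  rownames(out) <- NULL
  attr(out, "flows") <- flows
  out
}
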