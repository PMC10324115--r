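# Shared raster conventions
#
# Images are numeric matrices I[row, col], pixel centers at integer (row, col)
# coordinates starting at 1 (top-left origin, row increases downward).
# A flow field stores u = displacement along columns (+right) and
# v = displacement along rows (+down), both in pixels, as matrices of the
# image shape. Flows are forward maps frame1 -> frame2 and are applied by
# backward sampling (warping frame2 toward frame1).

#' Bilinear sampling of a raster at continuous coordinates
#'
#' Samples image values at arbitrary (row, col) positions with bilinear
#' interpolation. Positions outside the raster are clamped to the border
#' (replicated edge values) and flagged in the out-of-bounds indicator.
#'
#' @param img numeric matrix.
#' @param row,col numeric vectors of equal length; continuous 1-based
#'   coordinates of the sampling positions.
#' @return list with `values` (numeric vector) and `oob` (logical vector,
#'   `TRUE` where the requested position fell outside the raster).
#' @keywords internal
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  oob <- row < 1 | row > nr | col < 1 | col > nc
  r <- pmin(pmax(row, 1), nr)
  c <- pmin(pmax(col, 1), nc)
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(r0, nr - 1L); c0 <- pmin(c0, nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + nr]; v11 <- img[i00 + nr + 1]
  vals <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  list(values = vals, oob = oob)
}

#' Backward-warp an image along a flow field
#'
#' Resamples `img` at positions displaced by the flow: the output at pixel
#' x is `img(x + w(x))`, by bilinear interpolation. Warping the second
#' frame of a pair by the forward flow produces an image aligned with the
#' first frame ("image correction"). Samples falling outside the raster
#' replicate the border and are flagged in the validity mask.
#'
#' @param img numeric matrix.
#' @param flow a [flow_field] of the same shape as `img`.
#' @return list with `image` (warped matrix) and `oob` (logical matrix,
#'   `TRUE` where the sample position left the raster).
#' @examples
#' I <- matrix(runif(64), 8, 8)
#' w0 <- flow_field(matrix(0, 8, 8), matrix(0, 8, 8))
#' all.equal(warp_image(I, w0)$image, I)
#' @export
warp_image <- function(img, flow) {
  stopifnot(is.matrix(img))
  flow <- as_flow_field(flow)
  if (!all(dim(img) == dim(flow$u)))
    stop("warp_image: image and flow shapes differ")
  nr <- nrow(img); nc <- ncol(img)
  rr <- rep.int(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  s <- bilinear_sample(img, rr + as.vector(flow$v), cc + as.vector(flow$u))
  list(image = matrix(s$values, nr, nc), oob = matrix(s$oob, nr, nc))
}

#' Spatial and temporal image derivatives of a frame pair
#'
#' Central-difference spatial derivatives averaged over the two frames,
#' with replicated borders; the temporal derivative is the plain frame
#' difference.
#'
#' @param I1,I2 numeric matrices of equal shape.
#' @return list with matrices `Ix` (d/dcol), `Iy` (d/drow) and `It`.
#' @export
gradients <- function(I1, I2) {
  if (!all(dim(I1) == dim(I2))) stop("gradients: shapes differ")
  Iavg <- (I1 + I2) / 2
  list(Ix = ddx(Iavg), Iy = ddy(Iavg), It = I2 - I1)
}

# d/dcol, central differences, replicated border
ddx <- function(I) {
  nc <- ncol(I)
  right <- I[, c(2:nc, nc), drop = FALSE]
  left <- I[, c(1, 1:(nc - 1)), drop = FALSE]
  (right - left) / 2
}

# d/drow, central differences, replicated border
ddy <- function(I) {
  nr <- nrow(I)
  down <- I[c(2:nr, nr), , drop = FALSE]
  up <- I[c(1, 1:(nr - 1)), , drop = FALSE]
  (down - up) / 2
}

#' Resample a raster to a new size by bilinear interpolation
#'
#' Pixel-center aligned: output pixel i maps to input coordinate
#' (i - 0.5) * n_in / n_out + 0.5, so resampling to the same size is the
#' identity. Used both for pyramid construction (after anti-alias
#' filtering) and for upsampling flow between pyramid levels.
#'
#' @param img numeric matrix.
#' @param dim_out integer vector (rows, cols).
#' @return numeric matrix of shape `dim_out`.
#' @keywords internal
resample_bilinear <- function(img, dim_out) {
  nr_out <- dim_out[1]; nc_out <- dim_out[2]
  r_in <- (seq_len(nr_out) - 0.5) * nrow(img) / nr_out + 0.5
  c_in <- (seq_len(nc_out) - 0.5) * ncol(img) / nc_out + 0.5
  rr <- rep.int(r_in, nc_out)
  cc <- rep(c_in, each = nr_out)
  matrix(bilinear_sample(img, rr, cc)$values, nr_out, nc_out)
}

# Gaussian smoothing (EBImage, replicated borders); sigma = 0 is identity.
# sigma is capped so the kernel fits inside the raster (matters at coarse
# pyramid levels when the tensor integration scale is large).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  sigma <- min(sigma, (min(dim(img)) - 2) / 6)
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}

# Binary morphology on 0/1 masks; radius in pixels (box structuring element).
mask_erode <- function(mask, radius = 1L) {
  if (radius < 1) return(mask)
  m <- EBImage::erode(mask + 0, EBImage::makeBrush(2L * radius + 1L, "box"))
  as.matrix(m) > 0.5
}

mask_dilate <- function(mask, radius = 1L) {
  if (radius < 1) return(mask)
  m <- EBImage::dilate(mask + 0, EBImage::makeBrush(2L * radius + 1L, "box"))
  as.matrix(m) > 0.5
}
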