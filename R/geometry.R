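# Wall contour handling and segment geometry.
#
# A contour traces the endocardium (inner border) from one base endpoint,
# through the apex, to the other base endpoint, with the epicardium traced
# in the same order. "Clockwise" is defined in image coordinates (row
# increases downward): base-left -> apex -> base-right. Each side of the
# apex is split into three equal-arc-length spans, giving the six segments
# the apical two-chamber view contributes to the 16-segment model; a
# secondary halving yields twelve.

#' Wall contour with apex and base landmarks
#'
#' @param endo_points,epi_points n x 2 matrices of (row, col) coordinates
#'   (1-based, continuous) tracing each border from base-left through the
#'   apex to base-right.
#' @param apex_index index of the apex vertex in `endo_points`, strictly
#'   between the first and last vertex.
#' @return an object of class `wall_contour`.
#' @export
wall_contour <- function(endo_points, epi_points, apex_index) {
  endo_points <- as.matrix(endo_points)
  epi_points <- as.matrix(epi_points)
  stopifnot(ncol(endo_points) == 2, ncol(epi_points) == 2)
  n <- nrow(endo_points)
  apex_index <- as.integer(apex_index)
  if (n < 7) stop("wall_contour: too few endocardial points")
  if (apex_index <= 1 || apex_index >= n)
    stop("wall_contour: apex must lie strictly between the base endpoints")
  steps <- diff(endo_points)
  if (any(rowSums(steps^2) == 0))
    stop("wall_contour: repeated consecutive endocardial points")
  structure(list(endo_points = endo_points, epi_points = epi_points,
                 apex_index = apex_index,
                 base_left_index = 1L, base_right_index = n),
            class = "wall_contour")
}

#' @export
print.wall_contour <- function(x, ...) {
  cat(sprintf("wall_contour: %d endo / %d epi points, apex at endo index %d\n",
              nrow(x$endo_points), nrow(x$epi_points), x$apex_index))
  invisible(x)
}

#' Analytic contour of a U-phantom
#'
#' Derives the endocardial and epicardial polylines (about one pixel vertex
#' spacing) and the apex landmark directly from the phantom's analytic
#' geometry.
#'
#' @param p a [make_u_phantom] phantom.
#' @return a [wall_contour].
#' @export
phantom_contour <- function(p) {
  g <- p$geometry
  border <- function(radius) {
    left <- cbind(seq(g$top, g$r0, by = 1), g$cx - radius)
    n_arc <- max(8L, ceiling(pi * radius))
    th <- seq(0, pi, length.out = n_arc + 1L)[-c(1, n_arc + 1L)]
    arc <- cbind(g$r0 + radius * sin(th), g$cx - radius * cos(th))
    right <- cbind(seq(g$r0, g$top, by = -1), g$cx + radius)
    rbind(left, arc, right)
  }
  endo <- border(g$a)
  epi <- border(g$b)
  apex_index <- which.max(endo[, 1])
  wall_contour(endo, epi, apex_index)
}

arc_lengths <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(d))
}

# Vertex index closest to a target cumulative arc length
vertex_at_arc <- function(cumlen, target) which.min(abs(cumlen - target))

#' Split a wall contour into six segments
#'
#' Divides each side of the apex (base-left to apex, apex to base-right)
#' into three spans of equal arc length along the endocardium, giving six
#' segments ordered clockwise (label 1 at base-left). Wall-mask pixels are
#' assigned to the segment of their nearest endocardial vertex, so the
#' segment masks partition the wall exactly.
#'
#' @param contour a [wall_contour].
#' @param wall_mask logical matrix marking myocardial pixels, or `NULL` to
#'   rasterize it from the contour polygon.
#' @param dim image dimensions (rows, cols), required when `wall_mask` is
#'   `NULL`.
#' @return list of 6 `wall_segment` objects, each with `label`, `span`
#'   (endocardial index range), `center`, `tangent`, `normal`, `roi_mask`.
#' @export
split_six <- function(contour, wall_mask = NULL, dim = NULL) {
  stopifnot(inherits(contour, "wall_contour"))
  endo <- contour$endo_points
  ai <- contour$apex_index
  n <- nrow(endo)
  cum <- arc_lengths(endo)
  if (cum[ai] < 1e-9 || cum[n] - cum[ai] < 1e-9)
    stop("invalid contour: apex coincides with a base endpoint")
  if (is.null(wall_mask)) {
    if (is.null(dim)) stop("split_six: need wall_mask or dim")
    wall_mask <- contour_mask(contour, dim)
  }
  side1 <- cum[ai] * (1:2) / 3
  side2 <- cum[ai] + (cum[n] - cum[ai]) * (1:2) / 3
  bounds <- c(1L, vertex_at_arc(cum, side1[1]), vertex_at_arc(cum, side1[2]),
              ai, vertex_at_arc(cum, side2[1]), vertex_at_arc(cum, side2[2]), n)
  if (any(diff(bounds) < 1L))
    stop("invalid contour: segment boundaries collapsed")
  spans <- lapply(1:6, function(i) c(bounds[i], bounds[i + 1]))
  rois <- partition_mask(wall_mask, contour$endo_points, spans)
  build_segments(spans, as.character(1:6), contour, rois)
}

# Assign each TRUE pixel of `mask` to the span of its nearest vertex among
# endo[vrange], returning one disjoint logical mask per span.
partition_mask <- function(mask, endo, spans, vrange = NULL) {
  if (is.null(vrange)) vrange <- spans[[1]][1]:spans[[length(spans)]][2]
  vseg <- integer(max(vrange))
  for (i in seq_along(spans)) {
    idx <- spans[[i]][1]:spans[[i]][2]
    vseg[idx][vseg[idx] == 0L] <- i
  }
  pix <- which(mask, arr.ind = TRUE)
  nearest <- nearest_vertex(pix, endo[vrange, , drop = FALSE])
  pseg <- vseg[vrange[nearest]]
  lapply(seq_along(spans), function(i) {
    roi <- matrix(FALSE, nrow(mask), ncol(mask))
    roi[pix[pseg == i, , drop = FALSE]] <- TRUE
    roi
  })
}

#' Halve each segment by arc length (secondary segmentation)
#'
#' Splits each of the six segments into an upper and a lower half of equal
#' endocardial arc length, yielding twelve segments labeled
#' `"<parent>-upper"` / `"<parent>-lower"` (upper = nearer the base, lower
#' = nearer the apex, for both sides). Child masks partition the parent
#' mask.
#'
#' @param segments list of 6 segments from [split_six].
#' @param contour the [wall_contour] the segments were built from.
#' @return list of 12 `wall_segment` objects.
#' @export
subdivide <- function(segments, contour) {
  stopifnot(length(segments) == 6)
  endo <- contour$endo_points
  cum <- arc_lengths(endo)
  ai <- contour$apex_index
  spans <- list(); labels <- character(0); rois <- list()
  for (seg in segments) {
    i0 <- seg$span[1]; i1 <- seg$span[2]
    mid <- vertex_at_arc(cum, (cum[i0] + cum[i1]) / 2)
    mid <- min(max(mid, i0 + 1L), i1 - 1L)
    child_spans <- list(c(i0, mid), c(mid, i1))
    # "upper" = nearer the base: the first half on the base-left -> apex
    # side, the second half on the apex -> base-right side
    child_labels <- if (i1 <= ai)
      paste0(seg$label, c("-upper", "-lower"))
    else
      paste0(seg$label, c("-lower", "-upper"))
    spans <- c(spans, child_spans)
    labels <- c(labels, child_labels)
    rois <- c(rois, partition_mask(seg$roi_mask, endo, child_spans,
                                   vrange = i0:i1))
  }
  build_segments(spans, labels, contour, rois)
}

# Centers and per-segment tangent/normal bases over prepared ROI masks
build_segments <- function(spans, labels, contour, rois) {
  k <- length(spans)
  centers <- t(vapply(spans, segment_center, numeric(2), contour = contour))
  cavity <- colMeans(contour$endo_points)
  segs <- vector("list", k)
  for (i in seq_len(k)) {
    vp <- centers[max(i - 1L, 1L), ]
    vn <- centers[min(i + 1L, k), ]
    tn <- tangent_normal(vp, centers[i, ], vn, toward = cavity)
    segs[[i]] <- structure(
      list(label = labels[i], span = spans[[i]], center = centers[i, ],
           tangent = tn$tangent, normal = tn$normal, roi_mask = rois[[i]]),
      class = "wall_segment")
  }
  segs
}

nearest_vertex <- function(pix, verts) {
  out <- integer(nrow(pix))
  chunk <- 4000L
  for (s in seq(1L, nrow(pix), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pix))
    d <- outer(pix[s:e, 1], verts[, 1], `-`)^2 +
         outer(pix[s:e, 2], verts[, 2], `-`)^2
    out[s:e] <- max.col(-d, ties.method = "first")
  }
  out
}

#' Center point of a segment span
#'
#' Joins the span's two endocardial endpoints by a chord; from the chord
#' midpoint, marches horizontally (constant row) to the nearest
#' intersection with the span's endocardial polyline and returns that
#' point. If no horizontal intersection exists within the span (a
#' near-horizontal span), falls back to the arc-length midpoint.
#'
#' @param span integer pair (first and last endocardial vertex index) or a
#'   `wall_segment`.
#' @param contour a [wall_contour].
#' @return numeric (row, col).
#' @export
segment_center <- function(span, contour) {
  if (inherits(span, "wall_segment")) span <- span$span
  endo <- contour$endo_points
  i0 <- span[1]; i1 <- span[2]
  if (i1 <= i0) stop("segment_center: empty span")
  mid <- (endo[i0, ] + endo[i1, ]) / 2
  pts <- endo[i0:i1, , drop = FALSE]
  hits <- numeric(0)
  for (j in seq_len(nrow(pts) - 1L)) {
    r1 <- pts[j, 1]; r2 <- pts[j + 1L, 1]
    if ((r1 - mid[1]) * (r2 - mid[1]) <= 0 && r1 != r2) {
      t <- (mid[1] - r1) / (r2 - r1)
      hits <- c(hits, pts[j, 2] + t * (pts[j + 1L, 2] - pts[j, 2]))
    }
  }
  if (length(hits) > 0) {
    col <- hits[which.min(abs(hits - mid[2]))]
    return(c(mid[1], col))
  }
  cum <- arc_lengths(pts)
  target <- cum[length(cum)] / 2
  j <- max(which(cum <= target))
  if (j >= nrow(pts)) return(pts[nrow(pts), ])
  t <- (target - cum[j]) / (cum[j + 1L] - cum[j])
  pts[j, ] + t * (pts[j + 1L, ] - pts[j, ])
}

#' Circumferential tangent and radial normal at a point
#'
#' The tangent is the sum of the unit vectors from the predecessor to the
#' point and from the point to the successor, renormalized to unit length;
#' the normal is the tangent rotated by 90 degrees, with its sign chosen to
#' point toward `toward` (the cavity centroid), i.e. in the direction of
#' myocardial contraction. Endpoint positions replicate the available
#' neighbor (one-sided difference).
#'
#' @param v_prev,v,v_next (row, col) positions of the predecessor, the
#'   point, and the successor along the clockwise wall. `v_prev` or
#'   `v_next` may equal `v` at the ends.
#' @param toward (row, col) point the normal should face (cavity centroid).
#' @return list with unit vectors `tangent` and `normal` in (row, col)
#'   components.
#' @export
tangent_normal <- function(v_prev, v, v_next, toward) {
  d1 <- v - v_prev
  d2 <- v_next - v
  n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
  if (n1 == 0 && n2 == 0)
    stop("degenerate geometry: coincident neighbor points")
  t <- (if (n1 > 0) d1 / n1 else d2 / n2) +
       (if (n2 > 0) d2 / n2 else d1 / n1)
  nt <- sqrt(sum(t^2))
  if (nt < 1e-12)
    stop("degenerate geometry: opposing neighbor directions")
  t <- t / nt
  nrm <- c(-t[2], t[1])
  if (sum(nrm * (toward - v)) < 0) nrm <- -nrm
  list(tangent = t, normal = nrm)
}

#' Decompose a flow field into radial and circumferential components
#'
#' Projects the flow onto a segment's radial (cavity-directed) normal and
#' circumferential tangent. One basis per segment, applied to every pixel;
#' positive radial motion points into the cavity (contraction).
#'
#' @param flow a [flow_field].
#' @param segment a `wall_segment` (from [split_six] or [subdivide]).
#' @return list with matrices `radial` and `circumferential` (pixels).
#' @export
decompose <- function(flow, segment) {
  flow <- as_flow_field(flow)
  t <- segment$tangent; n <- segment$normal
  list(radial = flow$v * n[1] + flow$u * n[2],
       circumferential = flow$v * t[1] + flow$u * t[2])
}

# Rasterize the myocardial ring between epicardium and endocardium by
# even-odd scanline fill of the closed polygon (epi forward, endo reversed).
contour_mask <- function(contour, dim) {
  poly <- rbind(contour$epi_points,
                contour$endo_points[rev(seq_len(nrow(contour$endo_points))), ])
  nr <- dim[1]; nc <- dim[2]
  mask <- matrix(FALSE, nr, nc)
  n <- nrow(poly)
  xs <- poly[, 2]; ys <- poly[, 1]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  for (r in seq_len(nr)) {
    crosses <- (ys <= r & ye > r) | (ye <= r & ys > r)
    if (!any(crosses)) next
    t <- (r - ys[crosses]) / (ye[crosses] - ys[crosses])
    cols <- sort(xs[crosses] + t * (xe[crosses] - xs[crosses]))
    for (i in seq(1, length(cols) - 1, by = 2)) {
      c0 <- ceiling(cols[i]); c1 <- floor(cols[i + 1])
      if (c1 >= c0) mask[r, max(c0, 1):min(c1, nc)] <- TRUE
    }
  }
  mask
}
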