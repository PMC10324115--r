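# File I/O: image stacks (PNG/TIFF), Middlebury .flo flow fields, contour
# JSON, and curve CSV. All images are read as grayscale matrices in [0, 1]
# (multi-channel inputs are averaged). Contour files store 0-based (row,
# col) coordinates for interoperability; coordinates are 1-based in R.

#' Read a grayscale image sequence
#'
#' Accepts a directory of PNG/TIFF frames (sorted by filename), a character
#' vector of file paths, or a single multi-page TIFF. 8/16-bit integer data
#' are normalized to [0, 1] (png and tiff readers already return that
#' scale); color frames are averaged across channels.
#'
#' @param path directory, file vector, or multi-page TIFF path.
#' @param mm_per_px,frame_interval calibration attached to the sequence;
#'   `mm_per_px` has no default in the files themselves and must be
#'   supplied for millimetre output.
#' @return an [image_sequence].
#' @export
read_sequence <- function(path, mm_per_px = 1, frame_interval = 0.02) {
  files <- path
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("read_sequence: no PNG/TIFF files in ", path)
  }
  missing <- files[!file.exists(files)]
  if (length(missing) > 0)
    stop("read_sequence: cannot open ", paste(missing, collapse = ", "))
  frames <- list()
  for (f in files) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      frames <- c(frames, list(to_gray(png::readPNG(f))))
    } else {
      pages <- tiff::readTIFF(f, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      frames <- c(frames, lapply(pages, to_gray))
    }
  }
  image_sequence(frames, mm_per_px = mm_per_px,
                 frame_interval = frame_interval)
}

to_gray <- function(a) {
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                        drop = FALSE], c(1, 2), mean)
  m <- as.matrix(a)
  pmin(pmax(m, 0), 1)
}

#' Write an image sequence as PNG frames with a manifest
#'
#' @param seq an [image_sequence].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
write_sequence <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "image_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(seq$frames))
  for (k in seq_along(seq$frames)) {
    paths[k] <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    png::writePNG(pmin(pmax(seq$frames[[k]], 0), 1), paths[k])
  }
  manifest <- list(n_frames = length(seq$frames),
                   dim = dim(seq$frames[[1]]),
                   mm_per_px = seq$mm_per_px,
                   frame_interval = seq$frame_interval,
                   files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

FLO_MAGIC <- 202021.25

#' Write a flow field as a Middlebury .flo file
#'
#' Little-endian binary: float magic 202021.25, int32 width and height,
#' then row-major interleaved (u, v) float32 pairs.
#'
#' @param flow a [flow_field].
#' @param path output file path.
#' @export
write_flow <- function(flow, path) {
  flow <- as_flow_field(flow)
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- nrow(flow$u); nc <- ncol(flow$u)
  writeBin(FLO_MAGIC, con, size = 4, endian = "little")
  writeBin(c(as.integer(nc), as.integer(nr)), con, size = 4,
           endian = "little")
  # row-major pixel order, u before v at each pixel
  inter <- rbind(as.vector(t(flow$u)), as.vector(t(flow$v)))
  writeBin(as.vector(inter), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo flow field
#'
#' @param path .flo file path.
#' @return a [flow_field].
#' @export
read_flow <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, numeric(), 1, size = 4, endian = "little")
  if (abs(magic - FLO_MAGIC) > 1e-3)
    stop("read_flow: bad magic number in ", path, " (offset 0)")
  wh <- readBin(con, integer(), 2, size = 4, endian = "little")
  nc <- wh[1]; nr <- wh[2]
  dat <- readBin(con, numeric(), 2 * nr * nc, size = 4, endian = "little")
  if (length(dat) != 2 * nr * nc)
    stop("read_flow: truncated data in ", path)
  inter <- matrix(dat, nrow = 2)
  u <- matrix(inter[1, ], nr, nc, byrow = TRUE)
  v <- matrix(inter[2, ], nr, nc, byrow = TRUE)
  flow_field(u, v)
}

#' Read a wall contour from JSON
#'
#' Expects fields `endo`, `epi` (arrays of [row, col] pairs, 0-based) and
#' `apex_index` (0-based). Coordinates are converted to R's 1-based
#' convention.
#'
#' @param path JSON file path.
#' @return a [wall_contour].
#' @export
read_contour <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("endo", "epi", "apex_index"))
    if (is.null(x[[f]])) stop("read_contour: missing field '", f, "' in ", path)
  wall_contour(as.matrix(x$endo) + 1, as.matrix(x$epi) + 1,
               as.integer(x$apex_index) + 1L)
}

#' Write a wall contour to JSON (0-based coordinates)
#'
#' @param contour a [wall_contour].
#' @param path output path.
#' @export
write_contour <- function(contour, path) {
  jsonlite::write_json(
    list(endo = unname(contour$endo_points - 1),
         epi = unname(contour$epi_points - 1),
         apex_index = contour$apex_index - 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write segment displacement curves as tidy CSV
#'
#' Columns: frame, segment, incremental_px, cumulative_px, cumulative_mm.
#'
#' @param curves a `segment_curves` object from [track_sequence].
#' @param path output CSV path.
#' @return invisibly, the tidy data.frame written.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "segment_curves"))
  nf <- nrow(curves$cumulative_px)
  df <- data.frame(
    frame = rep(seq_len(nf), times = length(curves$labels)),
    segment = rep(curves$labels, each = nf),
    incremental_px = as.vector(curves$incremental_px),
    cumulative_px = as.vector(curves$cumulative_px),
    cumulative_mm = as.vector(curves$cumulative_mm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
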