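#' Render a synthetic oocyte silhouette frame
#'
#' Draws a centered disc of intensity `fg` on a background of intensity `bg`
#' (a silhouette may be dark-on-light or the inverse) and adds additive
#' Gaussian pixel noise. A pixel belongs to the disc when its center lies
#' within `radius_px` of the image center.
#'
#' @param radius_px Disc radius in pixels; 0 yields a uniform background
#'   frame. Must leave a margin of at least 2 px to the image edge.
#' @param shape Integer vector `c(rows, cols)` of the frame (default 256x256).
#' @param fg,bg Foreground (disc) and background intensities.
#' @param noise_sd Standard deviation of additive Gaussian noise (0 = none).
#' @param seed Integer seed for the noise.
#' @return A numeric `shape[1] x shape[2]` matrix.
#' @examples
#' fr <- render_oocyte_frame(50)
#' sum(fr < 0.5) # ~ pi * 50^2
#' @export
render_oocyte_frame <- function(radius_px, shape = c(256L, 256L),
                                fg = 0.1, bg = 0.9, noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 1), radius_px >= 0)
  if (radius_px > 0 && radius_px > min(shape) / 2 - 2) {
    stop("radius ", radius_px, " px too large for a ", shape[1], "x", shape[2],
         " frame (needs >= 2 px margin)", call. = FALSE)
  }
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- (rows - cy)^2 + (cols - cx)^2 <= radius_px^2
  frame <- matrix(bg, shape[1], shape[2])
  frame[inside] <- fg
  if (noise_sd > 0) {
    frame <- withr::with_seed(seed, {
      frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                     shape[1], shape[2])
    })
  }
  frame
}

#' Measure the silhouette area in a grayscale frame
#'
#' Segments the frame by Otsu's global threshold, takes the minority
#' intensity class as foreground (so dark-on-light and light-on-dark
#' silhouettes are both handled), keeps the largest connected component
#' under 8-connectivity, fills interior holes, and returns its pixel count.
#' The result is invariant to any increasing linear rescaling of the
#' intensities.
#'
#' @param frame Numeric matrix of pixel intensities.
#' @return Area of the silhouette in px^2 (a single number).
#' @examples
#' extract_area(render_oocyte_frame(50))
#' @export
extract_area <- function(frame) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame)
  if (diff(rng) <= .Machine$double.eps) {
    stop("no object: frame contains a single intensity", call. = FALSE)
  }
  norm <- (frame - rng[1]) / diff(rng) # Otsu in EBImage expects [0, 1]
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  # foreground = minority class
  if (sum(mask) > length(mask) / 2) mask <- !mask
  if (!any(mask)) {
    stop("no object: threshold produced an empty foreground", call. = FALSE)
  }
  lab <- .label8(mask)
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  comp <- lab == biggest
  comp <- EBImage::fillHull(EBImage::Image(comp * 1)) > 0
  sum(comp)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the label pairs.
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Read silhouette frames from image files
#'
#' Loads PNG/TIFF frames into grayscale intensity matrices. Files are
#' sorted by name, so a sortable time index in the filename (e.g.
#' `frame_000.png`, `frame_015.png`) fixes the acquisition order; times
#' are assigned from `interval_s`. Color images are averaged across
#' channels.
#'
#' @param paths Character vector of image file paths (or a single
#'   directory, from which all .png/.tif/.tiff files are taken).
#' @param interval_s Acquisition interval in seconds (default 15).
#' @return A list with `frames` (list of matrices) and `times` (seconds,
#'   starting at 0).
#' @export
read_frames <- function(paths, interval_s = 15) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  if (length(paths) == 0) stop("no image files found", call. = FALSE)
  paths <- sort(paths)
  frames <- lapply(paths, function(p) {
    img <- EBImage::imageData(EBImage::readImage(p))
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    as.matrix(img)
  })
  list(frames = frames, times = (seq_along(frames) - 1) * interval_s)
}

#' Build a swelling trace from a stack of silhouette frames
#'
#' Measures the silhouette area of every frame with [extract_area()],
#' normalizes to the first frame (rel_area = A_i / A_0) and derives the
#' relative volume V/V0 = (A/A0)^(3/2).
#'
#' @param frames List of numeric matrices, all the same dimensions.
#' @param times Acquisition times in seconds, strictly increasing, one per
#'   frame, first = 0.
#' @param oocyte_id,group,condition Labels copied into the output.
#' @return A `swelling_trace` tibble (see [simulate_swelling()]).
#' @examples
#' frames <- lapply(c(50, 52.5, 55), render_oocyte_frame)
#' trace_from_frames(frames, times = c(0, 15, 30))
#' @export
trace_from_frames <- function(frames, times, oocyte_id = "oo1",
                              group = "expressing", condition = "water") {
  stopifnot(is.list(frames), length(frames) >= 2,
            length(times) == length(frames))
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same dimensions", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  areas <- vapply(frames, extract_area, numeric(1))
  if (areas[1] <= 0) stop("zero silhouette area in frame 0", call. = FALSE)
  rel_area <- areas / areas[1]
  new_swelling_trace(tibble::tibble(
    oocyte_id = oocyte_id, group = group, condition = condition,
    time_s = as.numeric(times), rel_area = rel_area,
    rel_volume = relative_volume(rel_area)
  ))
}
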