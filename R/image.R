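# Image-based growth quantification: crop a plate image into 96 tiles,
# segment each pinned patch (Otsu threshold with a circle-detection
# fallback), and measure the pixelsum growth metric.

#' Otsu threshold of a grayscale tile
#'
#' Histogram-based threshold maximizing between-class variance.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param nbins Number of histogram bins (default 256).
#' @return Threshold on the intensity scale; `NA` for constant input.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) < .Machine$double.eps) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between[-nbins])]
}

#' Crop a plate image into 96 labelled tiles
#'
#' Partitions the image into an 8 x 12 grid of equal tiles labelled A1..H12
#' row-major (tile (1,1) = A1, tile (8,12) = H12). Dimensions not divisible
#' by the grid are trimmed evenly on both sides with a warning.
#'
#' @param image Grayscale intensity matrix.
#' @param nrow_grid,ncol_grid Grid size (default 8 x 12).
#' @return Named list of tile matrices, in row-major well order.
#' @export
crop_tiles <- function(image, nrow_grid = 8L, ncol_grid = 12L) {
  stopifnot(is.matrix(image), nrow(image) >= nrow_grid, ncol(image) >= ncol_grid)
  trim <- function(n, k) {
    extra <- n %% k
    lo <- extra %/% 2L
    c(lo + 1L, n - (extra - lo))
  }
  if (nrow(image) %% nrow_grid != 0 || ncol(image) %% ncol_grid != 0) {
    warning("image dimensions not divisible by grid; trimming evenly")
  }
  rr <- trim(nrow(image), nrow_grid)
  cc <- trim(ncol(image), ncol_grid)
  image <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  th <- nrow(image) %/% nrow_grid
  tw <- ncol(image) %/% ncol_grid
  tiles <- vector("list", nrow_grid * ncol_grid)
  labels <- character(length(tiles))
  k <- 0L
  for (r in seq_len(nrow_grid)) {
    for (cl in seq_len(ncol_grid)) {
      k <- k + 1L
      tiles[[k]] <- image[((r - 1L) * th + 1L):(r * th),
                          ((cl - 1L) * tw + 1L):(cl * tw), drop = FALSE]
      labels[k] <- well_label(r, cl)
    }
  }
  names(tiles) <- labels
  tiles
}

#' Segment the pinned patch within one tile
#'
#' Applies an Otsu threshold; if the resulting foreground fraction falls
#' outside the plausibility band `[min_frac, max_frac]` (e.g. inverted
#' contrast or noise-only tiles), falls back to a fixed-radius centered
#' circle and flags the tile. Constant tiles yield an empty mask with a flag.
#'
#' @param tile Intensity matrix.
#' @param min_frac,max_frac Plausible foreground fraction band (default
#'   0.01-0.60).
#' @param radius_frac Fallback circle radius as a fraction of the smaller
#'   tile dimension (default 0.3).
#' @return Logical mask matrix with attribute `flag` (`""`, `"constant"`, or
#'   `"circle_fallback"`).
#' @export
segment_patch <- function(tile, min_frac = 0.01, max_frac = 0.60, radius_frac = 0.3) {
  stopifnot(is.matrix(tile))
  th <- otsu_threshold(tile)
  if (is.na(th)) {
    mask <- matrix(FALSE, nrow(tile), ncol(tile))
    attr(mask, "flag") <- "constant"
    return(mask)
  }
  mask <- tile > th
  frac <- mean(mask)
  flag <- ""
  if (frac < min_frac || frac > max_frac) {
    ctr <- (dim(tile) + 1) / 2
    rad <- radius_frac * min(dim(tile))
    rowm <- matrix(seq_len(nrow(tile)), nrow(tile), ncol(tile))
    colm <- matrix(seq_len(ncol(tile)), nrow(tile), ncol(tile), byrow = TRUE)
    mask <- (rowm - ctr[1])^2 + (colm - ctr[2])^2 <= rad^2
    flag <- "circle_fallback"
  }
  attr(mask, "flag") <- flag
  mask
}

#' Measure the pixelsum of a segmented patch
#'
#' The growth metric: sum of grayscale intensities inside the patch mask.
#'
#' @param tile Intensity matrix.
#' @param mask Logical mask of the same shape.
#' @return One-row data frame with `pixelsum`, `area` and `flag`.
#' @export
measure_pixelsum <- function(tile, mask) {
  if (!identical(dim(tile), dim(mask))) stop("tile and mask shapes differ")
  data.frame(pixelsum = sum(tile[mask]), area = sum(mask),
             flag = attr(mask, "flag") %||% "", stringsAsFactors = FALSE)
}

#' Quantify a full plate image
#'
#' Runs crop -> segment -> measure over all 96 tiles and returns one patch
#' measurement per well, compatible with the growth-normalization input.
#'
#' @param image Grayscale plate image matrix.
#' @param plate_id,replicate Metadata attached to every row.
#' @param ... Passed to [segment_patch()].
#' @return Data frame with `plate_id`, `replicate`, `well`, `row`, `col`,
#'   `is_edge`, `pixelsum`, `area`, `flag`.
#' @export
quantify_plate_image <- function(image, plate_id = "P01", replicate = 1L, ...) {
  tiles <- crop_tiles(image)
  rows <- lapply(names(tiles), function(w) {
    tile <- tiles[[w]]
    mask <- segment_patch(tile, ...)
    m <- measure_pixelsum(tile, mask)
    cbind(data.frame(plate_id = plate_id, replicate = replicate, well = w,
                     row = well_row(w), col = well_col(w),
                     is_edge = is_edge_well(well_row(w), well_col(w)),
                     stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
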