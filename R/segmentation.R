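#' Foreground (cell-covered area) mask
#'
#' Separates cell-covered area from empty background using the intrinsic
#' autofluorescence of the cell bodies. Each channel is expressed as its
#' excess over its own background level (the intensity mode) normalized by
#' its dynamic range (99.5th percentile minus mode), clipped at the
#' equivalent of `2 * beta` on the output scale, and Gaussian-smoothed. The
#' per-pixel maximum of the two channels is mapped back onto the raw
#' marker-channel scale (so `beta` keeps marker intensity units) and
#' thresholded at `beta`.
#'
#' Clipping before smoothing makes the mask boundary the (approximate)
#' half-height contour of the cell edge: without it, the smoothed skirt of a
#' very bright cell would cross an absolute threshold several pixels outside
#' the cell, making the mask depend on marker brightness. Combining both
#' channels keeps marker-negative cells in the mask via their nucleus
#' signal. Connected foreground specks and enclosed holes smaller than
#' `min_area_px` are removed/filled.
#'
#' @param image A [multichannel_image()].
#' @param params An [analysis_params()] object.
#' @return Logical matrix, `TRUE` on cell-covered pixels.
#' @export
foreground_mask <- function(image, params = analysis_params()) {
  nuc <- nucleus_matrix(image)
  mar <- marker_matrix(image)
  b_m <- channel_mode(mar)
  span_m <- quantile(mar, 0.995, names = FALSE) - b_m
  scale_back <- if (span_m > 0) span_m else 1
  # clip level for the normalized excess: 2*beta on the output scale
  cap_e <- max((2 * params$beta - b_m) / scale_back, 0)
  excess <- function(ch) {
    b <- channel_mode(ch)
    span <- quantile(ch, 0.995, names = FALSE) - b
    e <- if (span > 0) (ch - b) / span else ch * 0
    gaussian_smooth(pmin(e, cap_e), params$smoothing_sigma)
  }
  comp <- pmax(excess(nuc), excess(mar)) * scale_back + b_m
  mask <- comp >= params$beta
  prune_mask(mask, params$min_area_px)
}

# Remove connected TRUE components smaller than min_area and fill enclosed
# FALSE holes smaller than min_area.
prune_mask <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_area)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  if (!any(!mask)) return(mask)
  hole_lab <- EBImage::bwlabel(!mask)
  edge_ids <- unique(c(hole_lab[1, ], hole_lab[nrow(hole_lab), ],
                       hole_lab[, 1], hole_lab[, ncol(hole_lab)]))
  hsizes <- tabulate(hole_lab[hole_lab > 0])
  fill <- setdiff(which(hsizes < min_area), edge_ids)
  if (length(fill)) mask[hole_lab %in% fill] <- TRUE
  mask
}

#' Detect nucleus seeds
#'
#' Finds local maxima of the Gaussian-smoothed nucleus channel restricted to
#' the foreground mask, keeping maxima with peak prominence at least `omega`
#' (persistence of the super-level-set component). Intensity plateaus
#' contribute exactly one seed at the plateau centroid (ties toward smaller
#' `(y, x)`). Seeds closer than the minimum separation
#' `2 * smoothing_sigma + 1` px are thinned, keeping the brighter peak.
#'
#' @param image A [multichannel_image()].
#' @param mask Logical foreground mask from [foreground_mask()].
#' @param params An [analysis_params()] object.
#' @return A data frame of class `seed_set` with 0-based columns `y`, `x`
#'   plus `value` (smoothed peak intensity) and `prominence`.
#' @export
detect_nuclei <- function(image, mask, params = analysis_params()) {
  stopifnot(all(dim(mask) == dim(image$pixels)[1:2]))
  sm <- gaussian_smooth(nucleus_matrix(image), params$smoothing_sigma)
  pk <- prominence_peaks_cpp(sm, mask, params$omega)
  seeds <- data.frame(y = pk$y - 1L, x = pk$x - 1L,
                      value = pk$value, prominence = pk$prominence)
  o <- order(-seeds$value, seeds$y, seeds$x)
  seeds <- seeds[o, , drop = FALSE]
  min_sep <- 2 * params$smoothing_sigma + 1
  if (nrow(seeds) > 1 && min_sep > 0) {
    keep <- rep(TRUE, nrow(seeds))
    for (i in seq_len(nrow(seeds))[-1]) {
      prev <- which(keep[seq_len(i - 1)])
      d2 <- (seeds$y[prev] - seeds$y[i])^2 + (seeds$x[prev] - seeds$x[i])^2
      if (any(d2 < min_sep^2)) keep[i] <- FALSE
    }
    seeds <- seeds[keep, , drop = FALSE]
  }
  rownames(seeds) <- NULL
  class(seeds) <- c("seed_set", "data.frame")
  seeds
}

#' Segment cells by nuclei-seeded watershed
#'
#' Marker-controlled watershed on the elevation surface
#' `E = -(Gaussian-smoothed nucleus channel)` (nuclei become basins), flooded
#' from the seeds and restricted to the foreground mask. Ties in elevation are
#' broken by Euclidean distance to the claiming seed, so on constant elevation
#' the partition is the nearest-seed assignment. Regions smaller than
#' `min_area_px` are removed; with `exclude_border` regions touching the image
#' edge are removed; labels are compacted to `1..N` in seed order.
#'
#' @param image A [multichannel_image()].
#' @param mask Logical foreground mask.
#' @param seeds A `seed_set` from [detect_nuclei()] (or any data frame with
#'   0-based `y`, `x` columns). Seeds outside the mask are dropped with a
#'   warning.
#' @param params An [analysis_params()] object.
#' @return Integer label matrix (0 = background).
#' @export
segment_cells <- function(image, mask, seeds, params = analysis_params()) {
  stopifnot(all(dim(mask) == dim(image$pixels)[1:2]))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  if (is.null(seeds) || nrow(seeds) == 0) return(labels)
  y1 <- as.integer(seeds$y) + 1L
  x1 <- as.integer(seeds$x) + 1L
  inside <- y1 >= 1 & y1 <= nrow(mask) & x1 >= 1 & x1 <= ncol(mask)
  inside[inside] <- mask[cbind(y1[inside], x1[inside])]
  if (any(!inside)) {
    warning(sprintf("%d seed(s) outside the foreground mask were dropped",
                    sum(!inside)))
    y1 <- y1[inside]
    x1 <- x1[inside]
  }
  if (length(y1) == 0) return(labels)
  elev <- -gaussian_smooth(nucleus_matrix(image), params$smoothing_sigma)
  labels <- seeded_watershed_cpp(elev, mask, y1, x1)
  relabel_regions(labels, params$min_area_px, params$exclude_border)
}

# Drop regions below min_area (and, optionally, border-touching regions);
# compact labels to 1..N preserving ascending (seed) order.
relabel_regions <- function(labels, min_area, exclude_border) {
  n <- max(labels)
  if (n == 0) return(labels)
  sizes <- tabulate(labels[labels > 0], nbins = n)
  drop <- sizes < min_area
  if (exclude_border) {
    edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
    drop[edge[edge > 0]] <- TRUE
  }
  map <- integer(n + 1)
  keep <- which(!drop & sizes > 0)
  map[keep + 1] <- seq_along(keep)
  matrix(map[labels + 1], nrow(labels), ncol(labels))
}
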