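#' Estimate the background fluorescence level
#'
#' Median marker-channel intensity over pixels outside the foreground mask; a
#' robust statistic, insensitive to bright debris. If the mask covers the
#' whole image there is no true background; the 1st percentile of the marker
#' channel is returned instead with a warning.
#'
#' @param image A [multichannel_image()].
#' @param mask Logical foreground mask.
#' @return Background level in raw intensity units.
#' @export
estimate_background <- function(image, mask) {
  mar <- marker_matrix(image)
  if (any(!mask)) return(median(mar[!mask]))
  warning("mask covers the whole image; falling back to the 1st percentile of the marker channel")
  quantile(mar, 0.01, names = FALSE)
}

# Crofton-style perimeter from directed intercept counts on the padded label
# map: P = pi/8 * (I_h + I_v + (I_d1 + I_d2)/sqrt(2)), calibrated so that a
# rasterized disc of radius r gives ~2*pi*r. Slightly below ImageJ's polygon
# perimeter on elongated shapes; low bias on convex blobs.
crofton_perimeter <- function(labels, n) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  count_dir <- function(a, b) {
    d <- a != b
    tabulate(c(a[d][a[d] > 0], b[d][b[d] > 0]), nbins = n)
  }
  ih <- count_dir(pad[, -ncol(pad)], pad[, -1])
  iv <- count_dir(pad[-nrow(pad), ], pad[-1, ])
  id1 <- count_dir(pad[-nrow(pad), -ncol(pad)], pad[-1, -1])
  id2 <- count_dir(pad[-nrow(pad), -1], pad[-1, -ncol(pad)])
  pi / 8 * (ih + iv + (id1 + id2) / sqrt(2))
}

#' Measure per-cell geometry and marker intensity
#'
#' One record per label: centroid (0-based pixel coordinates, unweighted mean
#' of member pixels), pixel area, Crofton-style perimeter, circularity
#' `4*pi*area/perimeter^2` clamped to 1, mean raw marker intensity, and the
#' background-corrected mean floored at 0. `log10_intensity` is
#' `log10(mean_corrected)`, or `NA` when the corrected mean is non-positive.
#' The `is_fluorescent` flag is initialised to `FALSE` and set by
#' [classify_cells()].
#'
#' @param labels Integer label matrix from [segment_cells()].
#' @param image A [multichannel_image()].
#' @param background Background level from [estimate_background()].
#' @return A data frame of class `cell_table`, one row per cell.
#' @export
measure_cells <- function(labels, image, background) {
  stopifnot(all(dim(labels) == dim(image$pixels)[1:2]))
  n <- max(labels)
  empty <- data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                      area_px = integer(), perimeter_px = numeric(),
                      circularity = numeric(), mean_raw = numeric(),
                      mean_corrected = numeric(), log10_intensity = numeric(),
                      is_fluorescent = logical(), touches_border = logical())
  class(empty) <- c("cell_table", "data.frame")
  if (n == 0) return(empty)
  mar <- marker_matrix(image)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  area <- tabulate(lab, nbins = n)
  cy <- tapply(rows, lab, mean) - 1
  cx <- tapply(cols, lab, mean) - 1
  mean_raw <- tapply(mar[idx], lab, mean)
  perim <- crofton_perimeter(labels, n)
  circ <- pmin(4 * pi * area / perim^2, 1)
  mean_corr <- pmax(mean_raw - background, 0)
  l10 <- ifelse(mean_corr > 0, log10(mean_corr), NA_real_)
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  touches <- seq_len(n) %in% border_ids
  out <- data.frame(cell_id = seq_len(n), x = as.numeric(cx),
                    y = as.numeric(cy), area_px = area,
                    perimeter_px = perim, circularity = circ,
                    mean_raw = as.numeric(mean_raw),
                    mean_corrected = as.numeric(mean_corr),
                    log10_intensity = as.numeric(l10),
                    is_fluorescent = FALSE, touches_border = touches)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Build the log10 single-cell intensity histogram
#'
#' Cells with positive corrected mean intensity are binned by
#' `log10(mean_corrected)` into `n_bins` equal-width bins spanning the
#' observed range of finite log10 values (a single distinct value yields one
#' unit-width bin centered on it). Cells with non-positive corrected
#' intensity are counted in `n_excluded` and omitted from the bins, so that
#' `sum(counts) + n_excluded` equals the number of cells measured.
#'
#' @param cells A `cell_table` from [measure_cells()].
#' @param params An [analysis_params()] object (`n_bins`).
#' @return An object of class `log10_histogram` with fields `bin_edges`
#'   (length `n_bins + 1`), `counts` and `n_excluded`.
#' @export
log10_histogram <- function(cells, params = analysis_params()) {
  vals <- cells$log10_intensity[!is.na(cells$log10_intensity)]
  n_excl <- nrow(cells) - length(vals)
  if (length(vals) == 0) {
    return(structure(list(bin_edges = numeric(0), counts = integer(0),
                          n_excluded = n_excl), class = "log10_histogram"))
  }
  lo <- min(vals)
  hi <- max(vals)
  if (lo == hi) {
    edges <- c(lo - 0.5, lo + 0.5)
    counts <- length(vals)
  } else {
    edges <- seq(lo, hi, length.out = params$n_bins + 1)
    bin <- pmin(pmax(findInterval(vals, edges, rightmost.closed = TRUE), 1),
                params$n_bins)
    counts <- tabulate(bin, nbins = params$n_bins)
  }
  structure(list(bin_edges = edges, counts = as.integer(counts),
                 n_excluded = as.integer(n_excl)), class = "log10_histogram")
}

#' @export
print.log10_histogram <- function(x, ...) {
  cat(sprintf("<log10_histogram> %d bins, %d cells binned, %d excluded\n",
              length(x$counts), sum(x$counts), x$n_excluded))
  invisible(x)
}
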