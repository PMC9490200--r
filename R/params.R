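#' Analysis parameters
#'
#' Bundles the three workflow parameters (`beta`, `omega`, `alpha`) together
#' with the structural settings of the pipeline. The defaults
#' `beta = 15, omega = 5, alpha = 0.4` are sufficient for typical monolayer
#' images and are the recommended starting point.
#'
#' @param beta Background threshold in raw intensity units: pixels of the
#'   smoothed nucleus/marker composite below `beta` are treated as cell-free
#'   background.
#' @param omega Segmentation sensitivity: minimum prominence (raw nucleus-
#'   channel intensity units) for a local maximum to become a cell seed.
#' @param alpha Intensity cutoff offset in log10 decades above the
#'   non-fluorescent population peak; cells at or above the resulting
#'   cutoff are classified fluorescent.
#' @param n_bins Number of bins of the log10 intensity histogram.
#' @param min_area_px Minimum region area (pixels); smaller segments are
#'   dropped, and foreground specks/holes below this size are cleaned up.
#' @param exclude_border If `TRUE`, regions touching the image edge are
#'   removed; by default they are kept and flagged `touches_border` so that
#'   ratio-based readouts are not biased in dense fields.
#' @param smoothing_sigma Gaussian pre-filter sigma in pixels used for the
#'   foreground mask, seed detection and the watershed elevation surface.
#' @return An object of class `analysis_params`.
#' @export
#' @examples
#' analysis_params()
#' analysis_params(beta = 20, alpha = 0.5)
analysis_params <- function(beta = 15, omega = 5, alpha = 0.4,
                            n_bins = 64, min_area_px = 30,
                            exclude_border = FALSE, smoothing_sigma = 2) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(omega), length(omega) == 1, omega > 0,
            is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.numeric(n_bins), length(n_bins) == 1, n_bins >= 8,
            is.numeric(min_area_px), length(min_area_px) == 1, min_area_px >= 1,
            is.logical(exclude_border), length(exclude_border) == 1,
            is.numeric(smoothing_sigma), length(smoothing_sigma) == 1,
            smoothing_sigma >= 0)
  structure(list(beta = beta, omega = omega, alpha = alpha,
                 n_bins = as.integer(n_bins),
                 min_area_px = as.integer(min_area_px),
                 exclude_border = exclude_border,
                 smoothing_sigma = smoothing_sigma),
            class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  cat(sprintf("  beta (background threshold)    : %g\n", x$beta))
  cat(sprintf("  omega (seed sensitivity)       : %g\n", x$omega))
  cat(sprintf("  alpha (log10 cutoff offset)    : %g\n", x$alpha))
  cat(sprintf("  n_bins / min_area_px           : %d / %d\n",
              x$n_bins, x$min_area_px))
  cat(sprintf("  exclude_border / smoothing     : %s / sigma = %g px\n",
              x$exclude_border, x$smoothing_sigma))
  invisible(x)
}

# Gaussian smoothing with replicate boundary; radius capped so the kernel
# never exceeds the image (EBImage::filter2 requirement on small images).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(x)  # constant: avoid FFT round-off ripple
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(x))
  if (cap %% 2L == 0L) cap <- cap - 1L
  radius <- min(radius, cap)
  if (radius < 3L) return(x)
  brush <- EBImage::makeBrush(radius, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(x, brush, boundary = "replicate"))
}
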