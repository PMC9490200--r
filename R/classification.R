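# 3-bin moving average with zero padding at the ends.
smooth3 <- function(counts) {
  n <- length(counts)
  if (n == 0) return(numeric(0))
  padded <- c(0, counts, 0)
  (padded[seq_len(n)] + padded[seq_len(n) + 1] + padded[seq_len(n) + 2]) / 3
}

# Leftmost-of-plateau local maxima of a vector (out-of-range treated as -Inf).
local_maxima <- function(s) {
  n <- length(s)
  if (n == 0) return(integer(0))
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  which(s > left & s >= right)
}

#' Classify cells into fluorescent and non-fluorescent populations
#'
#' Locates the non-fluorescent population peak in the 3-bin moving-average
#' smoothed log10 histogram and sets the classification cutoff `alpha` log10
#' decades above it: a cell is fluorescent iff its `log10_intensity` is at or
#' above the cutoff (cells with non-positive corrected intensity are always
#' non-fluorescent).
#'
#' The reference peak is the highest-count smoothed local maximum among the
#' significant peaks (smoothed count at least 10% of the global maximum and
#' at least 2, i.e. a mode of at least ~6 cells) whose bin center lies
#' within one decade of the background
#' threshold, i.e. at most `log10(10 * beta)`: the non-fluorescent population
#' sits just above the autofluorescence level that `beta` thresholds, while
#' the fluorescent population lies well above it. When no such peak exists
#' (no detectable non-fluorescent population, e.g. a fully transfected
#' image), the cutoff falls back to `log10(10 * beta)` itself, so a single
#' bright population is classified fluorescent rather than being measured
#' against its own peak.
#'
#' @param cells A `cell_table` from [measure_cells()].
#' @param hist The [log10_histogram()] built from the same cells.
#' @param params An [analysis_params()] object (`alpha`, `beta`).
#' @param image_title Title copied into the summary.
#' @return A list with `cells` (the table with `is_fluorescent` filled in)
#'   and `summary` (class `image_summary`: title, total cells, fluorescent
#'   cells, fraction, applied cutoff, parameters used).
#' @export
classify_cells <- function(cells, hist, params = analysis_params(),
                           image_title = "") {
  rho <- log10(10 * max(params$beta, 1))
  cutoff <- rho
  nb <- length(hist$counts)
  if (nb > 0 && sum(hist$counts) > 0) {
    s <- smooth3(hist$counts)
    centers <- (hist$bin_edges[-1] + hist$bin_edges[-(nb + 1)]) / 2
    peaks <- local_maxima(s)
    sig <- peaks[s[peaks] >= max(0.10 * max(s), 2)]
    cand <- sig[centers[sig] <= rho]
    if (length(cand) > 0) {
      best <- cand[which.max(s[cand])]  # which.max: leftmost on ties
      cutoff <- centers[best] + params$alpha
    }
  }
  fl <- !is.na(cells$log10_intensity) & cells$log10_intensity >= cutoff
  cells$is_fluorescent <- fl
  total <- nrow(cells)
  summary <- structure(list(image_title = image_title,
                            total_cells = total,
                            fluorescent_cells = sum(fl),
                            fluorescent_fraction =
                              if (total > 0) sum(fl) / total else 0,
                            cutoff_log10 = cutoff,
                            params_used = params),
                       class = "image_summary")
  list(cells = cells, summary = summary)
}

#' @export
print.image_summary <- function(x, ...) {
  cat(sprintf("<image_summary> '%s': %d cells, %d fluorescent (%.1f%%), cutoff log10 = %.3f\n",
              x$image_title, x$total_cells, x$fluorescent_cells,
              100 * x$fluorescent_fraction, x$cutoff_log10))
  invisible(x)
}

# Histogram mode of a channel: center of the highest-count bin among 256
# equal-width bins over the observed range (leftmost on ties).
channel_mode <- function(ch) {
  lo <- min(ch)
  hi <- max(ch)
  if (lo == hi) return(lo)
  edges <- seq(lo, hi, length.out = 257)
  bin <- pmin(pmax(findInterval(ch, edges, rightmost.closed = TRUE), 1), 256)
  counts <- tabulate(bin, nbins = 256)
  k <- which.max(counts)
  (edges[k] + edges[k + 1]) / 2
}

#' Automatically estimate analysis parameters from an image
#'
#' Heuristics for a starting parameter set when the defaults do not fit the
#' intensity scale of an experiment: `beta` is the marker-channel intensity
#' mode (dominated by background in sub-confluent images) plus three times a
#' robust spread estimate (scaled MAD of the sub-mode pixels, floored at 1/3
#' so a constant image yields `beta = value + 1`); `omega` is 5% of the
#' nucleus-channel dynamic range above its mode (99th percentile minus mode),
#' floored at 1; `alpha` stays at the 0.4 default, which is robust across
#' experiments. Intended as a first iteration, to be refined after inspecting
#' the overlay and histogram.
#'
#' @param image A [multichannel_image()].
#' @return An [analysis_params()] object.
#' @export
auto_estimate_params <- function(image) {
  mar <- marker_matrix(image)
  nuc <- nucleus_matrix(image)
  mode_m <- channel_mode(mar)
  sub <- mar[mar <= mode_m]
  spread <- 1.4826 * median(abs(sub - mode_m))
  beta <- mode_m + max(3 * spread, 1)
  mode_n <- channel_mode(nuc)
  omega <- max(0.05 * (quantile(nuc, 0.99, names = FALSE) - mode_n), 1)
  analysis_params(beta = beta, omega = omega, alpha = 0.4)
}
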