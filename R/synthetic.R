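#' Parameters of the synthetic monolayer generator
#'
#' Describes a two-channel monolayer culture: non-overlapping nuclei
#' (Gaussian blobs) surrounded by dimmer autofluorescent cell bodies
#' (discs), with a controllable fraction of cells carrying a bright
#' lognormal marker signal, on an additive Gaussian background. Intensities
#' live on a 16-bit-like scale; the defaults are chosen so the standard
#' analysis parameters `beta = 15, omega = 5, alpha = 0.4` work out of the
#' box. Geometry defaults (cell radius 10 +/- 1.5 px, nucleus radius
#' 4 +/- 0.5 px on a 512 x 512 frame) correspond to confluent HEK-like
#' cells (~20 um diameter) imaged at about 1 um/px.
#'
#' @param shape Image size `c(rows, cols)`.
#' @param n_cells Number of cells to place.
#' @param fluorescent_fraction Fraction of cells carrying marker signal;
#'   exactly `round(n_cells * fluorescent_fraction)` cells are flagged.
#' @param nucleus_radius_px,nucleus_radius_jitter Mean nucleus radius and
#'   half-width of its uniform jitter (px).
#' @param cell_radius_px,cell_radius_jitter Mean cell-body radius and jitter
#'   (px); must exceed the nucleus radius.
#' @param background_mean,background_sd Additive Gaussian background applied
#'   to both channels.
#' @param autofluorescence_level Dim marker-channel signal painted on every
#'   cell body; must exceed `background_mean`.
#' @param marker_log10_mean,marker_log10_sd Lognormal brightness
#'   (log10 scale) of fluorescent cells' marker signal.
#' @param nucleus_amplitude Peak intensity of the nucleus blobs.
#' @param rng_seed Integer seed; generation is bit-exact under a fixed seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(shape = c(512, 512), n_cells = 200,
                         fluorescent_fraction = 0.5,
                         nucleus_radius_px = 4, nucleus_radius_jitter = 0.5,
                         cell_radius_px = 10, cell_radius_jitter = 1.5,
                         background_mean = 5, background_sd = 2,
                         autofluorescence_level = 40,
                         marker_log10_mean = 3, marker_log10_sd = 0.25,
                         nucleus_amplitude = 500, rng_seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 8),
            n_cells >= 0,
            fluorescent_fraction >= 0, fluorescent_fraction <= 1,
            cell_radius_px > nucleus_radius_px,
            autofluorescence_level > background_mean,
            background_sd >= 0,
            10^marker_log10_mean > autofluorescence_level)
  structure(list(shape = as.integer(shape), n_cells = as.integer(n_cells),
                 fluorescent_fraction = fluorescent_fraction,
                 nucleus_radius_px = nucleus_radius_px,
                 nucleus_radius_jitter = nucleus_radius_jitter,
                 cell_radius_px = cell_radius_px,
                 cell_radius_jitter = cell_radius_jitter,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 autofluorescence_level = autofluorescence_level,
                 marker_log10_mean = marker_log10_mean,
                 marker_log10_sd = marker_log10_sd,
                 nucleus_amplitude = nucleus_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_params")
}

with_local_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

# Rejection-sampled centers (0-based, continuous) with a minimum pairwise
# distance of 1.6x the mean cell radius.
place_centers <- function(n, shape, min_dist) {
  ys <- numeric(n)
  xs <- numeric(n)
  placed <- 0
  attempts <- 0
  max_attempts <- max(n * 500, 1000)
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1
    y <- runif(1, 0, shape[1] - 1)
    x <- runif(1, 0, shape[2] - 1)
    if (placed == 0 ||
        all((ys[seq_len(placed)] - y)^2 + (xs[seq_len(placed)] - x)^2 >=
            min_dist^2)) {
      placed <- placed + 1
      ys[placed] <- y
      xs[placed] <- x
    }
  }
  if (placed < n)
    stop(sprintf("packing error: placed only %d of %d cells", placed, n))
  data.frame(y = ys, x = xs)
}

#' Generate a ground-truthed synthetic monolayer image
#'
#' Cell centers are placed by rejection sampling with minimum center distance
#' `1.6 * cell_radius_px`; the nucleus channel is a sum of Gaussian blobs
#' (sigma = nucleus radius / 2) at the centers; the marker channel carries
#' the autofluorescence level on every cell disc plus a lognormal-amplitude
#' signal on the discs of the fluorescent cells; Gaussian background noise is
#' added to both channels (clamped at 0). Exactly
#' `round(n_cells * fluorescent_fraction)` cells, chosen uniformly at random,
#' are flagged fluorescent.
#'
#' @param params A [synth_params()] object.
#' @param title Title given to the generated image.
#' @return A list with `image` (a [multichannel_image()], channel 0 =
#'   nucleus, channel 1 = marker) and `truth` (class `ground_truth`: centers
#'   with per-cell fluorescent flags and radii, the cell-footprint mask, and
#'   the realized fluorescent fraction).
#' @export
generate_monolayer <- function(params = synth_params(), title = "synthetic") {
  stopifnot(inherits(params, "synth_params"))
  shape <- params$shape
  area <- prod(shape)
  if (params$n_cells * pi * params$cell_radius_px^2 > 0.7 * area)
    stop("packing error: requested cells cover more than 70% of the frame")
  with_local_seed(params$rng_seed, {
    nuc <- matrix(0, shape[1], shape[2])
    mar <- matrix(0, shape[1], shape[2])
    footprint <- matrix(FALSE, shape[1], shape[2])
    n <- params$n_cells
    if (n > 0) {
      centers <- place_centers(n, shape, 1.6 * params$cell_radius_px)
      cell_r <- params$cell_radius_px +
        runif(n, -params$cell_radius_jitter, params$cell_radius_jitter)
      nuc_r <- params$nucleus_radius_px +
        runif(n, -params$nucleus_radius_jitter, params$nucleus_radius_jitter)
      n_fl <- round(n * params$fluorescent_fraction)
      fl <- rep(FALSE, n)
      if (n_fl > 0) fl[sample.int(n, n_fl)] <- TRUE
      amps <- ifelse(fl, 10^rnorm(n, params$marker_log10_mean,
                                  params$marker_log10_sd), 0)
      for (i in seq_len(n)) {
        cy <- centers$y[i]
        cx <- centers$x[i]
        r <- cell_r[i]
        y0 <- max(1, floor(cy + 1 - r))
        y1 <- min(shape[1], ceiling(cy + 1 + r))
        x0 <- max(1, floor(cx + 1 - r))
        x1 <- min(shape[2], ceiling(cx + 1 + r))
        yy <- y0:y1
        xx <- x0:x1
        d2 <- outer((yy - 1 - cy)^2, (xx - 1 - cx)^2, "+")
        disc <- d2 <= r^2
        mar[yy, xx][disc] <- mar[yy, xx][disc] +
          params$autofluorescence_level + amps[i]
        footprint[yy, xx][disc] <- TRUE
        # nucleus blob over a wider window (3 sigma)
        sg <- nuc_r[i] / 2
        w <- ceiling(3 * sg)
        y0 <- max(1, floor(cy + 1 - w)); y1 <- min(shape[1], ceiling(cy + 1 + w))
        x0 <- max(1, floor(cx + 1 - w)); x1 <- min(shape[2], ceiling(cx + 1 + w))
        yy <- y0:y1; xx <- x0:x1
        d2 <- outer((yy - 1 - cy)^2, (xx - 1 - cx)^2, "+")
        nuc[yy, xx] <- nuc[yy, xx] +
          params$nucleus_amplitude * exp(-d2 / (2 * sg^2))
      }
      truth_centers <- data.frame(cell_id = seq_len(n),
                                  y = centers$y, x = centers$x,
                                  radius_px = cell_r,
                                  is_fluorescent = fl)
      true_fraction <- n_fl / n
    } else {
      truth_centers <- data.frame(cell_id = integer(), y = numeric(),
                                  x = numeric(), radius_px = numeric(),
                                  is_fluorescent = logical())
      true_fraction <- 0
    }
    npx <- prod(shape)
    nuc <- pmax(nuc + rnorm(npx, params$background_mean,
                            params$background_sd), 0)
    mar <- pmax(mar + rnorm(npx, params$background_mean,
                            params$background_sd), 0)
    pixels <- array(c(nuc, mar), dim = c(shape, 2))
    image <- multichannel_image(pixels, nucleus_channel = 0,
                                marker_channel = 1, title = title)
    truth <- structure(list(centers = truth_centers,
                            footprint_mask = footprint,
                            true_fraction = true_fraction),
                       class = "ground_truth")
    list(image = image, truth = truth)
  })
}

#' Generate a mixing-series batch of synthetic images
#'
#' One image per fraction and replicate, emulating a cell-mixing validation
#' experiment where two populations (marker-positive and negative) are mixed
#' at known ratios. Seeds are derived deterministically from the base seed
#' (`base$rng_seed + running index`), so the series is reproducible
#' bit-exactly.
#'
#' @param fractions Input fluorescent fractions in `[0, 1]`.
#' @param base A [synth_params()] object used for everything except
#'   `fluorescent_fraction` and `rng_seed`.
#' @param n_replicates Images per fraction.
#' @return A list with one element per image: `list(image, truth,
#'   input_fraction, replicate)`, in fraction-major order.
#' @export
generate_mixing_series <- function(fractions, base = synth_params(),
                                   n_replicates = 3) {
  stopifnot(all(fractions >= 0 & fractions <= 1), n_replicates >= 1)
  out <- vector("list", length(fractions) * n_replicates)
  k <- 0
  for (f in fractions) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1
      p <- base
      p$fluorescent_fraction <- f
      p$rng_seed <- base$rng_seed + (k - 1L)
      title <- sprintf("mix_f%03d_r%d", round(f * 100), r)
      g <- generate_monolayer(p, title = title)
      out[[k]] <- list(image = g$image, truth = g$truth,
                       input_fraction = f, replicate = r)
    }
  }
  out
}

#' Write a synthetic batch to disk
#'
#' For each generated image, writes a two-page 16-bit TIFF (page 1 nucleus,
#' page 2 marker), a ground-truth CSV (`cell_id,y,x,is_fluorescent`) and a
#' JSON file of the generator parameters used.
#'
#' @param series Output of [generate_mixing_series()] (or a list of
#'   `list(image, truth)` entries).
#' @param dir Output directory (created if missing).
#' @param params The base [synth_params()] echoed into the JSON sidecars.
#' @return Invisibly, the vector of TIFF paths written.
#' @export
write_synthetic_batch <- function(series, dir, params = synth_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series))
  for (i in seq_along(series)) {
    entry <- series[[i]]
    stem <- file.path(dir, entry$image$title)
    write_image_tiff(entry$image, paste0(stem, ".tif"))
    tc <- entry$truth$centers
    con <- file(paste0(stem, "_truth.csv"), open = "wb")
    writeLines("cell_id,y,x,is_fluorescent", con, sep = "\n")
    if (nrow(tc) > 0)
      writeLines(paste(tc$cell_id, fmt_num(tc$y), fmt_num(tc$x),
                       fmt_bool(tc$is_fluorescent), sep = ","),
                 con, sep = "\n")
    close(con)
    meta <- unclass(params)
    meta$fluorescent_fraction <- entry$input_fraction %||% meta$fluorescent_fraction
    jsonlite::write_json(meta, paste0(stem, "_params.json"),
                         auto_unbox = TRUE, digits = NA)
    paths[i] <- paste0(stem, ".tif")
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
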