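#' Analyze a single image
#'
#' Runs the full per-image pipeline: foreground mask, nucleus seed
#' detection, seeded watershed, background estimation, per-cell
#' measurement, log10 histogram and population classification. Any stage
#' error is re-signalled with the stage name attached.
#'
#' @param image A [multichannel_image()].
#' @param params An [analysis_params()] object.
#' @return A list with `labels` (label matrix), `cells` (cell table with
#'   `is_fluorescent` filled), `histogram` and `summary`.
#' @export
analyze_image <- function(image, params = analysis_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("foreground_mask", foreground_mask(image, params))
  seeds <- stage("detect_nuclei", detect_nuclei(image, mask, params))
  labels <- stage("segment_cells", segment_cells(image, mask, seeds, params))
  bg <- stage("estimate_background", estimate_background(image, mask))
  cells <- stage("measure_cells", measure_cells(labels, image, bg))
  hist <- stage("log10_histogram", log10_histogram(cells, params))
  cl <- stage("classify_cells",
              classify_cells(cells, hist, params, image_title = image$title))
  list(labels = labels, cells = cl$cells, histogram = hist,
       summary = cl$summary)
}

#' Analyze all images in a folder tree
#'
#' Discovers every file with the given extension in `input_dir` and its
#' subfolders (lexicographic full-path order), analyzes each with
#' [analyze_image()], and writes per image: a segmentation overlay PNG, the
#' histogram as CSV and PNG, and the per-cell CSV, mirroring the subfolder
#' structure under `output_dir`. A single `summary.csv` collects one row per
#' image; a `run_log.txt` records the effective parameters and per-image
#' timing. Per-image failures are logged and skipped, not fatal.
#'
#' @param input_dir Folder with input images.
#' @param output_dir Output folder (created if missing).
#' @param ext Image file extension without the dot (default `"tif"`).
#' @param params An [analysis_params()] object, or `NULL` with
#'   `auto_params = TRUE`.
#' @param nucleus_channel,marker_channel 0-based channel indices.
#' @param auto_params If `TRUE`, estimate parameters per image with
#'   [auto_estimate_params()].
#' @return An object of class `batch_summary`: `rows` (list of image
#'   summaries in analysis order), `params`, `n_images`, `n_failed`,
#'   `failures` (named error notes).
#' @export
analyze_folder <- function(input_dir, output_dir, ext = "tif",
                           params = analysis_params(),
                           nucleus_channel = 0, marker_channel = 1,
                           auto_params = FALSE) {
  if (!dir.exists(input_dir)) stop(sprintf("input folder not found: %s", input_dir))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(input_dir, pattern = paste0("\\.", ext, "$"),
                      recursive = TRUE, full.names = FALSE)
  files <- sort(files, method = "radix")
  if (length(files) == 0)
    warning(sprintf("no .%s files found under %s", ext, input_dir))
  log_lines <- c(sprintf("scfq batch run: %d file(s), ext=.%s", length(files), ext),
                 if (auto_params) "params: auto-estimated per image"
                 else sprintf("params: beta=%g omega=%g alpha=%g bins=%d min_area=%d exclude_border=%s sigma=%g",
                              params$beta, params$omega, params$alpha,
                              params$n_bins, params$min_area_px,
                              params$exclude_border, params$smoothing_sigma))
  rows <- list()
  failures <- character(0)
  for (rel in files) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      image <- read_image(file.path(input_dir, rel), nucleus_channel,
                          marker_channel)
      p <- if (auto_params) auto_estimate_params(image) else params
      out <- analyze_image(image, p)
      subdir <- file.path(output_dir, dirname(rel))
      if (dirname(rel) != ".")
        dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
      stem <- file.path(output_dir,
                        paste0(tools::file_path_sans_ext(rel)))
      write_overlay(image, out$labels, paste0(stem, "_overlay.png"))
      write_histogram_csv(out$histogram, paste0(stem, "_hist.csv"))
      write_histogram_png(out$histogram, out$summary$cutoff_log10,
                          paste0(stem, "_hist.png"), title = image$title)
      write_cell_table(out$cells, paste0(stem, "_cells.csv"))
      out$summary
    }, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[rel] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     sprintf("FAIL %s (%.2fs): %s", rel, dt, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res
      log_lines <- c(log_lines,
                     sprintf("ok   %s (%.2fs): %d cells, %d fluorescent",
                             rel, dt, res$total_cells, res$fluorescent_cells))
    }
  }
  write_summary(rows, file.path(output_dir, "summary.csv"))
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  structure(list(rows = rows, params = if (auto_params) NULL else params,
                 n_images = length(files), n_failed = length(failures),
                 failures = failures),
            class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, ...) {
  cat(sprintf("<batch_summary> %d image(s), %d failed\n",
              x$n_images, x$n_failed))
  invisible(x)
}

#' Validate fraction recovery on a mixing series
#'
#' Ordinary least squares of the recovered fluorescent fraction on the input
#' (ground-truth) fraction; a faithful pipeline gives slope ~1, intercept ~0
#' and a coefficient of determination close to 1.
#'
#' @param input_fractions Ground-truth input fractions (>= 2 distinct
#'   values).
#' @param recovered_fractions Matching pipeline-recovered fractions.
#' @return An object of class `mixing_validation` with `slope`, `intercept`,
#'   `r_squared` and the matched fraction vectors.
#' @export
validate_mixing <- function(input_fractions, recovered_fractions) {
  stopifnot(length(input_fractions) == length(recovered_fractions),
            length(input_fractions) >= 2)
  if (length(unique(input_fractions)) < 2)
    stop("degenerate design: all input fractions identical")
  fit <- lm(recovered_fractions ~ input_fractions)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((recovered_fractions - mean(recovered_fractions))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(input_fractions = input_fractions,
                 recovered_fractions = recovered_fractions,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2),
            class = "mixing_validation")
}

#' @export
print.mixing_validation <- function(x, ...) {
  cat(sprintf("<mixing_validation> slope = %.3f, intercept = %.3f, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, length(x$input_fractions)))
  invisible(x)
}

#' Run the pipeline over a synthetic mixing series
#'
#' Convenience wrapper used for validation and benchmarking: analyzes every
#' image of a [generate_mixing_series()] result in memory and regresses the
#' recovered fluorescent fraction on the ground-truth input fraction.
#'
#' @param series Output of [generate_mixing_series()].
#' @param params An [analysis_params()] object.
#' @return A list with `validation` (a `mixing_validation`) and `summaries`.
#' @export
analyze_mixing_series <- function(series, params = analysis_params()) {
  summaries <- lapply(series, function(entry)
    analyze_image(entry$image, params)$summary)
  truth <- vapply(series, function(e) e$truth$true_fraction, numeric(1))
  recovered <- vapply(summaries, function(s) s$fluorescent_fraction,
                      numeric(1))
  list(validation = validate_mixing(truth, recovered),
       summaries = summaries)
}
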