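#' Multi-channel image container
#'
#' Stores raw pixel intensities of a 2-D multi-channel fluorescence image
#' together with the channel-role assignment. Pixels are kept as a
#' `rows x cols x channels` array of finite, non-negative intensities.
#' Channel indices and all reported coordinates are 0-based, row-major,
#' with `x` = column and `y` = row and pixel centers at integers.
#'
#' @param pixels Numeric array `rows x cols x channels` (a plain matrix is
#'   accepted only as part of a multi-channel stack; at least 2 channels are
#'   required).
#' @param nucleus_channel 0-based index of the nucleus-stain channel.
#' @param marker_channel 0-based index of the fluorescent-marker channel.
#' @param title Image title (source filename without extension).
#' @param pixel_size Optional physical pixel size in micrometres per pixel
#'   (metadata only; no computation uses it).
#' @return An object of class `mcimage`.
#' @export
multichannel_image <- function(pixels, nucleus_channel = 0, marker_channel = 1,
                               title = "", pixel_size = NULL) {
  if (length(dim(pixels)) != 3)
    stop("`pixels` must be a rows x cols x channels array")
  nch <- dim(pixels)[3]
  if (nch < 2) stop("at least 2 channels are required")
  for (idx in c(nucleus_channel, marker_channel))
    if (idx < 0 || idx >= nch)
      stop(sprintf("channel index %d out of range (image has %d channels)",
                   idx, nch))
  if (nucleus_channel == marker_channel)
    stop("nucleus_channel and marker_channel must differ")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and >= 0")
  structure(list(pixels = pixels,
                 nucleus_channel = as.integer(nucleus_channel),
                 marker_channel = as.integer(marker_channel),
                 title = title, pixel_size = pixel_size),
            class = "mcimage")
}

#' @export
print.mcimage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mcimage> '%s': %d x %d px, %d channel(s), nucleus=%d marker=%d\n",
              x$title, d[1], d[2], d[3], x$nucleus_channel, x$marker_channel))
  invisible(x)
}

nucleus_matrix <- function(image) image$pixels[, , image$nucleus_channel + 1L]
marker_matrix <- function(image) image$pixels[, , image$marker_channel + 1L]

#' Read a multi-channel raster image
#'
#' Reads a multi-page TIFF (one page per channel; a single page with an extra
#' sample dimension is also accepted) or a PNG with >= 2 channels. Additional
#' channels beyond the nucleus and marker assignment are retained but ignored
#' by the analysis.
#'
#' @param path Path to the image file.
#' @param nucleus_channel,marker_channel 0-based channel indices.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, nucleus_channel = 0, marker_channel = 1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop(sprintf("not a readable TIFF: %s (%s)",
                                     path, conditionMessage(e))))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) > 1) {
      chans <- lapply(pages, function(p) {
        if (length(dim(p)) == 3) p[, , 1] else p
      })
      arr <- array(unlist(chans), dim = c(dim(chans[[1]]), length(chans)))
    } else {
      p <- pages[[1]]
      arr <- if (length(dim(p)) == 3) p else array(p, dim = c(dim(p), 1))
    }
  } else if (ext == "png") {
    p <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop(sprintf("not a readable PNG: %s", path)))
    arr <- if (length(dim(p)) == 3) p else array(p, dim = c(dim(p), 1))
  } else {
    stop(sprintf("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  }
  nch <- dim(arr)[3]
  need <- max(nucleus_channel, marker_channel) + 1
  if (nch < need)
    stop(sprintf("channel index error: image '%s' has %d channel(s), need %d",
                 basename(path), nch, need))
  if (nch < 2)
    stop(sprintf("image '%s' has a single channel; two are required",
                 basename(path)))
  multichannel_image(arr * 1.0, nucleus_channel, marker_channel,
                     title = tools::file_path_sans_ext(basename(path)))
}

#' Write a two-channel image as a 16-bit multi-page TIFF
#'
#' One page per channel, uncompressed, values clamped to \[0, 65535\] and
#' rounded to integers by the 16-bit encoding. Integer-valued inputs round-trip
#' exactly through [read_image()].
#'
#' @param image A [multichannel_image()].
#' @param path Output path.
#' @export
write_image_tiff <- function(image, path) {
  pages <- lapply(seq_len(dim(image$pixels)[3]), function(k) {
    pmin(pmax(image$pixels[, , k], 0), 65535) / 65535
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                 compression = "none"),
                 error = function(e)
                   stop(sprintf("cannot write TIFF '%s': %s", path,
                                conditionMessage(e))))
  invisible(ok)
}

# Label-map contour pixels: a labelled pixel is a contour pixel when one of
# its 4-neighbours (outside the image counts as background) carries a
# strictly smaller label. This yields a 1-px contour on the inner boundary
# ring against background and a single-sided 1-px line between touching
# regions.
label_contours <- function(labels) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  nmin <- pmin(pad[1:nr, 2:(nc + 1)], pad[3:(nr + 2), 2:(nc + 1)],
               pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)])
  ctr > 0 & nmin < ctr
}

#' Write a segmentation overlay PNG
#'
#' Renders a two-colour composite (marker channel in green, nucleus channel in
#' blue, each normalized by its 99.5th percentile) and draws 1-px-wide pure red
#' contours at every boundary between distinct labels or label/background.
#'
#' @param image A [multichannel_image()].
#' @param labels Integer label matrix of the same size (0 = background).
#' @param path Output PNG path.
#' @export
write_overlay <- function(image, labels, path) {
  if (!all(dim(labels) == dim(image$pixels)[1:2]))
    stop("label map dimensions do not match the image")
  norm01 <- function(ch) {
    q <- quantile(ch, 0.995, names = FALSE)
    if (q <= 0) q <- max(ch, 1)
    pmin(ch / q, 1)
  }
  g <- norm01(marker_matrix(image))
  b <- norm01(nucleus_matrix(image))
  rgb <- array(0, dim = c(dim(labels), 3))
  rgb[, , 2] <- g
  rgb[, , 3] <- b
  ctr <- label_contours(labels)
  r1 <- rgb[, , 1]; g1 <- rgb[, , 2]; b1 <- rgb[, , 3]
  r1[ctr] <- 1; g1[ctr] <- 0; b1[ctr] <- 0
  rgb[, , 1] <- r1; rgb[, , 2] <- g1; rgb[, , 3] <- b1
  tryCatch(png::writePNG(rgb, path),
           error = function(e)
             stop(sprintf("cannot write PNG '%s': %s", path,
                          conditionMessage(e))))
  invisible(NULL)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  out
}
fmt_bool <- function(x) ifelse(x, "true", "false")

#' Write the per-cell data table
#'
#' CSV with the fixed header
#' `cell_id,x,y,area_px,perimeter_px,circularity,mean_raw,mean_corrected,log10_intensity,is_fluorescent,touches_border`,
#' one row per cell in ascending `cell_id` order. Cells with non-positive
#' corrected intensity have an empty `log10_intensity` field.
#'
#' @param cells Cell table as returned by [measure_cells()] /
#'   [classify_cells()].
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  header <- "cell_id,x,y,area_px,perimeter_px,circularity,mean_raw,mean_corrected,log10_intensity,is_fluorescent,touches_border"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (nrow(cells) > 0) {
    o <- order(cells$cell_id)
    cells <- cells[o, , drop = FALSE]
    lines <- paste(cells$cell_id, fmt_num(cells$x), fmt_num(cells$y),
                   cells$area_px, fmt_num(cells$perimeter_px),
                   fmt_num(cells$circularity), fmt_num(cells$mean_raw),
                   fmt_num(cells$mean_corrected),
                   fmt_num(cells$log10_intensity),
                   fmt_bool(cells$is_fluorescent),
                   fmt_bool(cells$touches_border), sep = ",")
    writeLines(lines, con, sep = "\n")
  }
  invisible(NULL)
}

#' Write the batch summary table
#'
#' CSV with the fixed header
#' `image_title,total_cells,fluorescent_cells,fluorescent_fraction`,
#' one row per analyzed image in analysis order.
#'
#' @param summaries A list of image summaries (see [classify_cells()]) or a
#'   single summary.
#' @param path Output CSV path.
#' @export
write_summary <- function(summaries, path) {
  if (!is.null(summaries$image_title)) summaries <- list(summaries)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("image_title,total_cells,fluorescent_cells,fluorescent_fraction",
             con, sep = "\n")
  for (s in summaries) {
    writeLines(paste(s$image_title, s$total_cells, s$fluorescent_cells,
                     fmt_num(s$fluorescent_fraction), sep = ","),
               con, sep = "\n")
  }
  invisible(NULL)
}

#' Write a log10 intensity histogram as CSV
#'
#' Columns `bin_left,bin_right,count` in log10-intensity units.
#'
#' @param hist A [log10_histogram()] object.
#' @param path Output CSV path.
#' @export
write_histogram_csv <- function(hist, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("bin_left,bin_right,count", con, sep = "\n")
  nb <- length(hist$counts)
  if (nb > 0) {
    writeLines(paste(fmt_num(hist$bin_edges[seq_len(nb)]),
                     fmt_num(hist$bin_edges[seq_len(nb) + 1]),
                     hist$counts, sep = ","),
               con, sep = "\n")
  }
  invisible(NULL)
}

#' Plot a log10 intensity histogram to PNG
#'
#' Bars at or above the classification cutoff (the fluorescent population) are
#' drawn in red, the non-fluorescent population in gray.
#'
#' @param hist A [log10_histogram()] object.
#' @param cutoff_log10 Applied log10 cutoff (vertical dashed line); may be
#'   `NA` to draw all bars gray.
#' @param path Output PNG path.
#' @param title Plot title.
#' @export
write_histogram_png <- function(hist, cutoff_log10, path, title = "") {
  png(path, width = 640, height = 480)
  on.exit(dev.off())
  nb <- length(hist$counts)
  if (nb == 0) {
    barplot(0, names.arg = "", ylab = "cells", main = title)
    return(invisible(NULL))
  }
  centers <- (hist$bin_edges[-1] + hist$bin_edges[-(nb + 1)]) / 2
  cols <- rep("gray60", nb)
  if (!is.na(cutoff_log10)) cols[centers >= cutoff_log10] <- "red3"
  barplot(hist$counts, names.arg = sprintf("%.2f", centers), col = cols,
          border = NA, las = 2, cex.names = 0.6,
          xlab = "log10 corrected mean intensity", ylab = "cells",
          main = title)
  invisible(NULL)
}
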