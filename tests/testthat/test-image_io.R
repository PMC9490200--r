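test_that("TIFF write/read round trip preserves integer pixel values", {
  set.seed(1)
  nuc <- matrix(sample.int(65535, 64 * 64, replace = TRUE) - 1L, 64, 64)
  mar <- matrix(sample.int(65535, 64 * 64, replace = TRUE) - 1L, 64, 64)
  img <- make_image(nuc * 1.0, mar * 1.0, title = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_image(path, 0, 1)
  expect_equal(back$pixels[, , 1], nuc, ignore_attr = TRUE)
  expect_equal(back$pixels[, , 2], mar, ignore_attr = TRUE)
  expect_identical(back$title, tools::file_path_sans_ext(basename(path)))
})

test_that("extra channels are retained but ignored by the analysis", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- list(matrix(0.1, 32, 32), matrix(0.2, 32, 32), matrix(0.9, 32, 32))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  img <- read_image(path, nucleus_channel = 0, marker_channel = 1)
  expect_equal(dim(img$pixels)[3], 3)
  res <- suppressWarnings(analyze_image(img, analysis_params()))
  expect_s3_class(res$summary, "image_summary")
  # same result as the two-channel version: channel 3 plays no role
  img2 <- make_image(img$pixels[, , 1], img$pixels[, , 2])
  res2 <- suppressWarnings(analyze_image(img2, analysis_params()))
  expect_equal(res$summary$total_cells, res2$summary$total_cells)
})

test_that("channel-index and missing-file errors are raised", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 16, 16), path, bits.per.sample = 16L)
  expect_error(read_image(path, 0, 1), "channel")
  expect_error(read_image(file.path(tempdir(), "nope_missing.tif")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not a tiff", bad)
  expect_error(read_image(bad), "TIFF")
})

test_that("overlay has red contours exactly on label boundaries", {
  nuc <- matrix(0, 20, 20)
  img <- make_image(nuc, nuc)
  labels <- matrix(0L, 20, 20)

  # no cells: overlay is the plain composite, no red pixel
  p0 <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, labels, p0)
  rgb <- png::readPNG(p0)
  expect_false(any(rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0 &
                     rgb[, , 1] > rgb[, , 2]))

  # one square: the 1-px inner boundary ring, enumerated
  labels[6:10, 6:10] <- 1L
  p1 <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, labels, p1)
  rgb <- png::readPNG(p1)
  red <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  ring <- matrix(FALSE, 20, 20)
  ring[6:10, 6:10] <- TRUE
  ring[7:9, 7:9] <- FALSE
  expect_identical(red, ring)

  # two touching labels: a 1-px contour runs along the shared edge
  labels <- matrix(0L, 20, 20)
  labels[6:10, 6:10] <- 1L
  labels[6:10, 11:15] <- 2L
  p2 <- withr::local_tempfile(fileext = ".png")
  write_overlay(img, labels, p2)
  rgb <- png::readPNG(p2)
  red <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  expect_true(all(red[6:10, 11]))   # label 2 side of the shared edge
  expect_true(all(red[6:10, 6]))    # outer ring still present
})

test_that("cell table and summary CSVs have the fixed headers and row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- cells_at(numeric(0))
  write_cell_table(empty, path)
  lines <- readLines(path)
  expect_identical(lines,
    "cell_id,x,y,area_px,perimeter_px,circularity,mean_raw,mean_corrected,log10_intensity,is_fluorescent,touches_border")

  cells <- cells_at(c(2, 3, 1))
  write_cell_table(cells, path)
  lines <- readLines(path)
  expect_length(lines, 4)
  expect_identical(substr(lines[2:4], 1, 2), c("1,", "2,", "3,"))

  # sentinel: non-positive corrected intensity -> empty log10 field
  cells$mean_corrected[2] <- 0
  cells$log10_intensity[2] <- NA
  write_cell_table(cells, path)
  expect_match(readLines(path)[3], ",,false,false$")

  spath <- withr::local_tempfile(fileext = ".csv")
  s <- list(image_title = "img_a", total_cells = 100L,
            fluorescent_cells = 40L, fluorescent_fraction = 0.4,
            cutoff_log10 = 2, params_used = analysis_params())
  class(s) <- "image_summary"
  write_summary(list(s), spath)
  expect_identical(readLines(spath),
    c("image_title,total_cells,fluorescent_cells,fluorescent_fraction",
      "img_a,100,40,0.4"))
})

test_that("histogram CSV export matches the histogram object", {
  cells <- cells_at(c(1, 1.5, 2, 2.5, 3))
  h <- log10_histogram(cells, analysis_params(n_bins = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  d <- read.csv(path)
  expect_identical(names(d), c("bin_left", "bin_right", "count"))
  expect_equal(sum(d$count), 5)
  expect_equal(d$bin_left, h$bin_edges[1:8])
})
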