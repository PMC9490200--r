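test_that("background estimate is the median outside the mask", {
  mar <- matrix(10, 32, 32)
  img <- make_image(matrix(0, 32, 32), mar)
  mask <- matrix(FALSE, 32, 32)
  mask[10:20, 10:20] <- TRUE
  expect_equal(estimate_background(img, mask), 10)

  # noisy background: agrees with an independently computed sample median
  set.seed(42)
  noise <- matrix(5 + rnorm(32 * 32), 32, 32)
  img2 <- make_image(matrix(0, 32, 32), noise)
  expect_equal(estimate_background(img2, mask), median(noise[!mask]))
  expect_lt(abs(estimate_background(img2, mask) - 5), 0.3)

  # all-true mask: fallback percentile with a warning
  img3 <- const_image(7)
  expect_warning(bg <- estimate_background(img3, matrix(TRUE, 32, 32)),
                 "whole image")
  expect_equal(bg, 7)
})

test_that("per-cell measurements are exact on a square region", {
  labels <- matrix(0L, 40, 40)
  labels[11:20, 16:25] <- 1L
  mar <- matrix(2, 40, 40)
  mar[labels == 1L] <- 50
  img <- make_image(matrix(0, 40, 40), mar)
  cells <- measure_cells(labels, img, background = 10)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$area_px, 100L)
  expect_equal(cells$mean_raw, 50)
  expect_equal(cells$mean_corrected, 40)
  expect_equal(cells$log10_intensity, log10(40))
  # centroid, 0-based: rows 11:20 -> y 14.5, cols 16:25 -> x 19.5
  expect_equal(cells$y, 14.5)
  expect_equal(cells$x, 19.5)
  expect_false(cells$touches_border)
})

test_that("circularity behaves like 4*pi*A/P^2 on discs and lines", {
  disc_labels <- function(r, pad = 5) {
    n <- 2 * (r + pad) + 1
    d2 <- outer((seq_len(n) - r - pad - 1)^2, (seq_len(n) - r - pad - 1)^2, "+")
    matrix(as.integer(d2 <= r^2), n, n)
  }
  img_for <- function(labels) {
    m <- matrix(0, nrow(labels), ncol(labels))
    make_image(m, m + 100)
  }
  circ <- vapply(c(5, 10, 20, 40), function(r) {
    l <- disc_labels(r)
    measure_cells(l, img_for(l), 0)$circularity
  }, numeric(1))
  expect_gte(circ[3], 0.95)                     # disc of radius 20
  expect_gte(circ[4], circ[1] - 0.02)           # converging toward 1
  expect_gte(min(circ), 0.85)  # radius-5 rasterization is the crudest

  line <- matrix(0L, 10, 40)
  line[5, 6:35] <- 1L
  lc <- measure_cells(line, img_for(line), 0)
  expect_lt(lc$circularity, 0.3)
  expect_equal(lc$area_px, 30L)
})

test_that("background subtraction floors at zero and never exceeds raw", {
  labels <- matrix(0L, 20, 20)
  labels[5:10, 5:10] <- 1L
  labels[12:17, 12:17] <- 2L
  mar <- matrix(0, 20, 20)
  mar[labels == 1L] <- 3    # below background
  mar[labels == 2L] <- 50
  img <- make_image(matrix(0, 20, 20), mar)
  cells <- measure_cells(labels, img, background = 10)
  expect_equal(cells$mean_corrected, c(0, 40))
  expect_true(all(cells$mean_corrected <= cells$mean_raw))
  expect_true(is.na(cells$log10_intensity[1]))
})

test_that("measurements are invariant under label permutation", {
  g <- generate_monolayer(small_synth(rng_seed = 9))
  res <- analyze_image(g$image)
  labels <- res$labels
  n <- max(labels)
  set.seed(1)
  perm <- sample.int(n)
  relabeled <- matrix(c(0L, perm)[labels + 1L], nrow(labels), ncol(labels))
  bg <- estimate_background(g$image, labels > 0)
  a <- measure_cells(labels, g$image, bg)
  b <- measure_cells(relabeled, g$image, bg)
  keys <- c("area_px", "mean_raw", "x", "y", "perimeter_px")
  ord <- function(d) d[do.call(order, d[keys]), keys]
  expect_equal(ord(a), ord(b), ignore_attr = TRUE)
})

test_that("log10 histogram bins, conserves counts and flags exclusions", {
  h1 <- log10_histogram(cells_at(rep(2, 5)), analysis_params())
  expect_equal(sum(h1$counts), 5)
  expect_equal(sum(h1$counts > 0), 1)            # one occupied unit-width bin
  expect_equal(mean(h1$bin_edges), 2)

  set.seed(11)
  cells <- cells_at(rnorm(200, 2, 0.5))
  cells$mean_corrected[1:7] <- 0
  cells$log10_intensity[1:7] <- NA
  h2 <- log10_histogram(cells, analysis_params(n_bins = 32))
  expect_equal(sum(h2$counts) + h2$n_excluded, nrow(cells))
  expect_equal(h2$n_excluded, 7L)
  expect_length(h2$bin_edges, 33)

  h0 <- log10_histogram(cells_at(numeric(0)), analysis_params())
  expect_equal(sum(h0$counts), 0)
  expect_equal(h0$n_excluded, 0L)
})

test_that("a bimodal intensity mixture yields two separated histogram modes", {
  set.seed(5)
  cells <- cells_at(c(rnorm(100, 2, 0.2), rnorm(100, 3.5, 0.2)))
  h <- log10_histogram(cells, analysis_params(n_bins = 40))
  s <- stats::filter(h$counts, rep(1 / 3, 3))
  s[is.na(s)] <- 0
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  peaks <- which(s > c(-Inf, s[-length(s)]) & s >= c(s[-1], -Inf))
  tall <- peaks[s[peaks] >= 0.25 * max(s)]
  expect_gte(length(tall), 2)
  expect_gte(max(centers[tall]) - min(centers[tall]), 1)
})
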