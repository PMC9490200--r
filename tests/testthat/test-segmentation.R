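test_that("foreground mask handles constant images at the threshold", {
  p <- analysis_params(beta = 15)
  expect_false(any(foreground_mask(const_image(0), p)))
  expect_true(all(foreground_mask(const_image(100), p)))
})

test_that("foreground mask matches the generator footprint (IoU >= 0.9)", {
  g <- generate_monolayer(synth_params(fluorescent_fraction = 0,
                                       background_sd = 0, rng_seed = 3))
  p <- analysis_params(beta = 15, smoothing_sigma = 0.5)
  mask <- foreground_mask(g$image, p)
  truth <- g$truth$footprint_mask
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.9)
})

test_that("nucleus seed detection finds isolated Gaussian blobs", {
  p <- analysis_params(omega = 5, smoothing_sigma = 2)
  flat <- const_image(10, 64, 64)
  mask <- matrix(TRUE, 64, 64)
  expect_equal(nrow(detect_nuclei(flat, mask, p)), 0)

  blob <- function(cy, cx, nr = 64, nc = 64, amp = 500, sg = 2.5) {
    amp * exp(-(outer((0:(nr - 1) - cy)^2, (0:(nc - 1) - cx)^2, "+")) /
                (2 * sg^2))
  }
  img1 <- make_image(blob(32, 32), matrix(0, 64, 64))
  s1 <- detect_nuclei(img1, mask, p)
  expect_equal(nrow(s1), 1)
  expect_lte(sqrt((s1$y - 32)^2 + (s1$x - 32)^2), 1)

  img2 <- make_image(blob(32, 17) + blob(32, 47), matrix(0, 64, 64))
  s2 <- detect_nuclei(img2, mask, p)
  expect_equal(nrow(s2), 2)
  expect_lte(min(abs(s2$x - 17)), 1)
  expect_lte(min(abs(s2$x - 47)), 1)
})

test_that("seed detection respects the prominence threshold omega", {
  # a major and a minor bump on a flat pedestal; after sigma = 2 smoothing
  # the minor bump's prominence is ~12, between the two omega settings
  bump <- function(cy, cx, amp, sg = 2.5) {
    amp * exp(-(outer((0:63 - cy)^2, (0:63 - cx)^2, "+")) / (2 * sg^2))
  }
  nuc2 <- 50 + bump(32, 32, 500) + bump(32, 50, 20)
  img <- make_image(nuc2, matrix(0, 64, 64))
  mask <- matrix(TRUE, 64, 64)
  n_lo <- nrow(detect_nuclei(img, mask, analysis_params(omega = 5)))
  n_hi <- nrow(detect_nuclei(img, mask, analysis_params(omega = 50)))
  expect_equal(n_lo, 2)
  expect_equal(n_hi, 1)
})

test_that("watershed on constant elevation splits at the bisector", {
  img <- const_image(10, 64, 64)
  mask <- matrix(TRUE, 64, 64)
  p <- analysis_params(min_area_px = 1)

  seeds <- data.frame(y = c(32, 32), x = c(20, 44))
  labels <- segment_cells(img, mask, seeds, p)
  expect_setequal(unique(as.vector(labels)), c(1L, 2L))
  # boundary within 1 px of the perpendicular bisector column x = 32
  for (row in c(1, 16, 32, 48, 64)) {
    run <- labels[row, ]
    flip <- which(diff(run) != 0)
    expect_length(flip, 1)
    expect_lte(abs((flip[1] - 1) + 0.5 - 32), 1)  # 0-based boundary position
  }

  # one seed: entire connected mask component labeled
  one <- segment_cells(img, mask, data.frame(y = 10, x = 10), p)
  expect_true(all(one == 1L))

  # empty seed set: all zeros, not an error
  zero <- segment_cells(img, mask, data.frame(y = numeric(), x = numeric()), p)
  expect_true(all(zero == 0L))
})

test_that("watershed equals brute-force nearest-seed on constant elevation", {
  # property suite over random two-seed and five-seed convex-mask instances
  set.seed(7)
  p <- analysis_params(min_area_px = 1)
  for (iter in 1:22) {
    nr <- sample(40:64, 1)
    nc <- sample(40:64, 1)
    img <- const_image(10, nr, nc)
    mask <- matrix(FALSE, nr, nc)
    r0 <- sort(sample(seq_len(nr), 2))
    c0 <- sort(sample(seq_len(nc), 2))
    if (diff(r0) < 10) r0 <- c(1, nr)
    if (diff(c0) < 10) c0 <- c(1, nc)
    mask[r0[1]:r0[2], c0[1]:c0[2]] <- TRUE
    ns <- if (iter %% 2 == 0) 5 else 2
    repeat {
      sy <- sample(r0[1]:r0[2], ns, replace = TRUE) - 1
      sx <- sample(c0[1]:c0[2], ns, replace = TRUE) - 1
      if (nrow(unique(cbind(sy, sx))) == ns) break
    }
    seeds <- data.frame(y = sy, x = sx)
    labels <- segment_cells(img, mask, seeds, p)
    oracle <- nearest_seed_oracle(mask, seeds)
    mismatch <- labels[oracle$idx] != oracle$labels[oracle$idx]
    # disagreements may only occur within 1 px of a bisector
    expect_true(all(oracle$margin[mismatch] <= 2))
    # near-bisector bands can hold a sizeable pixel share in small masks
    expect_lte(mean(mismatch), 0.15)
  }
})

test_that("label maps satisfy the partition invariants", {
  g <- generate_monolayer(small_synth(rng_seed = 5))
  p <- analysis_params()
  mask <- foreground_mask(g$image, p)
  seeds <- detect_nuclei(g$image, mask, p)
  labels <- segment_cells(g$image, mask, seeds, p)
  n <- max(labels)
  expect_true(all(sort(unique(as.vector(labels))) == 0:n))
  expect_true(all(mask[labels > 0]))          # labeled pixels inside the mask
  expect_lte(n, nrow(seeds))                  # count conservation
  expect_true(all(tabulate(labels[labels > 0], n) >= p$min_area_px))
})

test_that("seeds outside the mask are dropped with a warning", {
  img <- const_image(10, 32, 32)
  mask <- matrix(FALSE, 32, 32)
  mask[10:20, 10:20] <- TRUE
  seeds <- data.frame(y = c(15, 2), x = c(15, 2))
  expect_warning(labels <- segment_cells(img, mask, seeds,
                                         analysis_params(min_area_px = 1)),
                 "dropped")
  expect_equal(max(labels), 1L)
})

test_that("exclude_border removes edge-touching regions", {
  img <- const_image(10, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  seeds <- data.frame(y = c(5, 20), x = c(5, 20))
  p_keep <- analysis_params(min_area_px = 1, exclude_border = FALSE)
  p_drop <- analysis_params(min_area_px = 1, exclude_border = TRUE)
  expect_equal(max(segment_cells(img, mask, seeds, p_keep)), 2L)
  # full-frame mask: every watershed region touches the border
  expect_equal(max(segment_cells(img, mask, seeds, p_drop)), 0L)
})
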