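# Shared fixtures, all built in code.

# Small, fast generator settings for unit tests.
small_synth <- function(n_cells = 25, ...) {
  synth_params(shape = c(192, 192), n_cells = n_cells, ...)
}

# Two-channel image from explicit matrices.
make_image <- function(nuc, mar, title = "fixture") {
  multichannel_image(array(c(nuc, mar), dim = c(dim(nuc), 2)),
                     nucleus_channel = 0, marker_channel = 1, title = title)
}

# Constant-intensity two-channel image.
const_image <- function(value, nr = 32, nc = 32) {
  m <- matrix(value, nr, nc)
  make_image(m, m)
}

# Cell table with prescribed log10 intensities (geometry fields are
# placeholders; classification only reads log10_intensity).
cells_at <- function(log10_values) {
  v <- log10_values
  n <- length(v)
  data.frame(cell_id = seq_len(n), x = numeric(n), y = numeric(n),
             area_px = rep(50L, n), perimeter_px = rep(25, n),
             circularity = rep(1, n),
             mean_raw = 10^v + 5, mean_corrected = 10^v,
             log10_intensity = v, is_fluorescent = rep(FALSE, n),
             touches_border = rep(FALSE, n))
}

# Brute-force Euclidean nearest-seed assignment over a mask (0-based seeds);
# also returns the margin between the two smallest seed distances, used to
# identify near-bisector pixels.
nearest_seed_oracle <- function(mask, seeds) {
  idx <- which(mask)
  rows <- ((idx - 1) %% nrow(mask))
  cols <- ((idx - 1) %/% nrow(mask))
  d <- sapply(seq_len(nrow(seeds)), function(i)
    sqrt((rows - seeds$y[i])^2 + (cols - seeds$x[i])^2))
  d <- matrix(d, ncol = nrow(seeds))
  assign <- max.col(-d, ties.method = "first")
  sorted <- t(apply(d, 1, sort))
  margin <- if (ncol(d) > 1) sorted[, 2] - sorted[, 1] else rep(Inf, nrow(d))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[idx] <- assign
  list(labels = labels, idx = idx, margin = margin)
}
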