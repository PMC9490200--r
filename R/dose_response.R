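#' Langmuir-type inhibition model
#'
#' Fraction of infected cells at inhibitor concentration `c_inh` under the
#' one-parameter Langmuir-type model `f_inf = 1 / (1 + c_inh / ic50)`:
#' full infection at zero inhibitor, half-maximal inhibition exactly at
#' `c_inh = ic50`.
#'
#' @param c_inh Inhibitor concentration(s), `>= 0`.
#' @param ic50 Half-maximal inhibitory concentration, `> 0` (same units).
#' @return Infected fraction(s) in `(0, 1]`.
#' @export
#' @examples
#' langmuir_f(0, 10)    # 1
#' langmuir_f(10, 10)   # 0.5
langmuir_f <- function(c_inh, ic50) {
  if (!is.numeric(ic50) || length(ic50) != 1 || ic50 <= 0)
    stop("ic50 must be a single positive number")
  if (any(c_inh < 0)) stop("c_inh must be >= 0")
  1 / (1 + c_inh / ic50)
}

#' Construct an inhibition dataset
#'
#' @param concentrations Inhibitor concentrations (zero allowed for untreated
#'   controls).
#' @param fractions Matching infected fractions in `[0, 1]`.
#' @param replicate_sd Optional per-point standard deviations (used as
#'   inverse-variance weights in the fit).
#' @return A data frame of class `inhibition_dataset`.
#' @export
inhibition_dataset <- function(concentrations, fractions, replicate_sd = NULL) {
  stopifnot(length(concentrations) == length(fractions),
            length(fractions) >= 3,
            all(concentrations >= 0),
            all(fractions >= 0 & fractions <= 1))
  out <- data.frame(concentration = as.numeric(concentrations),
                    fraction = as.numeric(fractions))
  if (!is.null(replicate_sd)) {
    stopifnot(length(replicate_sd) == length(fractions), all(replicate_sd > 0))
    out$sd <- as.numeric(replicate_sd)
  }
  class(out) <- c("inhibition_dataset", "data.frame")
  out
}

#' Read an inhibition dataset from CSV
#'
#' Expects columns `concentration,fraction` and optionally `sd`.
#'
#' @param path CSV path.
#' @return An [inhibition_dataset()].
#' @export
read_inhibition_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("concentration", "fraction") %in% names(d)))
    stop("CSV must have columns concentration,fraction[,sd]")
  inhibition_dataset(d$concentration, d$fraction,
                     if ("sd" %in% names(d)) d$sd else NULL)
}

# Weighted RSS of the Langmuir model at theta = log10(ic50); zero
# concentrations contribute their (constant) residual against f = 1.
langmuir_rss <- function(theta, conc, frac, w) {
  pred <- 1 / (1 + conc * 10^(-theta))
  sum(w * (frac - pred)^2)
}

fit_theta <- function(conc, frac, w) {
  pos <- conc[conc > 0]
  lo <- log10(min(pos)) - 3
  hi <- log10(max(pos)) + 3
  grid <- seq(lo, hi, length.out = 60)
  rss <- vapply(grid, langmuir_rss, numeric(1), conc = conc, frac = frac, w = w)
  k <- which.min(rss)
  step <- grid[2] - grid[1]
  optimize(langmuir_rss,
           interval = c(grid[k] - step, grid[k] + step),
           conc = conc, frac = frac, w = w, tol = 1e-12)$minimum
}

#' Fit IC50 to an inhibition curve
#'
#' Nonlinear least squares of the one-parameter Langmuir-type model,
#' parameterized by `log10(IC50)` because concentrations typically span
#' several decades (top fixed at 1, bottom at 0, Hill slope 1; no
#' extensions). Zero-concentration points act as fixed `f = 1` anchors. The
#' 95% confidence interval is a case-resampling percentile bootstrap; the
#' interval is widened, if necessary, to contain the point estimate so that
#' `ci_low <= ic50 <= ci_high` always holds.
#'
#' @param data An [inhibition_dataset()] (or data frame with columns
#'   `concentration`, `fraction` and optionally `sd`).
#' @param ci_method Only `"bootstrap"` is implemented.
#' @param n_boot Number of bootstrap replicates.
#' @param rng_seed Seed for the bootstrap resampling (mandatory for
#'   reproducibility).
#' @return An object of class `dose_response_fit` with fields `ic50`,
#'   `ic50_ci` (`c(low, high)`), `residual_sum_squares`, `n_points`.
#' @export
fit_ic50 <- function(data, ci_method = "bootstrap", n_boot = 1000,
                     rng_seed = 1) {
  ci_method <- match.arg(ci_method, "bootstrap")
  conc <- data$concentration
  frac <- data$fraction
  if (length(conc) < 3) stop("at least 3 points are required")
  if (!any(conc > 0)) stop("fit failure: no positive concentrations")
  if (length(unique(frac)) == 1)
    stop("fit failure: degenerate data (all fractions equal)")
  w <- if (!is.null(data$sd)) 1 / data$sd^2 else rep(1, length(conc))
  if (!any(frac > 0.6) || !any(frac < 0.4))
    warning("data do not span both sides of the transition (recommended: at least one f > 0.6 and one f < 0.4)")
  theta <- fit_theta(conc, frac, w)
  rss <- langmuir_rss(theta, conc, frac, w)
  ic50 <- 10^theta

  boots <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(rng_seed)
    n <- length(conc)
    for (b in seq_len(n_boot)) {
      for (try in 1:20) {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(conc[idx] > 0) && length(unique(frac[idx])) > 1) break
      }
      if (!any(conc[idx] > 0) || length(unique(frac[idx])) == 1) next
      boots[b] <- 10^fit_theta(conc[idx], frac[idx], w[idx])
    }
  }
  bok <- boots[!is.na(boots)]
  ci <- if (length(bok) >= 10) {
    # order-statistic percentile convention (Efron), quantile type 6
    q <- quantile(bok, c(0.025, 0.975), names = FALSE, type = 6)
    c(min(q[1], ic50), max(q[2], ic50))
  } else c(NA_real_, NA_real_)

  structure(list(ic50 = ic50, ic50_ci = ci, residual_sum_squares = rss,
                 n_points = length(conc)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> IC50 = %.4g (95%% CI %.4g - %.4g), RSS = %.4g, n = %d\n",
              x$ic50, x$ic50_ci[1], x$ic50_ci[2],
              x$residual_sum_squares, x$n_points))
  invisible(x)
}

#' Plot a fitted inhibition curve to PNG
#'
#' @param data The [inhibition_dataset()] used for the fit.
#' @param fit The [fit_ic50()] result.
#' @param path Output PNG path.
#' @export
write_fit_png <- function(data, fit, path) {
  png(path, width = 640, height = 480)
  on.exit(dev.off())
  pos <- data$concentration > 0
  xr <- range(data$concentration[pos])
  cs <- 10^seq(log10(xr[1]) - 1, log10(xr[2]) + 1, length.out = 200)
  plot(data$concentration[pos], data$fraction[pos], log = "x",
       xlab = "inhibitor concentration", ylab = "infected fraction",
       ylim = c(0, 1), pch = 19)
  lines(cs, langmuir_f(cs, fit$ic50), col = "red3", lwd = 2)
  abline(v = fit$ic50, lty = 2, col = "gray40")
  legend("topright", bty = "n",
         legend = sprintf("IC50 = %.3g [%.3g, %.3g]",
                          fit$ic50, fit$ic50_ci[1], fit$ic50_ci[2]))
  invisible(NULL)
}
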