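#' Noise threshold from normal noise-peak parameters
#'
#' The low-expression peak of a one-color intensity distribution is
#' technical noise, well approximated by a normal distribution; values more
#' than `k` standard deviations above its mean are called expressed.
#'
#' @param mu Noise-peak mean (intensity units).
#' @param sigma Noise-peak standard deviation; must be positive.
#' @param k SD multiplier (default 3).
#' @return `mu + k * sigma`.
#' @export
noise_threshold <- function(mu, sigma, k = 3) {
  stopifnot(is.numeric(mu), is.numeric(sigma), sigma > 0, k > 0)
  mu + k * sigma
}

#' Construct a noise model
#'
#' @param mu,sigma Normal parameters of the low-expression noise peak.
#' @param k SD multiplier used for the threshold.
#' @return Object of class `noise_model` with `mu`, `sigma`, `k`,
#'   `threshold = mu + k * sigma` and `tail_prob`, the one-sided normal
#'   tail probability above the threshold (about 0.00135 for `k = 3`).
#' @export
noise_model <- function(mu, sigma, k = 3) {
  structure(list(mu = mu, sigma = sigma, k = k,
                 threshold = noise_threshold(mu, sigma, k),
                 tail_prob = stats::pnorm(k, lower.tail = FALSE)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf(
    "<noise_model> mu=%.4g sigma=%.4g k=%g -> threshold %.4g (tail p=%.2g)\n",
    x$mu, x$sigma, x$k, x$threshold, x$tail_prob))
  invisible(x)
}

# E[Z^2 | -a <= Z <= 0] for standard normal Z; the second moment of the
# left flank of a zero-truncated normal peak, expressed in units of sigma^2.
.left_moment <- function(a) {
  denom <- 0.5 - stats::pnorm(-a)
  1 - a * stats::dnorm(a) / denom
}

#' Fit a normal model to the low-expression noise peak
#'
#' Locates the low-intensity mode of the distribution by histogram: bin
#' width by the Freedman-Diaconis rule on the sub-median values, then the
#' peak position refined parabolically — a quadratic is fitted to the log
#' counts of the contiguous bins around the maximum that stay above half
#' the peak count (the log density of a normal peak is exactly quadratic
#' there), its vertex giving the mode; with fewer than three usable bins
#' the classic three-point parabolic interpolation of the peak bin and its
#' neighbours is used.  The fit fails with error `"no-noise-peak"` when
#' the histogram mode does not lie below the overall median (no
#' low-expression peak to model).
#'
#' The SD is estimated from the left flank only (values at or below the
#' mode, mirrored), because the right flank is contaminated by expressed
#' genes.  Intensities cannot be negative, so the left flank itself is
#' truncated at zero whenever the peak sits within a few SD of zero; the
#' naive mirrored second moment would then be biased low.  The estimator
#' corrects for this by solving
#' `mean((mu - v)^2 | 0 <= v <= mu) = sigma^2 * E[Z^2 | -mu/sigma <= Z <= 0]`
#' for `sigma`; when the peak is far from zero the correction factor is 1
#' and the estimate reduces to the plain mirrored SD.
#'
#' @param values Numeric vector of intensities (the post-normalization
#'   reference distribution, or pooled matrix values); at least `min_n`
#'   non-missing values.
#' @param k SD multiplier for the derived threshold (default 3).
#' @param min_n Minimum sample size for a stable histogram fit.
#' @return A [noise_model].
#' @export
fit_noise <- function(values, k = 3, min_n = 1000) {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (length(v) < min_n)
    stop(sprintf("fit_noise needs >= %d values, got %d", min_n, length(v)))
  med <- stats::median(v)
  sub <- v[v <= med]
  bw <- 2 * stats::IQR(sub) / length(sub)^(1 / 3)
  if (!is.finite(bw) || bw <= 0)
    stop("no-noise-peak: degenerate sub-median distribution")

  # histogram over the full range; the global mode must be a low mode
  rng <- range(v)
  breaks <- seq(rng[1], rng[2] + bw, by = bw)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  # pure-noise data has its mode at ~ the median, so reject only when the
  # histogram is clearly dominated by a high mode
  low <- which(centers < med)
  if (length(low) == 0L)
    stop("no-noise-peak: histogram mode is not below the overall median")
  c_low <- max(counts[low])
  c_high <- if (length(low) < length(counts))
    max(counts[-low]) else 0L
  if (c_high > 1.1 * c_low)
    stop("no-noise-peak: histogram mode is not below the overall median")
  p <- low[which.max(counts[low])]
  # refine within the half-height window around the peak
  lo_i <- p
  while (lo_i > 1L && counts[lo_i - 1L] >= 0.5 * counts[p]) lo_i <- lo_i - 1L
  hi_i <- p
  while (hi_i < length(counts) && counts[hi_i + 1L] >= 0.5 * counts[p])
    hi_i <- hi_i + 1L
  win <- lo_i:hi_i
  win <- win[counts[win] > 0]
  mu <- NA_real_
  if (length(win) >= 3L) {
    fit <- stats::lm.fit(cbind(1, centers[win], centers[win]^2),
                         log(counts[win]))
    b <- fit$coefficients
    if (is.finite(b[3]) && b[3] < 0) mu <- -b[2] / (2 * b[3])
  }
  if (is.na(mu) || mu < centers[lo_i] - bw || mu > centers[hi_i] + bw) {
    cl <- if (p > 1L) counts[p - 1L] else 0L
    cr <- if (p < length(counts)) counts[p + 1L] else 0L
    denom <- cl - 2 * counts[p] + cr
    delta <- if (denom < 0) 0.5 * (cl - cr) / denom else 0
    mu <- centers[p] + delta * bw
  }

  left <- v[v <= mu & v >= 0]
  if (length(left) < 10L)
    stop("no-noise-peak: too few values on the left flank of the mode")
  m2 <- mean((mu - left)^2)

  # invert sigma^2 * E[Z^2 | -mu/sigma <= Z <= 0] = m2; the map is
  # increasing in sigma and bounded above by mu^2/3 (uniform limit)
  if (m2 >= 0.99 * mu^2 / 3) {
    sigma <- sqrt(m2)  # near-uniform left flank: no correction possible
  } else {
    f <- function(s) s^2 * .left_moment(mu / s) - m2
    lo <- sqrt(m2)
    hi <- lo
    while (f(hi) < 0 && hi < 1e6 * lo) hi <- hi * 1.5
    sigma <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  nm <- noise_model(mu, sigma, k)
  nm$bin_width <- bw
  nm$n <- length(v)
  nm
}

#' Call genes expressed above the noise threshold
#'
#' A value is called expressed iff it is strictly greater than the model's
#' threshold; missing values stay missing.
#'
#' @param em An [expression_matrix] with `state = "normalized"`.
#' @param model A [noise_model].
#' @return Logical gene-by-experiment matrix (`NA` preserved).
#' @export
call_expressed <- function(em, model) {
  stopifnot(inherits(em, "expression_matrix"),
            inherits(model, "noise_model"))
  if (em$state != "normalized")
    stop("call_expressed expects a normalized matrix, got state=", em$state)
  em$values > model$threshold
}

#' Write a noise-model report
#'
#' Key-value JSON-style text with `mu`, `sigma`, `k`, `threshold` and the
#' one-sided normal tail probability above the threshold.
#'
#' @param model A [noise_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_noise_report <- function(model, path) {
  lines <- c("{",
             sprintf('  "mu": %.10g,', model$mu),
             sprintf('  "sigma": %.10g,', model$sigma),
             sprintf('  "k": %.10g,', model$k),
             sprintf('  "threshold": %.10g,', model$threshold),
             sprintf('  "tail_prob": %.10g', model$tail_prob),
             "}")
  writeLines(lines, path)
  invisible(path)
}
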