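#' Stationary response of an observable over a b_T grid
#'
#' For each grid value of the input `b_T`, measures the stationary mean and
#' standard deviation of one observable, either by stochastic simulation
#' (`estimator = "ssa"`: one seeded Gillespie run per grid point, seed =
#' `seed + point index`) or by the Linear Noise Approximation
#' (`estimator = "lna"`). This curve is the basis of the derepression-size
#' and channel-capacity analyses.
#'
#' @param params a [cerna_params()] object.
#' @param observable species name, one of [cerna_species()].
#' @param grid strictly increasing b_T values within `[bT_min, bT_max]`.
#' @param estimator `"ssa"` or `"lna"`.
#' @param seed base RNG seed (SSA mode).
#' @param t_end,burn_in,record_interval SSA budget per grid point (min).
#' @return A `data.frame` of class `cerna_response` with columns `b_T`,
#'   `mean`, `sd`, `cv`, `ok` and attributes `observable`, `provenance`.
#' @examples
#' p <- cerna_params(kplus_T = 0, kplus_C = 0)
#' rc <- response_sweep(p, "p_T", grid = c(0, 30, 60), estimator = "lna")
#' rc$mean   # 0, 1500, 3000: slope alpha_T/(deltap_T * d_T) = 50
#' @export
response_sweep <- function(params, observable = "p_T",
                           grid = seq(0, 60, length.out = 61),
                           estimator = c("lna", "ssa"), seed = 1L,
                           t_end = 3500, burn_in = 500, record_interval = 1) {
  estimator <- match.arg(estimator)
  params <- validate_params(params)
  observable <- match.arg(observable, cerna_species())
  .check_grid(grid, params)
  if (estimator == "lna") {
    out <- cv_curve(params, observable, grid)
    return(out)
  }
  rows <- lapply(seq_along(grid), function(i) {
    pt <- update_params(params, b_T = grid[i])
    net <- build_network(pt)
    res <- tryCatch({
      tr <- simulate_ssa(net, t_end = t_end, seed = as.integer(seed) + i,
                         record_interval = record_interval)
      sm <- stationary_summary(tr, burn_in = burn_in)
      data.frame(b_T = grid[i], mean = sm$mean[[observable]],
                 sd = sm$sd[[observable]],
                 cv = unname(sm$cv[observable]), ok = TRUE)
    }, error = function(e) {
      data.frame(b_T = grid[i], mean = NA_real_, sd = NA_real_,
                 cv = NA_real_, ok = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "observable") <- observable
  attr(out, "provenance") <- "SSA"
  class(out) <- c("cerna_response", "data.frame")
  out
}

#' Derepression size of the competitor
#'
#' The difference between the largest and smallest stationary mean of the
#' observable (canonically the competitor transcript `m_C`) over the full
#' input range of `b_T`. A large value signals active ceRNA crosstalk: the
#' target's transcription rate, by titrating the shared miRNA, visibly
#' de-represses the competitor.
#'
#' @param curve a response curve from [response_sweep()] for `m_C` (or any
#'   observable) covering `[bT_min, bT_max]`.
#' @return Non-negative scalar, molecules.
#' @export
derepression_size <- function(curve) {
  m <- curve$mean[curve$ok & is.finite(curve$mean)]
  if (length(m) == 0L) stop("response curve has no valid points")
  max(m) - min(m)
}

# Smoothing-spline fit of the mean response and its derivative.
# GCV picks the smoothing parameter; for noiseless LNA curves the fit
# follows the points essentially exactly.
.curve_derivative <- function(curve, spar = NULL) {
  ok <- curve$ok & is.finite(curve$mean)
  b <- curve$b_T[ok]; m <- curve$mean[ok]
  if (sum(ok) < 4L) stop("need at least 4 valid grid points")
  fit <- if (is.null(spar)) stats::smooth.spline(b, m, cv = FALSE)
         else stats::smooth.spline(b, m, spar = spar)
  list(fit = fit,
       deriv = function(x) stats::predict(fit, x, deriv = 1)$y,
       mean = function(x) stats::predict(fit, x)$y)
}

#' Small-noise optimal input distribution
#'
#' The input density that achieves the channel capacity in the small-noise
#' limit: `P_opt(b) proportional to |dMean/db| / sd(b)`, normalized over the
#' grid. The derivative of the mean response is taken from a smoothing-spline
#' fit (smoothing chosen by generalized cross-validation) because raw SSA
#' means are noisy; `spar` overrides the automatic choice.
#'
#' @param curve a response curve from [response_sweep()].
#' @param spar optional `smooth.spline` smoothing parameter.
#' @return List with `b` (grid), `density` (normalized so that the trapezoid
#'   integral over the grid is 1), `weights` (per-point sampling
#'   probabilities, summing to 1) and `Z` (the unnormalized integral
#'   `int |dMean/db| / sd db`, reused by the closed-form capacity).
#' @export
optimal_input_distribution <- function(curve, spar = NULL) {
  ok <- curve$ok & is.finite(curve$mean) & is.finite(curve$sd)
  # a zero-molecule boundary point (mean = sd = 0, e.g. b_T = 0 with no
  # other source) carries no signal and is excluded; zero noise at a point
  # with actual signal would make the SNA capacity ill-defined
  degenerate <- ok & curve$sd <= 0 & abs(curve$mean) <= .Machine$double.eps
  ok <- ok & !degenerate
  b <- curve$b_T[ok]; sdv <- curve$sd[ok]
  if (length(b) < 4L) stop("fewer than 4 usable grid points in response curve")
  mrange <- diff(range(curve$mean[ok]))
  if (mrange <= 1e-9 * max(1, max(abs(curve$mean[ok])))) {
    stop("flat response curve: zero-gain channel has no normalizable optimal input density")
  }
  if (any(sdv <= 0)) {
    dmu <- abs(.curve_derivative(curve[ok, ], spar)$deriv(b))
    if (any(sdv <= 0 & dmu > 1e-8 * max(dmu))) {
      stop("sd is zero where the mean response has gain; noiseless channel")
    }
  }
  der <- .curve_derivative(curve[ok, ], spar)
  dens <- abs(der$deriv(b)) / pmax(sdv, .Machine$double.eps)
  Z <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(b))
  if (!is.finite(Z) || Z <= 0) {
    stop("optimal input density is identically zero (flat response curve)")
  }
  w <- dens * c(diff(b)[1] / 2, (diff(b)[-1] + diff(b)[-(length(b) - 1)]) / 2,
                diff(b)[length(b) - 1] / 2)
  list(b = b, density = dens / Z, weights = w / sum(w), Z = Z,
       keep = which(ok))
}

# Plug-in mutual information (bits) of a 2-D sample with equal-width bins
# and Miller-Madow bias correction. Bin edges may be supplied to fix the
# output range across parameter settings.
.histogram_mi <- function(x, y, bins = c(30L, 30L),
                          xlim = range(x), ylim = range(y)) {
  bx <- seq(xlim[1], xlim[2], length.out = bins[1] + 1L)
  by <- seq(ylim[1], ylim[2], length.out = bins[2] + 1L)
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- x >= xlim[1] & x <= xlim[2] & y >= ylim[1] & y <= ylim[2]
  ix <- ix[keep]; iy <- iy[keep]
  n <- length(ix)
  if (n < 10L) stop("too few samples inside the histogram range")
  joint <- table(factor(ix, levels = seq_len(bins[1])),
                 factor(iy, levels = seq_len(bins[2]))) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- H(px) + H(py) - H(joint[nz])
  # Miller-Madow: each plug-in entropy is biased down by (K-1)/(2N ln 2)
  kx <- sum(px > 0); ky <- sum(py > 0); kxy <- sum(nz)
  mm <- ((kx - 1) + (ky - 1) - (kxy - 1)) / (2 * n * log(2))
  list(mi = mi + mm, mi_plugin = mi, n = n,
       occupied = c(x = kx, y = ky, joint = kxy))
}

#' Channel capacity under the Small Noise Approximation
#'
#' Estimates the capacity `I_max` of the channel from the input `b_T` to an
#' output observable, given the measured response curve, by the four-step
#' small-noise protocol: (1) the curve supplies mean and noise per input;
#' (2) the optimal input distribution `P_opt(b) ~ |dMean/db|/sd(b)` is
#' formed; (3) inputs are drawn from `P_opt` and outputs from the Gaussian
#' channel `N(mean(b), sd(b)^2)` read off the curve; (4) the mutual
#' information of the sampled joint histogram (equal-width bins,
#' Miller--Madow bias correction) is the headline estimate. The closed-form
#' small-noise capacity `log2(Z / sqrt(2*pi*e))` with
#' `Z = int |dMean/db|/sd db` is reported alongside as a consistency
#' diagnostic; a negative closed form (noise too large for the
#' approximation) is flagged, not an error.
#'
#' @param curve a response curve from [response_sweep()].
#' @param n_samples Monte-Carlo sample size (>= 1e4 recommended).
#' @param bins histogram bins per axis (length 1 or 2).
#' @param seed RNG seed for the sampling step.
#' @param o_range optional fixed output range `c(min, max)`; by default the
#'   range realized by the samples. Fixing it allows capacities measured at
#'   different parameter settings to be compared on a common output window.
#' @param spar optional smoothing parameter passed to the spline derivative.
#' @return An object of class `cerna_capacity`: list with `I_max` (bits;
#'   the histogram estimate), `I_sna` (closed form), `sna_valid`,
#'   `p_opt` (from [optimal_input_distribution()]), `o_range`, `bins`,
#'   `n_samples`, `seed`.
#' @export
estimate_capacity <- function(curve, n_samples = 1e5, bins = 30L, seed = 1L,
                              o_range = NULL, spar = NULL) {
  bins <- rep(as.integer(bins), length.out = 2L)
  popt <- optimal_input_distribution(curve, spar = spar)
  b <- curve$b_T[popt$keep]; mu <- curve$mean[popt$keep]
  sdv <- curve$sd[popt$keep]
  set.seed(as.integer(seed))
  idx <- sample.int(length(b), n_samples, replace = TRUE, prob = popt$weights)
  x <- b[idx]
  y <- stats::rnorm(n_samples, mean = mu[idx], sd = sdv[idx])
  if (is.null(o_range)) o_range <- range(y)
  h <- .histogram_mi(x, y, bins = bins,
                     xlim = range(b), ylim = o_range)
  I_sna <- log2(popt$Z / sqrt(2 * pi * exp(1)))
  out <- list(I_max = h$mi, I_plugin = h$mi_plugin, I_sna = I_sna,
              sna_valid = is.finite(I_sna) && I_sna > 0,
              p_opt = popt, o_range = o_range, bins = bins,
              n_samples = as.integer(n_samples), seed = as.integer(seed),
              occupied = h$occupied)
  class(out) <- "cerna_capacity"
  out
}

#' @export
print.cerna_capacity <- function(x, ...) {
  cat("Channel capacity (SNA): I_max =", round(x$I_max, 3),
      "bits (histogram), closed form", round(x$I_sna, 3), "bits\n")
  if (!x$sna_valid) cat("  note: closed form non-positive; small-noise assumption weak\n")
  invisible(x)
}

#' Monte-Carlo error of a capacity estimate
#'
#' Re-runs the histogram capacity estimator with independent sampling seeds
#' and reports the spread, the standard way to attach an error bar to
#' `I_max` without assuming anything about the estimator's distribution.
#'
#' @inheritParams estimate_capacity
#' @param n_rep number of replicate estimates.
#' @return List with `I_max` (mean over replicates), `se` (standard
#'   deviation over replicates) and `replicates` (the individual values).
#' @export
capacity_replicates <- function(curve, n_rep = 5L, n_samples = 1e5,
                                bins = 30L, seed = 1L, o_range = NULL,
                                spar = NULL) {
  vals <- vapply(seq_len(n_rep), function(r) {
    estimate_capacity(curve, n_samples = n_samples, bins = bins,
                      seed = as.integer(seed) + r, o_range = o_range,
                      spar = spar)$I_max
  }, numeric(1))
  list(I_max = mean(vals), se = stats::sd(vals), replicates = vals)
}

#' Noise reduction at matched mean between two response curves
#'
#' Compares two CV-vs-mean curves of the same observable (e.g. slow vs fast
#' catalytic complex processing) and reports the maximal relative CV
#' reduction of `fast` with respect to `slow` at matched mean expression:
#' the slow curve's CV is interpolated onto each fast-curve mean inside the
#' overlapping mean range, and the largest value of
#' `100 * (cv_slow - cv_fast) / cv_slow` is returned.
#'
#' @param slow,fast response curves ([response_sweep()]) of the same
#'   observable; means must be monotone enough in `b_T` for interpolation on
#'   the mean axis (guaranteed here, where means increase with `b_T`).
#' @param min_mean lower bound of the matched-mean window (molecules);
#'   excludes the near-zero-expression corner where CVs diverge.
#' @return List with `max_reduction_pct`, `at_mean` (mean level where the
#'   maximum occurs) and `table` (per-point comparison).
#' @export
cv_reduction_at_matched_mean <- function(slow, fast, min_mean = 1) {
  oks <- slow$ok & is.finite(slow$cv) & is.finite(slow$mean)
  okf <- fast$ok & is.finite(fast$cv) & is.finite(fast$mean)
  s <- slow[oks, ]; f <- fast[okf, ]
  s <- s[order(s$mean), ]; f <- f[order(f$mean), ]
  lo <- max(min(s$mean), min(f$mean), min_mean)
  hi <- min(max(s$mean), max(f$mean))
  if (!(hi > lo)) stop("mean ranges of the two curves do not overlap")
  sel <- f$mean >= lo & f$mean <= hi
  if (!any(sel)) stop("no fast-curve points inside the matched-mean window")
  cv_s <- stats::approx(s$mean, s$cv, xout = f$mean[sel], ties = mean)$y
  red <- 100 * (cv_s - f$cv[sel]) / cv_s
  tab <- data.frame(mean = f$mean[sel], cv_fast = f$cv[sel], cv_slow = cv_s,
                    reduction_pct = red)
  tab <- tab[is.finite(tab$reduction_pct), ]
  if (nrow(tab) == 0L) stop("no finite matched-mean comparisons")
  i <- which.max(tab$reduction_pct)
  list(max_reduction_pct = tab$reduction_pct[i], at_mean = tab$mean[i],
       table = tab)
}
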