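#' Exact stochastic simulation (direct-method Gillespie)
#'
#' Samples one trajectory of the chemical master equation of the network by
#' the direct method: at each step the waiting time is exponential with rate
#' equal to the total propensity and the reaction is drawn proportionally to
#' its propensity. The state is recorded on an equally spaced time grid
#' (sample-and-hold). Seeding is explicit: the same `seed`, network and
#' initial state give bit-identical trajectories.
#'
#' @param network a [build_network()] object.
#' @param initial integer-valued initial state (length 8, ordered as
#'   [cerna_species()]); default is the deterministic steady state rounded to
#'   integers, which shortens the transient.
#' @param t_end total simulated time (min).
#' @param seed integer RNG seed.
#' @param record_interval spacing of recorded samples (min).
#' @param record_start time of the first recorded sample (min); samples
#'   before it are discarded at source. Recording from 0 keeps the transient.
#' @return An object of class `cerna_trajectory`: list with `time` (numeric
#'   vector), `states` (samples x 8 matrix), `seed`, `t_end`,
#'   `record_interval`, `record_start`.
#' @examples
#' net <- build_network(cerna_params(kplus_T = 0, kplus_C = 0))
#' tr <- simulate_ssa(net, t_end = 200, seed = 1)
#' colMeans(tr$states)
#' @export
simulate_ssa <- function(network, initial = NULL, t_end, seed,
                         record_interval = 1, record_start = 0) {
  stopifnot(inherits(network, "cerna_network"))
  if (t_end <= 0) stop("t_end must be positive")
  if (is.null(initial)) {
    ss <- tryCatch(solve_steady_state(network), error = function(e) NULL)
    initial <- if (!is.null(ss) && ss$converged) round(ss$state) else
      rep(0, length(network$species))
  }
  initial <- .check_state(network, initial)
  if (any(initial != floor(initial))) stop("initial state must be integer-valued")
  set.seed(as.integer(seed))
  res <- .ssa_kernel(network$stoich, network$rates, network$reactants,
                     as.numeric(initial), as.numeric(t_end),
                     as.numeric(record_start), as.numeric(record_interval))
  colnames(res$states) <- network$species
  traj <- list(time = res$time, states = res$states, seed = as.integer(seed),
               t_end = t_end, record_interval = record_interval,
               record_start = record_start)
  class(traj) <- "cerna_trajectory"
  traj
}

#' @export
print.cerna_trajectory <- function(x, ...) {
  cat("cerna_trajectory:", nrow(x$states), "samples over",
      format(x$t_end), "min (seed", x$seed, ")\n")
  invisible(x)
}

# Integrated-autocorrelation-corrected standard error of the mean via
# non-overlapping batch means; returns list(se, ess).
.batch_se <- function(v, n_batch = 30L) {
  n <- length(v)
  n_batch <- max(2L, min(n_batch, n %/% 2L))
  bsize <- n %/% n_batch
  if (bsize < 1L) return(list(se = NA_real_, ess = NA_real_))
  m <- matrix(v[seq_len(bsize * n_batch)], nrow = bsize)
  bm <- colMeans(m)
  se <- stats::sd(bm) / sqrt(n_batch)
  s2 <- stats::var(v)
  ess <- if (is.finite(se) && se > 0) s2 / se^2 else n
  list(se = se, ess = min(ess, n))
}

#' Stationary moments of a trajectory
#'
#' Time-averaged means, variances, coefficients of variation and pairwise
#' Pearson correlations from the post-burn-in portion of a trajectory,
#' together with autocorrelation-corrected standard errors of the means
#' (non-overlapping batch means) and the implied effective sample sizes.
#'
#' The CV of a species whose time-averaged mean is zero is flagged undefined
#' (`NA` with `cv_defined = FALSE`) rather than propagating `Inf`; Pearson
#' coefficients involving a zero-variance species are likewise `NA`.
#'
#' @param traj a [simulate_ssa()] trajectory.
#' @param burn_in time (min, from trajectory start) discarded before
#'   averaging. Default 500 min = 50 times the slowest decay timescale of the
#'   baseline rates (all decay rates are >= 0.1/min).
#' @param sample_interval spacing (min) at which the recorded samples are
#'   thinned before averaging; must be a multiple of the recording interval.
#' @return An object of class `cerna_summary`: list with `mean`, `var`,
#'   `sd`, `cv`, `cv_defined`, `se_mean`, `ess` (per-species vectors),
#'   `pearson` (8 x 8 matrix) and `n_samples`.
#' @export
stationary_summary <- function(traj, burn_in = 500, sample_interval = NULL) {
  stopifnot(inherits(traj, "cerna_trajectory"))
  if (is.null(sample_interval)) sample_interval <- traj$record_interval
  thin <- sample_interval / traj$record_interval
  if (abs(thin - round(thin)) > 1e-8 || thin < 1) {
    stop("sample_interval must be a positive multiple of the recording interval")
  }
  keep <- which(traj$time >= burn_in)
  if (length(keep) == 0L) stop("burn_in discards the whole trajectory")
  keep <- keep[seq(1L, length(keep), by = round(thin))]
  if (length(keep) < 100L) {
    stop("fewer than 100 post-burn-in samples; lengthen the run or reduce burn_in")
  }
  X <- traj$states[keep, , drop = FALSE]
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  sdv <- sqrt(v)
  cv_defined <- mu > 0
  cv <- ifelse(cv_defined, sdv / mu, NA_real_)
  bs <- lapply(seq_len(ncol(X)), function(j) .batch_se(X[, j]))
  se <- vapply(bs, `[[`, numeric(1), "se")
  ess <- vapply(bs, `[[`, numeric(1), "ess")
  names(se) <- names(ess) <- colnames(X)
  P <- suppressWarnings(stats::cor(X))
  P[!is.finite(P)] <- NA_real_
  diag(P)[apply(X, 2, stats::sd) == 0] <- NA_real_
  out <- list(mean = mu, var = v, sd = sdv, cv = cv, cv_defined = cv_defined,
              se_mean = se, ess = ess, pearson = P, n_samples = nrow(X))
  class(out) <- "cerna_summary"
  out
}

#' @export
print.cerna_summary <- function(x, ...) {
  cat("Stationary summary over", x$n_samples, "samples\n")
  print(round(rbind(mean = x$mean, sd = x$sd, cv = x$cv, ess = x$ess), 4))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Tabular form: a `time` column followed by one column per species.
#'
#' @param traj a `cerna_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$time, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a stationary summary as JSON
#'
#' Means, variances, CVs and the Pearson matrix keyed by species name.
#'
#' @param summary a `cerna_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  obj <- list(mean = as.list(summary$mean), var = as.list(summary$var),
              cv = as.list(summary$cv), ess = as.list(summary$ess),
              pearson = summary$pearson, n_samples = summary$n_samples)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       matrix = "rowmajor")
  invisible(path)
}
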