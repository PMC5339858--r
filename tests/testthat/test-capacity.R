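# build a synthetic response curve in the shape response_sweep() returns
make_curve <- function(b, mean, sd) {
  out <- data.frame(b_T = b, mean = mean, sd = sd,
                    cv = ifelse(mean > 0, sd / mean, NA_real_), ok = TRUE)
  attr(out, "observable") <- "p_T"
  attr(out, "provenance") <- "synthetic"
  class(out) <- c("cerna_response", "data.frame")
  out
}

test_that("response sweeps reproduce decoupled closed forms", {
  grid <- seq(0, 60, length.out = 13)
  # competitor decoupled from the target input: flat m_C = b_C/d_C
  mC <- response_sweep(params_mirna_only(), "m_C", grid, "lna")
  expect_equal(mC$mean, rep(150, 13), tolerance = 1e-6)
  # fully decoupled target protein: linear through origin, slope 50
  pT <- response_sweep(params_decoupled(), "p_T", grid, "lna")
  expect_equal(pT$mean, 50 * grid, tolerance = 1e-6)
  # ceRNA effect: the competitor mean rises with b_T when coupled
  mC2 <- response_sweep(params_cerna(), "m_C", grid, "lna")
  expect_true(all(diff(mC2$mean) > 0))
})

test_that("derepression size measures the coupled response range", {
  grid <- seq(0, 60, length.out = 13)
  mC <- response_sweep(params_mirna_only(), "m_C", grid, "lna")
  expect_equal(derepression_size(mC), 0, tolerance = 1e-6)
  mC2 <- response_sweep(params_cerna(), "m_C", grid, "lna")
  d <- derepression_size(mC2)
  expect_gt(d, 0)
  # invariant under traversal order of the grid
  rev_curve <- mC2[rev(seq_len(nrow(mC2))), ]
  expect_equal(derepression_size(rev_curve), d)
})

test_that("optimal input distribution follows |gain|/noise", {
  b <- seq(0, 100, length.out = 201)
  # linear response, constant noise: uniform optimum
  u <- optimal_input_distribution(make_curve(b, b, rep(1, length(b))))
  expect_lt(diff(range(u$density)), 0.05 * mean(u$density))
  expect_equal(sum(u$weights), 1)
  # quadratic response on [0, 1]: density 2b
  b2 <- seq(0, 1, length.out = 201)
  q <- optimal_input_distribution(make_curve(b2, b2^2, rep(1, length(b2))))
  interior <- b2 > 0.1 & b2 < 0.9
  expect_equal(q$density[interior], 2 * b2[interior], tolerance = 0.05)
  # flat response: unnormalizable density
  expect_error(
    optimal_input_distribution(make_curve(b, rep(5, length(b)),
                                          rep(1, length(b)))),
    "zero|flat")
})

test_that("capacity estimator matches the linear Gaussian closed form", {
  b <- seq(0, 100, length.out = 201)
  curve <- make_curve(b, b, rep(1, length(b)))
  # bins must resolve the conditional noise scale (sd = 1 on a range of 100)
  est <- estimate_capacity(curve, n_samples = 1e5, bins = c(100, 200),
                           seed = 17)
  closed <- log2(100 / sqrt(2 * pi * exp(1)))
  expect_equal(est$I_sna, closed, tolerance = 0.01)
  expect_lt(abs(est$I_max - closed), 0.15)
  expect_true(est$sna_valid)
})

test_that("histogram MI is exact on a noiseless bijection and null on independence", {
  set.seed(101)
  n <- 8L
  x <- rep(seq_len(n), each = 2000) + stats::runif(16000, -0.2, 0.2)
  y <- rep(seq_len(n), each = 2000) + stats::runif(16000, -0.2, 0.2)
  h <- cernanoise:::.histogram_mi(x, y, bins = c(n, n))
  expect_equal(h$mi, log2(n), tolerance = 0.02)
  # independent inputs and outputs: MI within estimator bias of zero
  y2 <- sample(y)
  h0 <- cernanoise:::.histogram_mi(x, y2, bins = c(30, 30))
  expect_lt(abs(h0$mi), 0.05)
  expect_gt(h0$mi, -0.05)  # bias correction never pushes far below zero
})

test_that("coarsening the output binning cannot raise the information", {
  b <- seq(0, 100, length.out = 201)
  curve <- make_curve(b, b, rep(2, length(b)))
  fine <- estimate_capacity(curve, n_samples = 5e4, bins = c(30, 40),
                            seed = 23)
  coarse <- estimate_capacity(curve, n_samples = 5e4, bins = c(30, 8),
                              seed = 23)
  expect_lt(coarse$I_max, fine$I_max + 0.05)
})

test_that("replicate seeds quantify the Monte-Carlo error of the capacity", {
  b <- seq(0, 100, length.out = 201)
  curve <- make_curve(b, b, rep(2, length(b)))
  rep5 <- capacity_replicates(curve, n_rep = 5, n_samples = 2e4, seed = 40)
  expect_length(rep5$replicates, 5)
  expect_gt(rep5$se, 0)
  # replicates scatter around the single-shot estimate
  single <- estimate_capacity(curve, n_samples = 2e4, seed = 41)$I_max
  expect_lt(abs(rep5$I_max - single), 5 * rep5$se + 0.05)
})

test_that("capacity sampling is reproducible and seed-sensitive", {
  b <- seq(0, 60, length.out = 61)
  curve <- make_curve(b, 2 * b, 1 + 0.05 * b)
  a1 <- estimate_capacity(curve, n_samples = 2e4, seed = 5)
  a2 <- estimate_capacity(curve, n_samples = 2e4, seed = 5)
  a3 <- estimate_capacity(curve, n_samples = 2e4, seed = 6)
  expect_identical(a1$I_max, a2$I_max)
  expect_false(identical(a1$I_max, a3$I_max))
  expect_gt(a1$I_max, 0)
})
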