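test_that("steady state solves the decoupled closed forms", {
  net <- build_network(params_decoupled(b_T = 15))
  ss <- solve_steady_state(net)
  expect_true(ss$converged)
  expect_equal(ss$state[["m_T"]], 150, tolerance = 1e-8)
  expect_equal(ss$state[["mu"]], 250, tolerance = 1e-8)
  expect_equal(ss$state[["p_T"]], 750, tolerance = 1e-8)
  # no transcription, active binding: empty target branch
  net0 <- build_network(params_cerna(b_T = 0))
  ss0 <- solve_steady_state(net0)
  expect_equal(ss0$state[["m_T"]], 0, tolerance = 1e-8)
  expect_equal(ss0$state[["c_T"]], 0, tolerance = 1e-8)
  expect_equal(ss0$state[["p_T"]], 0, tolerance = 1e-8)
  expect_lt(ss0$residual, 1e-9)
})

test_that("regulated target approaches the unrepressed slope beyond crossover", {
  # threshold-linear profile: repressed at low b_T, slope alpha_T/(deltap_T d_T)
  # far above the crossover
  p <- params_mirna_only()
  curve <- cv_curve(p, "p_T", grid = seq(0, 60, by = 1))
  slope_free <- p$alpha_T / (p$deltap_T * p$d_T)  # 50
  slope_60 <- (curve$mean[61] - curve$mean[59]) / 2
  expect_lt(abs(slope_60 - slope_free) / slope_free, 0.1)
  # repressed regime: strongly sub-linear
  slope_low <- (curve$mean[6] - curve$mean[4]) / 2
  expect_lt(slope_low, 0.3 * slope_free)
})

test_that("Lyapunov covariance matches closed forms on linear circuits", {
  # birth-death: Sigma = mean (Poisson)
  res <- lna_covariance(matrix(-0.1), matrix(2 * 10), mean = c(m = 100))
  expect_equal(res$cov[1, 1], 100, tolerance = 1e-10)
  expect_equal(unname(res$cv[1]), 0.1, tolerance = 1e-10)
  expect_lt(res$residual, 1e-8 * 20)

  # two-stage expression: protein Fano factor 1 + alpha/(d + delta_p) = 3.5
  p <- params_two_stage()
  s <- lna_summary(p)
  i <- match(c("m_T", "p_T"), names(s$lna$mean))
  fano_m <- unname(s$lna$cov[i[1], i[1]] / s$lna$mean[[i[1]]])
  fano_p <- unname(s$lna$cov[i[2], i[2]] / s$lna$mean[[i[2]]])
  expect_equal(fano_m, 1, tolerance = 1e-8)
  expect_equal(fano_p, 1 + p$alpha_T / (p$d_T + p$deltap_T), tolerance = 1e-8)

  # decoupled network: block-diagonal covariance, zero cross-correlation,
  # Poisson transcripts
  sd <- lna_summary(params_decoupled())
  P <- sd$lna$pearson
  expect_equal(P["m_T", "m_C"], 0, tolerance = 1e-10)
  expect_equal(P["m_T", "mu"], 0, tolerance = 1e-10)
  expect_equal(P["p_T", "p_C"], 0, tolerance = 1e-10)
  expect_equal(sd$lna$cov["m_T", "m_T"], sd$lna$mean[["m_T"]],
               tolerance = 1e-8)
  expect_equal(sd$lna$cov["mu", "mu"], sd$lna$mean[["mu"]], tolerance = 1e-8)
})

test_that("eigen-decomposition form agrees with the Lyapunov solution", {
  # distinct decay rates keep the Jacobian diagonalizable; with repeated
  # rates (package defaults) the eigenvector matrix is defective and the
  # eigen route must refuse rather than return garbage
  p <- params_cerna(d_T = 0.11, d_C = 0.09, delta = 0.12, deltap_T = 0.13,
                    deltap_C = 0.07)
  s <- lna_summary(p)
  dyn <- s$steady$dynamic
  A <- jacobian_matrix(s$network, s$steady$state)[dyn, dyn]
  G <- diffusion_matrix(s$network, s$steady$state)[dyn, dyn]
  expect_equal(lna_covariance_eigen(A, G), s$lna$cov, tolerance = 1e-6)

  s0 <- lna_summary(params_cerna())
  dyn0 <- s0$steady$dynamic
  A0 <- jacobian_matrix(s0$network, s0$steady$state)[dyn0, dyn0]
  G0 <- diffusion_matrix(s0$network, s0$steady$state)[dyn0, dyn0]
  expect_error(lna_covariance_eigen(A0, G0), "defective|degenerate")
})

test_that("unstable Jacobians are rejected with the offending eigenvalue", {
  expect_error(lna_covariance(matrix(c(0.2, 0, 0, -1), 2), diag(2)),
               "eigenvalue")
})

test_that("covariance matrices are symmetric PSD with tight residuals", {
  for (p in list(params_cerna(),
                 do.call(update_params, c(list(params_cerna()), ppi_on)))) {
    s <- lna_summary(p)
    S <- s$lna$cov
    expect_equal(S, t(S))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8 * sum(diag(S))))
    dyn <- s$steady$dynamic
    G <- diffusion_matrix(s$network, s$steady$state)[dyn, dyn]
    expect_lt(s$lna$residual, 1e-8 * max(abs(G)))
  }
})

test_that("CV curves have the canonical circuit shapes", {
  grid <- seq(0, 60, length.out = 61)
  # unregulated: CV decreases monotonically with expression
  un <- cv_curve(params_decoupled(), "p_T", grid)
  expect_true(all(diff(un$cv[un$b_T > 0]) < 0))
  # miRNA-regulated: a single interior CV peak at the crossover
  mir <- cv_curve(params_mirna_only(), "p_T", grid)
  cv <- mir$cv[mir$ok & is.finite(mir$cv)]
  expect_equal(n_local_maxima(cv), 1L)
  # ceRNA regulation beats miRNA-only noise at matched high expression
  ce <- cv_curve(params_cerna(), "p_T", grid)
  hi <- which(ce$mean > 500 & ce$mean < max(mir$mean))
  cv_mir_matched <- stats::approx(mir$mean, mir$cv, xout = ce$mean[hi])$y
  expect_gt(length(hi), 5)
  expect_true(all(ce$cv[hi] < cv_mir_matched))
})
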