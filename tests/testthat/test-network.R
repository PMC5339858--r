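test_that("network enumerates the full elementary reaction list", {
  net <- build_network(cerna_params())
  expect_equal(net$species, c("m_T", "m_C", "mu", "c_T", "c_C",
                              "p_T", "p_C", "C_p"))
  expect_equal(dim(net$stoich), c(8L, 21L))
  # one synthesis per free RNA species, two complex-processing channels per
  # miRNA:ceRNA complex, reversible PPI with complex decay
  expect_equal(sum(grepl("^synthesis", net$labels)), 3L)
  expect_equal(sum(grepl("catalytic", net$labels)), 2L)
  expect_equal(sum(grepl("stoichiometric", net$labels)), 2L)
})

test_that("mass-action propensities vanish with their reactants", {
  net <- build_network(cerna_params())
  # no miRNA: no association; no complexes: no dissociation or complex decay
  s <- c(m_T = 10, m_C = 10, mu = 0, c_T = 0, c_C = 0, p_T = 5, p_C = 5,
         C_p = 0)
  a <- propensities(net, s)
  expect_true(all(a[grepl("association mu", net$labels)] == 0))
  expect_true(all(a[grepl("dissociation c|decay c_", net$labels)] == 0))
  expect_true(all(a >= 0))
  # zero-rate reactions contribute zero propensity anywhere
  net0 <- build_network(cerna_params(kP_plus = 0))
  a0 <- propensities(net0, c(10, 10, 10, 5, 5, 50, 50, 3))
  expect_equal(unname(a0[net0$rate_names == "kP_plus"]), 0)
  expect_error(propensities(net, c(-1, 0, 0, 0, 0, 0, 0, 0)), "non-negative")
})

test_that("drift reproduces the macroscopic rate equations", {
  p <- cerna_params()
  net <- build_network(p)
  # all-zero state: only synthesis fires
  expect_equal(unname(drift(net, rep(0, 8))),
               c(p$b_T, p$b_C, p$beta, 0, 0, 0, 0, 0))
  # decoupled flux balance: zero drift at the closed-form steady state
  netd <- build_network(params_decoupled())
  sd_state <- c(150, 150, 250, 0, 0, 750, 750, 0)
  expect_equal(max(abs(drift(netd, sd_state))), 0)
  # coupled baseline: drift vanishes at the numerically solved steady state
  ss <- solve_steady_state(net)
  expect_lt(max(abs(drift(net, ss$state))), 1e-8)
})

test_that("analytic Jacobian matches central finite differences", {
  coupled <- do.call(update_params,
                     c(list(cerna_params(kappa_T = 7)), ppi_on))
  for (p in list(cerna_params(), coupled)) {
    net <- build_network(p)
    s <- c(m_T = 80, m_C = 120, mu = 40, c_T = 15, c_C = 25, p_T = 300,
           p_C = 500, C_p = 12)
    A <- jacobian_matrix(net, s)
    h <- 1e-4
    for (j in seq_along(s)) {
      sp <- s; sm <- s
      sp[j] <- s[j] + h; sm[j] <- s[j] - h
      num <- (drift(net, sp) - drift(net, sm)) / (2 * h)
      expect_equal(unname(A[, j]), unname(num), tolerance = 1e-6)
    }
  }
  # decoupled network: no cross-derivatives between the three chains
  Ad <- jacobian_matrix(build_network(params_decoupled()),
                        c(150, 150, 250, 0, 0, 750, 750, 0))
  expect_equal(Ad["m_T", "mu"], 0)
  expect_equal(Ad["m_C", "m_T"], 0)
  expect_equal(Ad["p_T", "m_C"], 0)
})

test_that("diffusion matrix is the propensity-weighted outer-product sum", {
  p <- cerna_params()
  net <- build_network(p)
  s <- c(m_T = 80, m_C = 120, mu = 40, c_T = 15, c_C = 25, p_T = 300,
         p_C = 500, C_p = 12)
  G <- diffusion_matrix(net, s)
  # brute-force oracle: sum over reactions of a_r * s_r s_r^T
  a <- propensities(net, s)
  Gref <- matrix(0, 8, 8)
  for (r in seq_along(a)) {
    v <- net$stoich[, r]
    Gref <- Gref + a[r] * (v %o% v)
  }
  expect_equal(unname(G), unname(Gref))
  expect_equal(G, t(G))
  expect_true(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values >
                  -1e-8 * sum(diag(G))))
  # association reaction contribution carries the (-1,-1,+1) outer product
  only_bind <- cerna_params(b_T = 0, b_C = 0, beta = 0, d_T = 0, d_C = 0,
                            delta = 0, kminus_T = 0, kminus_C = 0,
                            sigma_T = 0, sigma_C = 0, kappa_T = 0,
                            kappa_C = 0, alpha_T = 0, alpha_C = 0,
                            deltap_T = 0, deltap_C = 0, kplus_C = 0)
  nb <- build_network(only_bind)
  Gb <- diffusion_matrix(nb, s)
  flux <- only_bind$kplus_T * s[["mu"]] * s[["m_T"]]
  expect_equal(Gb["m_T", "m_T"], flux)
  expect_equal(Gb["mu", "mu"], flux)
  expect_equal(Gb["c_T", "c_T"], flux)
  expect_equal(Gb["m_T", "mu"], flux)
  expect_equal(Gb["m_T", "c_T"], -flux)
  # birth-death at its steady state: Gamma = [2 b]
  bd <- build_network(params_birth_death(b = 10, d = 0.1))
  Gbd <- diffusion_matrix(bd, c(100, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(Gbd["m_T", "m_T"], 20)
  expect_equal(sum(abs(Gbd)), 20)
})

test_that("binding-only and PPI-only dynamics conserve their totals", {
  # only association/dissociation active: mu + c_T + c_C is invariant
  p <- cerna_params(b_T = 0, b_C = 0, beta = 0, d_T = 0, d_C = 0, delta = 0,
                    sigma_T = 0, sigma_C = 0, kappa_T = 0, kappa_C = 0,
                    alpha_T = 0, alpha_C = 0, deltap_T = 0, deltap_C = 0)
  net <- build_network(p)
  tr <- simulate_ssa(net, initial = c(30, 20, 25, 0, 0, 0, 0, 0),
                     t_end = 50, seed = 11, record_interval = 0.1)
  tot <- tr$states[, "mu"] + tr$states[, "c_T"] + tr$states[, "c_C"]
  expect_true(all(tot == 25))
  # only protein complexation active: p_T + C_p and p_C + C_p invariant
  q <- cerna_params(b_T = 0, b_C = 0, beta = 0, d_T = 0, d_C = 0, delta = 0,
                    kplus_T = 0, kplus_C = 0, alpha_T = 0, alpha_C = 0,
                    deltap_T = 0, deltap_C = 0, kP_plus = 0.01,
                    kP_minus = 0.005, deltap_P = 0)
  netq <- build_network(q)
  trq <- simulate_ssa(netq, initial = c(0, 0, 0, 0, 0, 40, 25, 0),
                      t_end = 50, seed = 12, record_interval = 0.1)
  expect_true(all(trq$states[, "p_T"] + trq$states[, "C_p"] == 40))
  expect_true(all(trq$states[, "p_C"] + trq$states[, "C_p"] == 25))
})

test_that("dynamic species detection drops frozen modules", {
  dyn <- dynamic_species(build_network(cerna_params()))  # PPI off
  expect_equal(dyn, 1:7)
  dyn_all <- dynamic_species(build_network(
    do.call(update_params, c(list(cerna_params()), ppi_on))))
  expect_equal(dyn_all, 1:8)
})
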