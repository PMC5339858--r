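#' Pearson correlations along a b_T sweep
#'
#' Stationary Pearson coefficients of selected species pairs as a function
#' of the target transcription rate, reported against the mean target
#' protein level (the natural x-axis for correlation-pattern plots). LNA
#' mode is analytic; SSA mode estimates the correlations from one seeded
#' trajectory per grid point.
#'
#' @param params a [cerna_params()] object.
#' @param pairs list of length-2 character vectors of species names;
#'   default the transcript pair and the protein pair.
#' @param grid strictly increasing b_T values.
#' @param estimator `"lna"` or `"ssa"`.
#' @param seed base seed (SSA mode).
#' @param t_end,burn_in SSA budget per point (min).
#' @return Data frame with columns `b_T`, `mean_p_T`, then one
#'   `rho_<a>_<b>` column per pair; attribute `provenance`.
#' @export
pearson_sweep <- function(params,
                          pairs = list(c("m_T", "m_C"), c("p_T", "p_C")),
                          grid = seq(0, 60, by = 2),
                          estimator = c("lna", "ssa"), seed = 1L,
                          t_end = 3500, burn_in = 500) {
  estimator <- match.arg(estimator)
  params <- validate_params(params)
  .check_grid(grid, params)
  cn <- vapply(pairs, function(pr) paste0("rho_", pr[1], "_", pr[2]),
               character(1))
  guess <- NULL
  rows <- lapply(seq_along(grid), function(i) {
    pt <- update_params(params, b_T = grid[i])
    row <- stats::setNames(rep(NA_real_, 2 + length(pairs)),
                           c("b_T", "mean_p_T", cn))
    row[["b_T"]] <- grid[i]
    if (estimator == "lna") {
      s <- lna_summary(pt, guess = guess)
      guess <<- s$steady$state
      row[["mean_p_T"]] <- s$steady$state[["p_T"]]
      P <- s$lna$pearson
      for (k in seq_along(pairs)) {
        pr <- pairs[[k]]
        if (all(pr %in% rownames(P))) row[[cn[k]]] <- P[pr[1], pr[2]]
      }
    } else {
      net <- build_network(pt)
      tr <- simulate_ssa(net, t_end = t_end, seed = as.integer(seed) + i)
      sm <- stationary_summary(tr, burn_in = burn_in)
      row[["mean_p_T"]] <- sm$mean[["p_T"]]
      for (k in seq_along(pairs)) {
        pr <- pairs[[k]]
        row[[cn[k]]] <- sm$pearson[pr[1], pr[2]]
      }
    }
    as.data.frame(as.list(row))
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- toupper(estimator)
  out
}

#' Scenario configuration
#'
#' Bundles everything one of the canonical analyses needs: the scenario
#' name, parameter overrides on top of [cerna_params()] defaults, the b_T
#' grid, the estimator and SSA budget, and explicit seeds.
#'
#' @param name one of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`,
#'   `"custom"` (the figure names label the five canonical result families:
#'   crossover and CV curves; circuit CV comparison with capacity and
#'   derepression vs competitor binding; recycling; Pearson sign reversal;
#'   complex-channel capacity map).
#' @param overrides named list of [cerna_params()] replacements.
#' @param grid b_T grid (molecules/min).
#' @param estimator `"lna"` or `"ssa"`.
#' @param seed integer seed.
#' @param t_end,burn_in SSA budget (min).
#' @param out_dir optional output directory; when given, [run_scenario()]
#'   writes CSV tables and a metadata JSON there.
#' @return A `cerna_scenario_config` list.
#' @export
scenario_config <- function(name = c("fig2", "fig3", "fig4", "fig5", "fig6",
                                     "custom"),
                            overrides = list(),
                            grid = seq(0, 60, by = 2),
                            estimator = c("lna", "ssa"),
                            seed = 1L, t_end = 3500, burn_in = 500,
                            out_dir = NULL) {
  name <- match.arg(name)
  estimator <- match.arg(estimator)
  base <- cerna_params()
  if (length(overrides)) base <- do.call(update_params, c(list(base), overrides))
  cfg <- list(name = name, params = base, overrides = overrides, grid = grid,
              estimator = estimator, seed = as.integer(seed), t_end = t_end,
              burn_in = burn_in, out_dir = out_dir)
  .check_grid(grid, base)
  class(cfg) <- "cerna_scenario_config"
  cfg
}

.meta <- function(cfg, extra = list()) {
  c(list(name = cfg$name, params = unclass(cfg$params),
         overrides = cfg$overrides, grid = cfg$grid,
         estimator = cfg$estimator, seed = cfg$seed,
         t_end = cfg$t_end, burn_in = cfg$burn_in,
         package_version = as.character(utils::packageVersion("cernanoise"))),
    extra)
}

#' Run a canonical scenario
#'
#' Executes one of the five result families on the configured parameters and
#' budget and returns (optionally writes) its tables:
#'
#' * `fig2`: mean and CV of `p_T` (and the competitor protein) vs `b_T` for
#'   a miRNA-only circuit at several target binding strengths, and for the
#'   ceRNA circuit.
#' * `fig3`: CV-vs-mean curves for unregulated / miRNA-only / ceRNA
#'   circuits; capacity `I_max(p_T, b_T)` and derepression size `Delta_C`
#'   as functions of the competitor binding strength `kplus_C`.
#' * `fig4`: CV-vs-mean curves at slow (`kappa_T = 0.001`) vs fast
#'   (`kappa_T = 7`) catalytic complex decay, for the ceRNA and miRNA-only
#'   circuits, with the maximal matched-mean CV reduction of each.
#' * `fig5`: Pearson(m_T, m_C) and Pearson(p_T, p_C) vs mean target protein
#'   for competition-only, PPI-only and competition+PPI circuits.
#' * `fig6`: capacity `I_max(C_p, b_T)` over a (kplus_T, kplus_C) grid at
#'   fixed output range.
#' * `custom`: response curve, stationary Pearson sweep and capacity at the
#'   configured parameters.
#'
#' If `cfg$out_dir` is set, every table is written as CSV and a metadata
#' JSON embedding the fully resolved parameters and seeds is placed
#' alongside.
#'
#' @param cfg a [scenario_config()].
#' @return A named list of data frames / scalars (scenario dependent), with
#'   attribute `meta`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "cerna_scenario_config"))
  res <- switch(cfg$name,
                fig2 = .scenario_fig2(cfg),
                fig3 = .scenario_fig3(cfg),
                fig4 = .scenario_fig4(cfg),
                fig5 = .scenario_fig5(cfg),
                fig6 = .scenario_fig6(cfg),
                custom = .scenario_custom(cfg))
  attr(res, "meta") <- .meta(cfg)
  if (!is.null(cfg$out_dir)) .write_scenario(res, cfg)
  res
}

.sweep <- function(cfg, params, observable) {
  response_sweep(params, observable, grid = cfg$grid,
                 estimator = cfg$estimator, seed = cfg$seed,
                 t_end = cfg$t_end, burn_in = cfg$burn_in)
}

.scenario_fig2 <- function(cfg) {
  kplus_values <- c(0.002, 0.01, 0.05, 0.25)
  mirna <- lapply(kplus_values, function(k) {
    p <- update_params(cfg$params, kplus_T = k, kplus_C = 0)
    cbind(.sweep(cfg, p, "p_T"), kplus_T = k)
  })
  ce <- update_params(cfg$params, kplus_T = 0.05, kplus_C = 0.05)
  list(mirna_only = do.call(rbind, mirna),
       cerna_p_T = .sweep(cfg, ce, "p_T"),
       cerna_p_C = .sweep(cfg, ce, "p_C"),
       cerna_m_C = .sweep(cfg, ce, "m_C"))
}

.scenario_fig3 <- function(cfg, kplus_C_grid = 10^seq(-4, 0, length.out = 9)) {
  unreg <- update_params(cfg$params, kplus_T = 0, kplus_C = 0)
  mirna <- update_params(cfg$params, kplus_C = 0)
  cerna <- cfg$params
  cvs <- list(unregulated = .sweep(cfg, unreg, "p_T"),
              mirna_only = .sweep(cfg, mirna, "p_T"),
              cerna = .sweep(cfg, cerna, "p_T"))
  cap <- lapply(seq_along(kplus_C_grid), function(i) {
    p <- update_params(cfg$params, kplus_C = kplus_C_grid[i])
    curve <- .sweep(cfg, p, "p_T")
    mC <- .sweep(cfg, p, "m_C")
    est <- estimate_capacity(curve, seed = cfg$seed + i)
    data.frame(kplus_C = kplus_C_grid[i], I_max = est$I_max,
               I_sna = est$I_sna, delta_C = derepression_size(mC))
  })
  c(cvs, list(capacity_vs_kplus_C = do.call(rbind, cap)))
}

.scenario_fig4 <- function(cfg) {
  run_pair <- function(p) {
    slow <- .sweep(cfg, update_params(p, kappa_T = 0.001), "p_T")
    fast <- .sweep(cfg, update_params(p, kappa_T = 7.0), "p_T")
    list(slow = slow, fast = fast,
         reduction = cv_reduction_at_matched_mean(slow, fast))
  }
  ce <- run_pair(cfg$params)
  mi <- run_pair(update_params(cfg$params, kplus_C = 0))
  list(cerna_slow = ce$slow, cerna_fast = ce$fast,
       mirna_slow = mi$slow, mirna_fast = mi$fast,
       reduction = data.frame(
         circuit = c("cerna", "mirna_only"),
         max_reduction_pct = c(ce$reduction$max_reduction_pct,
                               mi$reduction$max_reduction_pct),
         at_mean = c(ce$reduction$at_mean, mi$reduction$at_mean)))
}

.scenario_fig5 <- function(cfg) {
  ppi <- list(kP_plus = 0.002, kP_minus = 0.001, deltap_P = 0.1)
  comp_only <- update_params(cfg$params, kP_plus = 0, kP_minus = 0,
                             deltap_P = 0)
  ppi_only <- do.call(update_params,
                      c(list(update_params(cfg$params, kplus_T = 0,
                                           kplus_C = 0)), ppi))
  both <- do.call(update_params, c(list(cfg$params), ppi))
  sw <- function(p) pearson_sweep(p, grid = cfg$grid,
                                  estimator = cfg$estimator, seed = cfg$seed,
                                  t_end = cfg$t_end, burn_in = cfg$burn_in)
  list(competition_only = sw(comp_only), ppi_only = sw(ppi_only),
       competition_ppi = sw(both))
}

.scenario_fig6 <- function(cfg,
                           kplus_T_grid = 10^seq(-3, -1, length.out = 5),
                           kplus_C_grid = 10^seq(-3, -1, length.out = 5)) {
  base <- update_params(cfg$params, kP_plus = 0.002, kP_minus = 0.001,
                        deltap_P = 0.1)
  # fixed output window: the C_p range realized at the reference point
  ref <- update_params(base, kplus_T = 0.05, kplus_C = 0.05)
  ref_curve <- .sweep(cfg, ref, "C_p")
  o_range <- range(ref_curve$mean[ref_curve$ok], na.rm = TRUE)
  o_range <- o_range + c(-3, 3) * max(ref_curve$sd[ref_curve$ok], na.rm = TRUE)
  o_range[1] <- max(o_range[1], 0)
  rows <- list()
  for (i in seq_along(kplus_T_grid)) for (j in seq_along(kplus_C_grid)) {
    p <- update_params(base, kplus_T = kplus_T_grid[i],
                       kplus_C = kplus_C_grid[j])
    curve <- .sweep(cfg, p, "C_p")
    est <- tryCatch(
      estimate_capacity(curve, seed = cfg$seed + 100 * i + j,
                        o_range = o_range),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      kplus_T = kplus_T_grid[i], kplus_C = kplus_C_grid[j],
      I_max = if (is.null(est)) NA_real_ else est$I_max,
      I_sna = if (is.null(est)) NA_real_ else est$I_sna)
  }
  list(capacity_map = do.call(rbind, rows),
       o_range = data.frame(o_min = o_range[1], o_max = o_range[2]))
}

.scenario_custom <- function(cfg) {
  curve <- .sweep(cfg, cfg$params, "p_T")
  cap <- tryCatch(estimate_capacity(curve, seed = cfg$seed),
                  error = function(e) NULL)
  list(response_p_T = curve,
       pearson = pearson_sweep(cfg$params, grid = cfg$grid,
                               estimator = cfg$estimator, seed = cfg$seed,
                               t_end = cfg$t_end, burn_in = cfg$burn_in),
       capacity = data.frame(
         I_max = if (is.null(cap)) NA_real_ else cap$I_max,
         I_sna = if (is.null(cap)) NA_real_ else cap$I_sna))
}

.write_scenario <- function(res, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res)) {
    x <- res[[nm]]
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(cfg$out_dir,
                                    paste0(cfg$name, "_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(.meta(cfg),
                       file.path(cfg$out_dir, paste0(cfg$name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
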