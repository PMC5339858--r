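#' Species labels of the network
#'
#' Fixed ordering used by every matrix and serialized output:
#' `m_T`, `m_C` (free ceRNAs), `mu` (free miRNA), `c_T`, `c_C`
#' (miRNA:ceRNA complexes), `p_T`, `p_C` (free proteins), `C_p`
#' (protein complex).
#'
#' @return Character vector of length 8.
#' @export
cerna_species <- function() {
  c("m_T", "m_C", "mu", "c_T", "c_C", "p_T", "p_C", "C_p")
}

# Reaction table: one row per elementary mass-action reaction.
# rate: name of the rate constant in cerna_params.
# reactants: species whose counts multiply the rate constant (mass action);
#   all reactions here are zeroth, first or second order with distinct
#   reactant species (no homodimerisation).
.reaction_table <- function() {
  sp <- cerna_species()
  n <- length(sp)
  mk <- function(rate, reactants, changes, label) {
    s <- integer(n); names(s) <- sp
    for (nm in names(changes)) s[[nm]] <- changes[[nm]]
    list(rate = rate, reactants = match(reactants, sp), stoich = s, label = label)
  }
  list(
    mk("b_T",      character(), list(m_T = 1L),                       "synthesis m_T"),
    mk("b_C",      character(), list(m_C = 1L),                       "synthesis m_C"),
    mk("beta",     character(), list(mu = 1L),                        "synthesis mu"),
    mk("d_T",      "m_T",       list(m_T = -1L),                      "decay m_T"),
    mk("d_C",      "m_C",       list(m_C = -1L),                      "decay m_C"),
    mk("delta",    "mu",        list(mu = -1L),                       "decay mu"),
    mk("kplus_T",  c("mu", "m_T"), list(mu = -1L, m_T = -1L, c_T = 1L), "association mu+m_T -> c_T"),
    mk("kplus_C",  c("mu", "m_C"), list(mu = -1L, m_C = -1L, c_C = 1L), "association mu+m_C -> c_C"),
    mk("kminus_T", "c_T",       list(c_T = -1L, mu = 1L, m_T = 1L),   "dissociation c_T -> mu+m_T"),
    mk("kminus_C", "c_C",       list(c_C = -1L, mu = 1L, m_C = 1L),   "dissociation c_C -> mu+m_C"),
    mk("sigma_T",  "c_T",       list(c_T = -1L),                      "stoichiometric decay c_T"),
    mk("sigma_C",  "c_C",       list(c_C = -1L),                      "stoichiometric decay c_C"),
    mk("kappa_T",  "c_T",       list(c_T = -1L, mu = 1L),             "catalytic decay c_T (miRNA recycled)"),
    mk("kappa_C",  "c_C",       list(c_C = -1L, mu = 1L),             "catalytic decay c_C (miRNA recycled)"),
    mk("alpha_T",  "m_T",       list(p_T = 1L),                       "translation m_T -> m_T+p_T"),
    mk("alpha_C",  "m_C",       list(p_C = 1L),                       "translation m_C -> m_C+p_C"),
    mk("deltap_T", "p_T",       list(p_T = -1L),                      "decay p_T"),
    mk("deltap_C", "p_C",       list(p_C = -1L),                      "decay p_C"),
    mk("kP_plus",  c("p_T", "p_C"), list(p_T = -1L, p_C = -1L, C_p = 1L), "association p_T+p_C -> C_p"),
    mk("kP_minus", "C_p",       list(C_p = -1L, p_T = 1L, p_C = 1L),  "dissociation C_p -> p_T+p_C"),
    mk("deltap_P", "C_p",       list(C_p = -1L),                      "decay C_p")
  )
}

#' Build the mass-action reaction network
#'
#' Assembles the 21 elementary reactions of the model (transcription and
#' decay of the two ceRNAs and the miRNA; reversible miRNA--ceRNA binding;
#' stoichiometric and catalytic complex decay; translation; protein decay;
#' reversible protein-complex formation and complex decay) into a
#' stoichiometry matrix plus mass-action propensity definitions. Reactions
#' whose rate constant is zero are kept in the table and contribute zero
#' propensity everywhere.
#'
#' @param params a [cerna_params()] object.
#' @return An object of class `cerna_network` with elements
#'   `species` (labels), `stoich` (8 x 21 integer matrix; column r is the
#'   state change of reaction r), `rates` (numeric vector of rate constants),
#'   `reactants` (list of reactant species indices per reaction),
#'   `labels` (human-readable reaction descriptions) and `params`.
#' @examples
#' net <- build_network(cerna_params())
#' dim(net$stoich)      # 8 species x 21 reactions
#' @export
build_network <- function(params) {
  params <- validate_params(params)
  tab <- .reaction_table()
  sp <- cerna_species()
  stoich <- vapply(tab, function(r) r$stoich, integer(length(sp)))
  rownames(stoich) <- sp
  net <- list(
    species   = sp,
    stoich    = stoich,
    rates     = vapply(tab, function(r) params[[r$rate]], numeric(1)),
    rate_names = vapply(tab, function(r) r$rate, character(1)),
    reactants = lapply(tab, function(r) r$reactants),
    labels    = vapply(tab, function(r) r$label, character(1)),
    params    = params
  )
  colnames(net$stoich) <- net$rate_names
  class(net) <- "cerna_network"
  net
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("cerna_network:", length(x$species), "species,", length(x$rates),
      "mass-action reactions (", sum(x$rates > 0), "with nonzero rate )\n")
  invisible(x)
}

.check_state <- function(network, state) {
  if (length(state) != length(network$species)) {
    stop("state must have ", length(network$species), " components (",
         paste(network$species, collapse = ", "), ")")
  }
  state <- as.numeric(state)
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state components must be finite and non-negative")
  }
  names(state) <- network$species
  state
}

#' Mass-action propensities
#'
#' Evaluates each reaction's propensity, rate constant times the product of
#' its reactant copy numbers, at a given state.
#'
#' @param network a `cerna_network`.
#' @param state numeric vector of 8 non-negative copy numbers, ordered as
#'   [cerna_species()].
#' @return Numeric vector of 21 non-negative propensities.
#' @export
propensities <- function(network, state) {
  state <- .check_state(network, state)
  a <- network$rates
  for (r in seq_along(a)) {
    for (i in network$reactants[[r]]) a[r] <- a[r] * state[i]
  }
  names(a) <- network$labels
  a
}

#' Deterministic drift (macroscopic rate equations)
#'
#' Rate of change of each species' mean copy number,
#' `sum_r stoich[, r] * a_r(state)` -- the right-hand side of the
#' deterministic rate equations of the network.
#'
#' @inheritParams propensities
#' @return Named numeric vector of length 8 (molecules/min).
#' @export
drift <- function(network, state) {
  a <- propensities(network, state)
  d <- as.numeric(network$stoich %*% a)
  names(d) <- network$species
  d
}

#' Jacobian of the drift
#'
#' Closed-form derivative matrix `A[i, j] = d drift_i / d x_j` of the
#' mass-action rate equations, evaluated at `state`. This is the matrix
#' whose eigenvalues determine local stability and which enters the Linear
#' Noise Approximation.
#'
#' @inheritParams propensities
#' @return 8 x 8 numeric matrix with species labels on both dimensions.
#' @export
jacobian_matrix <- function(network, state) {
  state <- .check_state(network, state)
  n <- length(network$species)
  m <- length(network$rates)
  # dA[r, j] = d a_r / d x_j: for a_r = c * prod(x_i over reactants),
  # derivative w.r.t. reactant j is c * prod of the other reactants.
  dA <- matrix(0, m, n)
  for (r in seq_len(m)) {
    re <- network$reactants[[r]]
    for (j in re) {
      dA[r, j] <- network$rates[r] * prod(state[setdiff(re, j)])
    }
  }
  A <- network$stoich %*% dA
  dimnames(A) <- list(network$species, network$species)
  A
}

#' LNA diffusion matrix
#'
#' The diffusion matrix of the Linear Noise Approximation,
#' `Gamma = sum_r a_r(state) * s_r s_r^T` with `s_r` the stoichiometric
#' change vector of reaction r; for a mass-action network this is the
#' variance of the white noise driving the linearized fluctuation dynamics.
#'
#' @inheritParams propensities
#' @return Symmetric positive semidefinite 8 x 8 matrix.
#' @export
diffusion_matrix <- function(network, state) {
  a <- propensities(network, state)
  S <- network$stoich
  G <- S %*% (a * t(S))
  G <- (G + t(G)) / 2
  dimnames(G) <- list(network$species, network$species)
  G
}

#' Dynamic species of a network
#'
#' Indices of species touched by at least one reaction with a nonzero rate
#' constant. Species outside this set are frozen (their copy number never
#' changes); steady-state solving and the LNA operate on the dynamic subset
#' only, which keeps the Jacobian non-singular when e.g. the protein-complex
#' module is switched off.
#'
#' @param network a `cerna_network`.
#' @return Integer vector of species indices.
#' @export
dynamic_species <- function(network) {
  active <- network$rates > 0
  unname(which(apply(network$stoich[, active, drop = FALSE] != 0, 1, any)))
}

#' Export a labelled matrix as CSV
#'
#' Writes a species-by-species matrix (Jacobian, diffusion, covariance) with
#' species labels as header and first column.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
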