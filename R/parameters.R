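#' Kinetic parameters of the miRNA--ceRNA--protein network
#'
#' Construct the full rate-constant set of the model: one miRNA (`mu`)
#' negatively regulating two ceRNAs (`m_T`, the target, and `m_C`, the
#' competitor) through reversible binding into complexes `c_T`, `c_C`; the
#' complexes are processed either stoichiometrically (both molecules
#' destroyed) or catalytically (ceRNA cleaved, miRNA recycled); each free
#' ceRNA is translated into a protein (`p_T`, `p_C`) and the two proteins can
#' associate into a binary complex `C_p`.
#'
#' Defaults are the baseline parameter set used throughout the package's
#' scenario analyses: transcription and decay rates give free-species levels
#' of a few hundred molecules, complex processing is dominated by
#' stoichiometric decay (`sigma` = 1/min against `kminus` = `kappa` =
#' 0.001/min), and the protein-complex module is off (`kP_plus` = 0). The
#' miRNA--ceRNA association rates default to 0.05 /molecule/min, which puts
#' the target's repressed-to-free crossover inside the input range
#' `[bT_min, bT_max]` (see the package vignette for how this was chosen).
#'
#' @param b_T target transcription rate (molecules/min); the input variable,
#'   constrained to `[bT_min, bT_max]`.
#' @param b_C competitor transcription rate (molecules/min).
#' @param beta miRNA transcription rate (molecules/min).
#' @param d_T,d_C free ceRNA decay rates (1/min).
#' @param delta free miRNA decay rate (1/min).
#' @param kplus_T,kplus_C miRNA--ceRNA association rates (1/(molecule min)).
#' @param kminus_T,kminus_C complex dissociation rates (1/min).
#' @param sigma_T,sigma_C stoichiometric complex decay rates (1/min); both the
#'   miRNA and the ceRNA bound in the complex are destroyed.
#' @param kappa_T,kappa_C catalytic complex decay rates (1/min); the ceRNA is
#'   cleaved and the miRNA returns to the free pool.
#' @param alpha_T,alpha_C translation rates (molecules/min per mRNA).
#' @param deltap_T,deltap_C free protein decay rates (1/min).
#' @param kP_plus protein-complex association rate (1/(molecule min)).
#' @param kP_minus protein-complex dissociation rate (1/min).
#' @param deltap_P protein-complex decay rate (1/min).
#' @param bT_min,bT_max bounds of the input variable `b_T` (molecules/min).
#'
#' @return An object of class `cerna_params`: a named list of the rates above.
#' @examples
#' p <- cerna_params(b_T = 15)
#' p$beta / p$delta   # free miRNA level when unbound: 250 molecules
#' @export
cerna_params <- function(b_T = 15, b_C = 15, beta = 25,
                         d_T = 0.1, d_C = 0.1, delta = 0.1,
                         kplus_T = 0.05, kplus_C = 0.05,
                         kminus_T = 0.001, kminus_C = 0.001,
                         sigma_T = 1, sigma_C = 1,
                         kappa_T = 0.001, kappa_C = 0.001,
                         alpha_T = 0.5, alpha_C = 0.5,
                         deltap_T = 0.1, deltap_C = 0.1,
                         kP_plus = 0, kP_minus = 0, deltap_P = 0,
                         bT_min = 0, bT_max = 60) {
  p <- list(b_T = b_T, b_C = b_C, beta = beta,
            d_T = d_T, d_C = d_C, delta = delta,
            kplus_T = kplus_T, kplus_C = kplus_C,
            kminus_T = kminus_T, kminus_C = kminus_C,
            sigma_T = sigma_T, sigma_C = sigma_C,
            kappa_T = kappa_T, kappa_C = kappa_C,
            alpha_T = alpha_T, alpha_C = alpha_C,
            deltap_T = deltap_T, deltap_C = deltap_C,
            kP_plus = kP_plus, kP_minus = kP_minus, deltap_P = deltap_P,
            bT_min = bT_min, bT_max = bT_max)
  p <- lapply(p, as.numeric)
  class(p) <- "cerna_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks that every rate constant is a finite non-negative scalar and that
#' the input-variable bounds are ordered. Called by [cerna_params()] and by
#' every entry point that accepts user-supplied parameters.
#'
#' @param params a `cerna_params` object or named list with the same fields.
#' @return The validated `cerna_params` object, invisibly usable downstream.
#' @export
validate_params <- function(params) {
  fields <- names(formals(cerna_params))
  if (!all(fields %in% names(params))) {
    stop("missing parameter field(s): ",
         paste(setdiff(fields, names(params)), collapse = ", "))
  }
  extra <- setdiff(names(params), fields)
  if (length(extra)) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "))
  }
  for (nm in fields) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar")
    }
    if (v < 0) stop("parameter '", nm, "' is negative (", v, "); all rates must be >= 0")
  }
  if (params$bT_min > params$bT_max) stop("bT_min exceeds bT_max")
  if (!inherits(params, "cerna_params")) class(params) <- "cerna_params"
  params
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named rates replaced; unknown names or
#' negative values are rejected.
#'
#' @param params a `cerna_params` object.
#' @param ... named replacements, e.g. `kplus_C = 0, kappa_T = 7`.
#' @return A validated `cerna_params` object.
#' @examples
#' base <- cerna_params()
#' mirna_only <- update_params(base, kplus_C = 0)
#' @export
update_params <- function(params, ...) {
  params <- validate_params(params)
  dots <- list(...)
  if (length(dots) == 0L) return(params)
  if (is.null(names(dots)) || any(names(dots) == "")) {
    stop("all replacements must be named")
  }
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown)) stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) params[[nm]] <- as.numeric(dots[[nm]])
  validate_params(params)
}

#' Read / write parameters as a flat key-value config file
#'
#' The on-disk format is flat YAML whose keys are exactly the field names of
#' [cerna_params()]. Keys that are absent take the package defaults; unknown
#' keys are an error.
#'
#' @param path file path.
#' @param params a `cerna_params` object (for writing).
#' @return `read_params()` returns a validated `cerna_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a flat key-value mapping")
  unknown <- setdiff(names(raw), names(formals(cerna_params)))
  if (length(unknown)) stop("unknown parameter key(s) in config: ",
                            paste(unknown, collapse = ", "))
  do.call(cerna_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- validate_params(params)
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @export
print.cerna_params <- function(x, ...) {
  cat("miRNA-ceRNA-protein kinetic parameters (units: molecules/min, 1/min, 1/(molecule min))\n")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}
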