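#' Deterministic steady state of the network
#'
#' Solves `drift(x) = 0` for the dynamic species by damped Newton iteration
#' with the analytic Jacobian, started from the decoupled closed form
#' (each birth--death chain balanced independently, complexes empty) or from
#' a user-supplied guess. If Newton stalls, the rate equations are first
#' relaxed by numerical integration (`deSolve::lsoda`) and Newton is
#' restarted from the relaxed state. Species untouched by any nonzero-rate
#' reaction are frozen at their guess value (zero by default).
#'
#' @param network a [build_network()] object.
#' @param guess optional initial state (length 8).
#' @param tol convergence tolerance on the infinity norm of the drift
#'   (molecules/min).
#' @param max_iter maximum Newton iterations.
#' @return An object of class `cerna_steady_state`: list with `state`
#'   (named length-8 vector), `residual` (infinity norm of the drift),
#'   `converged` (logical) and `dynamic` (indices of dynamic species).
#' @examples
#' net <- build_network(cerna_params(kplus_T = 0, kplus_C = 0))
#' solve_steady_state(net)$state[["m_T"]]   # b_T / d_T = 150
#' @export
solve_steady_state <- function(network, guess = NULL, tol = 1e-9,
                               max_iter = 200L) {
  stopifnot(inherits(network, "cerna_network"))
  p <- network$params
  if (is.null(guess)) {
    guess <- c(m_T = p$b_T / p$d_T, m_C = p$b_C / p$d_C, mu = p$beta / p$delta,
               c_T = 0, c_C = 0,
               p_T = p$alpha_T * p$b_T / (p$d_T * max(p$deltap_T, 1e-12)),
               p_C = p$alpha_C * p$b_C / (p$d_C * max(p$deltap_C, 1e-12)),
               C_p = 0)
    guess[!is.finite(guess)] <- 0
  }
  x <- .check_state(network, guess)
  dyn <- dynamic_species(network)
  if (length(dyn) == 0L) {
    out <- list(state = x, residual = 0, converged = TRUE, dynamic = dyn)
    class(out) <- "cerna_steady_state"
    return(out)
  }

  newton <- function(x) {
    for (it in seq_len(max_iter)) {
      f <- drift(network, x)[dyn]
      res <- max(abs(f))
      if (res < tol) return(list(x = x, residual = res, converged = TRUE))
      A <- jacobian_matrix(network, x)[dyn, dyn, drop = FALSE]
      step <- tryCatch(solve(A, -f), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, residual = res, converged = FALSE))
      lambda <- 1
      improved <- FALSE
      for (k in 1:30) {
        xn <- x
        xn[dyn] <- pmax(x[dyn] + lambda * step, 0)
        rn <- max(abs(drift(network, xn)[dyn]))
        if (rn < res) { x <- xn; improved <- TRUE; break }
        lambda <- lambda / 2
      }
      if (!improved) return(list(x = x, residual = res, converged = FALSE))
    }
    list(x = x, residual = max(abs(drift(network, x)[dyn])), converged = FALSE)
  }

  sol <- newton(x)
  if (!sol$converged || sol$residual >= tol) {
    # relax by ODE integration, then polish
    rhs <- function(t, y, parms) {
      s <- x
      s[dyn] <- pmax(y, 0)
      list(drift(network, s)[dyn])
    }
    times <- c(0, 10^seq(0, 4, by = 1))
    ode <- deSolve::lsoda(y = x[dyn], times = times, func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-10)
    x2 <- x
    x2[dyn] <- pmax(ode[nrow(ode), -1], 0)
    sol2 <- newton(x2)
    if (sol2$residual < sol$residual) sol <- sol2
  }
  if (!sol$converged) {
    stop("steady-state solve did not converge; residual = ",
         format(sol$residual), " at state (",
         paste(signif(sol$x, 6), collapse = ", "), ")")
  }
  out <- list(state = sol$x, residual = sol$residual, converged = TRUE,
              dynamic = dyn)
  class(out) <- "cerna_steady_state"
  out
}

#' @export
print.cerna_steady_state <- function(x, ...) {
  cat("Deterministic steady state (residual", format(x$residual, digits = 3), "):\n")
  print(round(x$state, 4))
  invisible(x)
}

#' Stationary covariance by the Linear Noise Approximation
#'
#' Solves the stationary Lyapunov equation `A S + S A^T + Gamma = 0` for the
#' fluctuation covariance `S` around a stable steady state, via the
#' Kronecker-product linear system. The eigen-decomposition form of the same
#' solution is available as [lna_covariance_eigen()] and is used as a
#' cross-check; the Lyapunov route is numerically robust to near-degenerate
#' eigenvalues.
#'
#' @param A Jacobian at the steady state (all eigenvalues must have negative
#'   real part).
#' @param Gamma diffusion matrix at the steady state.
#' @param mean optional steady-state means, used to derive CVs.
#' @return An object of class `cerna_lna`: list with `cov` (covariance
#'   matrix), `cv` (named vector, `NA` where the mean is below 1e-9),
#'   `pearson` (correlation matrix), `mean` and `residual` (Lyapunov
#'   residual norm).
#' @export
lna_covariance <- function(A, Gamma, mean = NULL) {
  A <- as.matrix(A); Gamma <- as.matrix(Gamma)
  n <- nrow(A)
  stopifnot(ncol(A) == n, all(dim(Gamma) == n))
  ev <- eigen(A, only.values = TRUE)$values
  bad <- which(Re(ev) >= 0)
  if (length(bad)) {
    stop("steady state is not linearly stable: eigenvalue ",
         format(ev[bad[1]]), " has non-negative real part")
  }
  In <- diag(n)
  K <- In %x% A + A %x% In
  S <- matrix(solve(K, -as.vector(Gamma)), n, n)
  S <- (S + t(S)) / 2
  resid <- max(abs(A %*% S + S %*% t(A) + Gamma))
  sdv <- sqrt(pmax(diag(S), 0))
  P <- S / (sdv %o% sdv)
  P[!is.finite(P)] <- NA_real_
  cv <- rep(NA_real_, n)
  if (!is.null(mean)) {
    cv <- ifelse(mean > 1e-9, sdv / mean, NA_real_)
    names(cv) <- names(mean)
  }
  dimnames(S) <- dimnames(P) <- dimnames(A)
  out <- list(cov = S, cv = cv, pearson = P, mean = mean, residual = resid)
  class(out) <- "cerna_lna"
  out
}

#' Eigen-decomposition form of the stationary LNA covariance
#'
#' Computes `S_ab = sum_kl B_ak B_bl (B^-1 Gamma B^-T)_kl / (-(lambda_k +
#' lambda_l))` from the eigenvectors `B` and eigenvalues `lambda` of the
#' Jacobian. Mathematically identical to the Lyapunov solution of
#' [lna_covariance()]; kept as an independent small-matrix cross-check.
#'
#' @inheritParams lna_covariance
#' @return Covariance matrix (real part).
#' @export
lna_covariance_eigen <- function(A, Gamma) {
  e <- eigen(A)
  B <- e$vectors
  lam <- e$values
  sv <- svd(B)$d
  if (min(sv) / max(sv) < 1e-12) {
    stop("Jacobian is defective or near-degenerate (eigenvector matrix ",
         "numerically singular); use lna_covariance() instead")
  }
  G <- solve(B) %*% Gamma %*% t(solve(B))
  M <- -G / outer(lam, lam, `+`)
  S <- B %*% M %*% t(B)
  S <- Re(S)
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(A)
  S
}

#' Full LNA summary at a parameter point
#'
#' Convenience wrapper: steady state, Jacobian and diffusion on the dynamic
#' species, Lyapunov covariance, CVs and Pearson matrix.
#'
#' @param params a [cerna_params()] object.
#' @param guess optional steady-state guess (warm start).
#' @return List with `steady` (a `cerna_steady_state`), `lna` (a
#'   `cerna_lna` over the dynamic species) and `network`.
#' @export
lna_summary <- function(params, guess = NULL) {
  net <- build_network(params)
  ss <- solve_steady_state(net, guess = guess)
  dyn <- ss$dynamic
  A <- jacobian_matrix(net, ss$state)[dyn, dyn, drop = FALSE]
  G <- diffusion_matrix(net, ss$state)[dyn, dyn, drop = FALSE]
  lna <- lna_covariance(A, G, mean = ss$state[dyn])
  list(steady = ss, lna = lna, network = net)
}

#' LNA response curve of mean and CV over a b_T grid
#'
#' Sweeps the input variable `b_T` over a grid, solving the steady state
#' (warm-started from the previous grid point) and the LNA covariance at each
#' point, and reports the mean, standard deviation and CV of one observable.
#' Grid points where the steady state is unstable or the solve fails are
#' flagged (`ok = FALSE`, NA moments) and the sweep continues.
#'
#' @param params a [cerna_params()] object.
#' @param observable species name, one of [cerna_species()].
#' @param grid numeric vector of b_T values (molecules/min), strictly
#'   increasing, within `[bT_min, bT_max]`.
#' @return A `data.frame` of class `cerna_response` with columns `b_T`,
#'   `mean`, `sd`, `cv`, `ok`; attributes `observable` and
#'   `provenance = "LNA"`.
#' @export
cv_curve <- function(params, observable = "p_T", grid = seq(0, 60, by = 1)) {
  params <- validate_params(params)
  observable <- match.arg(observable, cerna_species())
  .check_grid(grid, params)
  guess <- NULL
  rows <- lapply(grid, function(b) {
    pt <- update_params(params, b_T = b)
    res <- tryCatch({
      s <- lna_summary(pt, guess = guess)
      guess <<- s$steady$state
      m <- s$steady$state[[observable]]
      idx <- match(observable, names(s$lna$mean))
      sdv <- if (!is.na(idx)) sqrt(max(s$lna$cov[idx, idx], 0)) else 0
      data.frame(b_T = b, mean = m, sd = sdv,
                 cv = if (m > 1e-9) sdv / m else NA_real_, ok = TRUE)
    }, error = function(e) {
      data.frame(b_T = b, mean = NA_real_, sd = NA_real_, cv = NA_real_,
                 ok = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "observable") <- observable
  attr(out, "provenance") <- "LNA"
  class(out) <- c("cerna_response", "data.frame")
  out
}

.check_grid <- function(grid, params) {
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 points")
  }
  if (min(grid) < params$bT_min - 1e-9 || max(grid) > params$bT_max + 1e-9) {
    stop("grid must lie within [bT_min, bT_max] = [",
         params$bT_min, ", ", params$bT_max, "]")
  }
  invisible(grid)
}

#' Export a response curve as CSV
#'
#' Columns `b_T`, `mean`, `sd`, `cv` (plus `ok`), with the observable and
#' provenance recorded as comment-free extra columns.
#'
#' @param curve a `cerna_response` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$observable <- attr(curve, "observable")
  df$provenance <- attr(curve, "provenance")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
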