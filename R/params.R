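#' Baseline model parameters
#'
#' Rate set for the baseline multi-strain SI model with two infection stages
#' (acute, chronic), a single treated compartment and within-host mutation.
#' Acute-stage transmissibility is proportional to the chronic one,
#' \eqn{\beta_A = \xi \beta_C}.
#'
#' @param beta_C chronic-stage transmissibility rate (per unit time).
#' @param xi acute/chronic proportionality, dimensionless.
#' @param gamma inverse duration of the acute stage.
#' @param mu mortality / population turnover rate (must be > 0).
#' @param u_T treatment enrollment rate (control).
#' @param A within-host `mutation_matrix`.
#' @return an object of class `c("baseline_params", "multistrain_params")`.
#' @examples
#' A <- neighbor_mutation_matrix(retention_from_frequencies(c(27, 9, 3, 1) / 40, 0.25))
#' p <- baseline_params(beta_C = 0.301, xi = 5, gamma = 3, mu = 0.025, u_T = 0.4, A = A)
#' r0(p)
#' @export
baseline_params <- function(beta_C, xi, gamma, mu, u_T, A) {
  A <- as_mutation_matrix(A)
  check_rate(beta_C, "beta_C"); check_rate(xi, "xi"); check_rate(gamma, "gamma")
  check_rate(mu, "mu"); check_rate(u_T, "u_T")
  if (mu <= 0) stop("mu must be strictly positive", call. = FALSE)
  structure(list(beta_C = beta_C, xi = xi, gamma = gamma, mu = mu, u_T = u_T,
                 A = A, n = nrow(A)),
            class = c("baseline_params", "multistrain_params"))
}

#' Extended model parameters
#'
#' Rate set for the extended model with per-strain transmissibility
#' \eqn{\beta_{Ci}}, strain-specific treatment failure \eqn{\zeta_i} (reversion
#' from treatment to active chronic infection), a prophylaxis compartment with
#' enrollment rate \eqn{u_P}, inverse duration \eqn{\delta} and per-strain
#' protection \eqn{\psi_i \in [0,1]} (\eqn{\psi_i = 1} is full protection).
#'
#' @param beta_C length-n vector of chronic transmissibilities (a scalar is
#'   recycled).
#' @param xi,gamma,mu,u_T as in [baseline_params()].
#' @param u_P prophylaxis enrollment rate (control).
#' @param zeta length-n treatment failure rates.
#' @param psi length-n prophylaxis protection levels in \[0, 1\].
#' @param delta inverse duration of prophylaxis.
#' @param A within-host `mutation_matrix`.
#' @return an object of class `c("extended_params", "multistrain_params")`.
#' @export
extended_params <- function(beta_C, xi, gamma, mu, u_T, u_P, zeta, psi, delta, A) {
  A <- as_mutation_matrix(A)
  n <- nrow(A)
  beta_C <- recycle_n(beta_C, n, "beta_C")
  zeta <- recycle_n(zeta, n, "zeta")
  psi <- recycle_n(psi, n, "psi")
  check_rate(beta_C, "beta_C"); check_rate(xi, "xi"); check_rate(gamma, "gamma")
  check_rate(mu, "mu"); check_rate(u_T, "u_T"); check_rate(u_P, "u_P")
  check_rate(zeta, "zeta"); check_rate(delta, "delta")
  if (mu <= 0) stop("mu must be strictly positive", call. = FALSE)
  if (any(psi < 0) || any(psi > 1))
    stop("psi must lie in [0, 1]", call. = FALSE)
  structure(list(beta_C = beta_C, xi = xi, gamma = gamma, mu = mu, u_T = u_T,
                 u_P = u_P, zeta = zeta, psi = psi, delta = delta, A = A, n = n),
            class = c("extended_params", "multistrain_params"))
}

as_mutation_matrix <- function(A) {
  if (inherits(A, "mutation_matrix")) return(A)
  mutation_matrix(as.matrix(A))
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop(sprintf("%s must be non-negative numeric", name), call. = FALSE)
  invisible(x)
}

recycle_n <- function(x, n, name) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n)
    stop(sprintf("%s must have length 1 or n = %d", name, n), call. = FALSE)
  x
}

#' @export
print.multistrain_params <- function(x, ...) {
  kind <- if (inherits(x, "baseline_params")) "baseline" else "extended"
  cat(sprintf("%s multi-strain SI model, n = %d strains\n", kind, x$n))
  cat(sprintf("  beta_C = %s, xi = %g, gamma = %g, mu = %g, u_T = %g\n",
              paste(format(x$beta_C, digits = 6), collapse = " "),
              x$xi, x$gamma, x$mu, x$u_T))
  if (inherits(x, "extended_params"))
    cat(sprintf("  u_P = %g, delta = %g, zeta = %s, psi = %s\n",
                x$u_P, x$delta, paste(format(x$zeta), collapse = " "),
                paste(format(x$psi), collapse = " ")))
  cat(sprintf("  mutation topology: %s\n", attr(x$A, "topology")))
  invisible(x)
}

#' @export
summary.multistrain_params <- function(object, ...) {
  print(object)
  rep <- r0(object)
  cat(sprintf("  controlled R0 = %.6g\n", rep$value))
  invisible(rep)
}

#' Compartment names for a model state
#'
#' Baseline states are ordered `[I_A1..I_An, I_C1..I_Cn, T, S]`; extended
#' states `[I_A1..I_An, I_C1..I_Cn, T_1..T_n, S, P]`. All I/O and Jacobians
#' use this fixed ordering.
#'
#' @param params a `multistrain_params` object.
#' @return character vector of compartment names.
#' @export
state_names <- function(params) {
  n <- params$n
  base <- c(paste0("I_A", seq_len(n)), paste0("I_C", seq_len(n)))
  if (inherits(params, "baseline_params")) c(base, "T", "S")
  else c(base, paste0("T", seq_len(n)), "S", "P")
}

#' Assemble a model state vector
#'
#' Builds the ordered compartment vector for a model, checking non-negativity
#' and that the components sum to 1 (the state simplex).
#'
#' @param params a `multistrain_params` object.
#' @param I_A,I_C length-n acute and chronic infected fractions.
#' @param T_ treated fraction: scalar for the baseline model, length-n vector
#'   for the extended model.
#' @param S susceptible fraction; if `NULL`, set to the simplex remainder.
#' @param P prophylaxed fraction (extended model only).
#' @return named numeric state vector.
#' @export
model_state <- function(params, I_A = 0, I_C = 0, T_ = 0, S = NULL, P = 0) {
  n <- params$n
  I_A <- recycle_n(I_A, n, "I_A"); I_C <- recycle_n(I_C, n, "I_C")
  extended <- inherits(params, "extended_params")
  T_ <- if (extended) recycle_n(T_, n, "T_") else T_[1]
  P <- if (extended) P[1] else NULL
  partial <- sum(I_A) + sum(I_C) + sum(T_) + sum(P)
  if (is.null(S)) S <- 1 - partial
  x <- c(I_A, I_C, T_, S, P)
  names(x) <- state_names(params)
  if (any(x < -1e-12))
    stop("state components must be non-negative", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8)
    stop(sprintf("state must lie on the simplex (sum = %.8g)", sum(x)),
         call. = FALSE)
  x
}

# split a state vector into named components
split_state <- function(x, params) {
  n <- params$n
  out <- list(I_A = x[seq_len(n)], I_C = x[n + seq_len(n)])
  if (inherits(params, "baseline_params")) {
    out$T_ <- x[2 * n + 1]
    out$S <- x[2 * n + 2]
  } else {
    out$T_ <- x[2 * n + seq_len(n)]
    out$S <- x[3 * n + 1]
    out$P <- x[3 * n + 2]
  }
  out
}

#' Force of infection
#'
#' Per-strain rate at which a susceptible acquires strain i:
#' \eqn{\phi_i = \beta_{Ci} (\xi I_{Ai} + \sum_j \alpha_{ij} I_{Cj})}
#' (in the baseline model all \eqn{\beta_{Ci} = \beta_C}). Acute hosts
#' transmit only the founder strain; chronic hosts transmit the
#' mutation-weighted strain mix.
#'
#' @param state model state vector (fixed ordering, see [state_names()]).
#' @param params a `multistrain_params` object.
#' @return non-negative length-n vector.
#' @export
force_of_infection <- function(state, params) {
  n <- params$n
  if (length(state) != length(state_names(params)))
    stop("state has wrong length for this model", call. = FALSE)
  I_A <- state[seq_len(n)]
  I_C <- state[n + seq_len(n)]
  unname(params$beta_C * (params$xi * I_A + drop(params$A %*% I_C)))
}

#' Model right-hand sides
#'
#' Time derivatives of the compartment fractions. Both systems conserve the
#' total population (`sum(rhs) == 0`) and are essentially non-negative, so the
#' state simplex is forward invariant.
#'
#' @param state model state vector.
#' @param params a `multistrain_params` object.
#' @return named derivative vector of the same length as `state`.
#' @export
rhs_baseline <- function(state, params) {
  if (!inherits(params, "baseline_params"))
    stop("rhs_baseline needs baseline_params", call. = FALSE)
  n <- params$n
  s <- split_state(state, params)
  phi <- force_of_infection(state, params)
  with(params, {
    dI_A <- phi * s$S - (gamma + mu) * s$I_A
    dI_C <- gamma * s$I_A - (u_T + mu) * s$I_C
    dT <- u_T * sum(s$I_C) - mu * s$T_
    dS <- mu - sum(phi) * s$S - mu * s$S
    out <- c(dI_A, dI_C, dT, dS)
    names(out) <- state_names(params)
    out
  })
}

#' @rdname rhs_baseline
#' @export
rhs_extended <- function(state, params) {
  if (!inherits(params, "extended_params"))
    stop("rhs_extended needs extended_params", call. = FALSE)
  s <- split_state(state, params)
  phi <- force_of_infection(state, params)
  with(params, {
    dI_A <- phi * s$S + (1 - psi) * phi * s$P - (gamma + mu) * s$I_A
    dI_C <- gamma * s$I_A + zeta * s$T_ - (u_T + mu) * s$I_C
    dT <- u_T * s$I_C - zeta * s$T_ - mu * s$T_
    dS <- mu - u_P * s$S - sum(phi) * s$S + delta * s$P - mu * s$S
    dP <- u_P * s$S - sum((1 - psi) * phi) * s$P - delta * s$P - mu * s$P
    out <- c(dI_A, dI_C, dT, dS, dP)
    names(out) <- state_names(params)
    out
  })
}

#' @rdname rhs_baseline
#' @export
model_rhs <- function(state, params) {
  if (inherits(params, "baseline_params")) rhs_baseline(state, params)
  else rhs_extended(state, params)
}

#' Collapse an extended parameter set to the baseline model
#'
#' The extended model reduces exactly to the baseline one when all strains
#' share the same transmissibility, treatment never fails and nobody is
#' enrolled into prophylaxis. The collapse refuses (naming the violated
#' condition) otherwise.
#'
#' @param params an `extended_params` object.
#' @return a `baseline_params` object with the shared rates.
#' @export
collapse_extended <- function(params) {
  if (!inherits(params, "extended_params"))
    stop("collapse_extended needs extended_params", call. = FALSE)
  if (diff(range(params$beta_C)) > 0)
    stop("cannot collapse: beta_C is not uniform across strains", call. = FALSE)
  if (any(params$zeta > 0))
    stop("cannot collapse: zeta is not identically zero", call. = FALSE)
  if (params$u_P > 0)
    stop("cannot collapse: u_P is not zero", call. = FALSE)
  baseline_params(beta_C = params$beta_C[1], xi = params$xi,
                  gamma = params$gamma, mu = params$mu, u_T = params$u_T,
                  A = params$A)
}
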