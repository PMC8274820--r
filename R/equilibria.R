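#' Disease-free equilibrium
#'
#' The baseline model has the unique disease-free state with everybody
#' susceptible. In the extended model prophylaxis enrollment shifts the DFE:
#' \eqn{S_{DFE} = (\delta+\mu)/(\delta+\mu+u_P)},
#' \eqn{P_{DFE} = u_P/(\delta+\mu+u_P)}.
#'
#' @param params a `multistrain_params` object.
#' @return named model state vector (a zero of the right-hand side).
#' @export
dfe <- function(params) {
  if (inherits(params, "baseline_params"))
    return(model_state(params, S = 1))
  S <- with(params, (delta + mu) / (delta + mu + u_P))
  model_state(params, S = S, P = 1 - S)
}

#' Endemic equilibrium of the baseline model (closed form)
#'
#' For an irreducible mutation matrix with positive diagonal the baseline
#' system has a unique endemic equilibrium whenever \eqn{R_0 > 1}, with
#' components proportional to the dominant eigenvector \eqn{v} of A:
#' \deqn{I_{Ai}^* = \frac{\mu}{\gamma+\mu}\Big(1-\frac{1}{R_0}\Big) v_i,\quad
#'   I_{Ci}^* = \frac{\gamma\mu}{(\gamma+\mu)(u_T+\mu)}\Big(1-\frac1{R_0}\Big) v_i,}
#' \deqn{T^* = \frac{\gamma u_T}{(\gamma+\mu)(u_T+\mu)}\Big(1-\frac1{R_0}\Big),
#'   \quad S^* = 1/R_0.}
#' The prevalence is \eqn{\Pi = 1 - S^* = (R_0-1)/R_0}, and the chronic
#' compartment satisfies the mixing identity \eqn{I_C^* = A I_C^*}: at
#' equilibrium, the chance of meeting a chronic carrier of strain i equals the
#' chance of catching strain i from a random chronic carrier.
#'
#' @param params a `baseline_params` object with irreducible `A` and R0 > 1.
#' @return an object of class `endemic_equilibrium` with `state`, `R0`,
#'   `prevalence`, `acute_chronic_ratio`, `v`, `source` and `residual`.
#' @export
endemic_baseline <- function(params) {
  if (!inherits(params, "baseline_params"))
    stop("endemic_baseline needs baseline_params", call. = FALSE)
  if (!is_irreducible(params$A))
    stop("mutation matrix is reducible; use endemic_family()", call. = FALSE)
  R0 <- r0(params)$value
  if (R0 < 1 - 1e-12)
    stop(sprintf("no endemic equilibrium: R0 = %.6g <= 1", R0), call. = FALSE)
  v <- dominant_eigenpair(params$A)$v
  frac <- max(0, 1 - 1 / R0)
  st <- with(params, model_state(
    params,
    I_A = mu / (gamma + mu) * frac * v,
    I_C = gamma * mu / ((gamma + mu) * (u_T + mu)) * frac * v,
    T_ = gamma * u_T / ((gamma + mu) * (u_T + mu)) * frac,
    S = 1 / R0))
  new_equilibrium(st, params, R0, v = v, source = "closed_form")
}

new_equilibrium <- function(state, params, R0, v = NULL, source, converged = TRUE) {
  structure(list(state = state, R0 = R0,
                 prevalence = 1 - state[["S"]],
                 acute_chronic_ratio = acute_chronic_ratio(params),
                 v = v, source = source, converged = converged,
                 residual = max(abs(model_rhs(state, params))),
                 params = params),
            class = "endemic_equilibrium")
}

#' @export
print.endemic_equilibrium <- function(x, ...) {
  cat(sprintf("Endemic equilibrium (%s; R0 = %.6g)\n", x$source, x$R0))
  print(round(x$state, 8))
  cat(sprintf("  prevalence = %.6g, acute/chronic transmission ratio = %.6g, rhs residual = %.2g\n",
              x$prevalence, x$acute_chronic_ratio, x$residual))
  invisible(x)
}

#' Acute-to-chronic transmission ratio at equilibrium
#'
#' Ratio of transmissions generated by acutely infected hosts to those
#' generated by chronic hosts at the endemic equilibrium:
#' \eqn{r_{AC} = \xi (u_T+\mu) / \gamma}. Together with the prevalence it lets
#' one recover \eqn{\xi} and \eqn{\beta_C} from population data.
#'
#' @param params a `multistrain_params` object (uses the shared rates).
#' @return scalar ratio.
#' @export
acute_chronic_ratio <- function(params) {
  with(params, xi * (u_T + mu) / gamma)
}

#' Family of endemic equilibria for a reducible mutation matrix
#'
#' When the mutation matrix is reducible the unit eigenvalue can be multiple
#' (q <= k, the number of irreducible blocks) and the endemic equilibria form
#' a family: the closed-form components hold with \eqn{v} replaced by any
#' vector \eqn{\bar v} in the span of the unit-eigenvalue eigenvectors
#' (subject to non-negativity). The basis members and a combination helper
#' are returned; combinations with negative components are flagged as
#' non-physical rather than silently rescaled.
#'
#' @param params a `baseline_params` object with R0 > 1.
#' @return an object of class `equilibrium_family`: list with `q`, `basis`
#'   (list of `endemic_equilibrium` for each sum-normalizable eigenvector),
#'   `eigenvectors`, `decomposition`, and `member(weights)`, a function
#'   returning the equilibrium for a convex combination of the basis vectors.
#' @export
endemic_family <- function(params) {
  if (!inherits(params, "baseline_params"))
    stop("endemic_family needs baseline_params", call. = FALSE)
  R0 <- r0(params)$value
  if (R0 <= 1)
    stop(sprintf("no endemic equilibria: R0 = %.6g <= 1", R0), call. = FALSE)
  nf <- normal_form(params$A)
  build <- function(vbar) {
    frac <- 1 - 1 / R0
    with(params, model_state(
      params,
      I_A = mu / (gamma + mu) * frac * vbar,
      I_C = gamma * mu / ((gamma + mu) * (u_T + mu)) * frac * vbar,
      T_ = gamma * u_T / ((gamma + mu) * (u_T + mu)) * frac,
      S = 1 / R0))
  }
  U <- nf$unit_eigenvectors
  basis <- list()
  for (c in seq_len(ncol(U))) {
    vb <- U[, c]
    if (abs(sum(vb) - 1) < 1e-8 && all(vb > -1e-10)) {
      vb <- pmax(vb, 0); vb <- vb / sum(vb)
      basis[[length(basis) + 1L]] <-
        new_equilibrium(build(vb), params, R0, v = vb, source = "closed_form")
    }
  }
  member <- function(weights) {
    if (length(weights) != ncol(U))
      stop("need one weight per unit eigenvector", call. = FALSE)
    vbar <- drop(U %*% weights)
    if (abs(sum(vbar) - 1) > 1e-8)
      stop("combination must keep sum(v) = 1", call. = FALSE)
    if (any(vbar < -1e-10))
      stop("non-physical combination: negative strain frequencies", call. = FALSE)
    new_equilibrium(build(pmax(vbar, 0)), params, R0, v = vbar,
                    source = "closed_form")
  }
  structure(list(q = nf$q, basis = basis, eigenvectors = U,
                 decomposition = nf, member = member, R0 = R0),
            class = "equilibrium_family")
}

#' @export
print.equilibrium_family <- function(x, ...) {
  cat(sprintf("Endemic equilibrium family: q = %d unit eigenvalue(s), %d non-negative basis member(s)\n",
              x$q, length(x$basis)))
  invisible(x)
}

#' Numeric endemic equilibrium of the extended model
#'
#' No closed form is available for the general extended system; the
#' equilibrium is found by damped Newton iteration on the right-hand side with
#' the susceptible fraction eliminated through the simplex constraint. The
#' iteration starts from the collapsed baseline closed form when the
#' parameters permit, otherwise from a long-time integration of the flow (or
#' from the supplied `start` state, used by the sweep drivers for warm-started
#' continuation).
#'
#' @param params an `extended_params` object with R0 > 1.
#' @param start optional state vector used as the initial Newton iterate.
#' @param tol Newton tolerance on the max-norm of the right-hand side.
#' @param max_iter maximum Newton iterations.
#' @return an `endemic_equilibrium` with `source = "numeric"`. On convergence
#'   failure the integration-only state is returned with `converged = FALSE`
#'   and a warning.
#' @export
endemic_extended <- function(params, start = NULL, tol = 1e-12, max_iter = 100L) {
  if (!inherits(params, "extended_params"))
    stop("endemic_extended needs extended_params", call. = FALSE)
  R0 <- r0(params)$value
  if (R0 <= 1)
    stop(sprintf("no endemic equilibrium: R0 = %.6g <= 1", R0), call. = FALSE)
  n <- params$n
  if (is.null(start)) {
    start <- tryCatch({
      eq <- endemic_baseline(collapse_extended(params))
      s <- split_state(eq$state, collapse_extended(params))
      model_state(params, I_A = s$I_A, I_C = s$I_C,
                  T_ = params$u_T * s$I_C / (params$zeta + params$mu),
                  S = NULL, P = 0)
    }, error = function(e) {
      steady_state(params, t_max = 2e4, tol = 1e-8)$state
    })
  }
  # Newton on all compartments except S (S = 1 - sum of the rest)
  idx <- setdiff(seq_along(start), 3 * n + 1)
  g <- function(y) {
    x <- numeric(3 * n + 2)
    x[idx] <- y
    x[3 * n + 1] <- 1 - sum(y)
    names(x) <- state_names(params)
    unname(rhs_extended(x, params)[idx])
  }
  newton <- function(y) {
    res <- g(y)
    for (it in seq_len(max_iter)) {
      if (max(abs(res)) < tol) break
      J <- num_jacobian(g, y)
      step <- tryCatch(solve(J, res), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        y_new <- y - lambda * step
        res_new <- tryCatch(g(y_new), error = function(e) NULL)
        if (!is.null(res_new) && all(is.finite(res_new)) &&
            max(abs(res_new)) < max(abs(res))) break
        lambda <- lambda / 2
        if (lambda < 1e-8) { res_new <- res; y_new <- y; break }
      }
      if (identical(y_new, y)) break
      y <- y_new; res <- res_new
    }
    list(y = y, res = max(abs(res)))
  }
  sol <- newton(unname(start[idx]))
  # a root with meaningfully negative components is a spurious equilibrium
  # outside the simplex; restart from the flow, which stays in the physical
  # basin of attraction
  if (sol$res > 1e-9 || min(sol$y) < -1e-8) {
    x1 <- steady_state(params, x0 = pmax(start, 0) / sum(pmax(start, 0)),
                       t_max = 5e4, tol = 1e-9)$state
    sol2 <- newton(unname(x1[idx]))
    if (sol2$res <= 1e-9 && min(sol2$y) >= -1e-8) sol <- sol2
    else sol <- list(y = unname(x1[idx]), res = max(abs(g(unname(x1[idx])))))
  }
  ok <- sol$res <= 1e-9 && min(sol$y) >= -1e-8
  if (!ok)
    warning(sprintf("equilibrium solve did not fully converge (residual %.3g)",
                    sol$res), call. = FALSE)
  x <- numeric(3 * n + 2)
  x[idx] <- pmax(sol$y, 0)
  x[3 * n + 1] <- 1 - sum(x[idx])
  names(x) <- state_names(params)
  new_equilibrium(x, params, R0, v = NULL, source = "numeric", converged = ok)
}

num_jacobian <- function(f, y, h = 1e-8) {
  f0 <- f(y)
  J <- matrix(0, length(f0), length(y))
  for (j in seq_along(y)) {
    hj <- h * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + hj
    ym <- y; ym[j] <- ym[j] - hj
    J[, j] <- (f(yp) - f(ym)) / (2 * hj)
  }
  J
}
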