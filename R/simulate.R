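#' Integrate a multi-strain model
#'
#' Solves the baseline or extended system forward in time with a
#' stiff-capable solver (the rate scales are well separated: acute recovery
#' gamma = O(1) against turnover mu = O(0.01)). States are checked against the
#' simplex along the way; components more negative than -1e-12 are flagged,
#' smaller excursions are clipped to zero.
#'
#' @param params a `multistrain_params` object.
#' @param x0 initial state on the simplex; defaults to
#'   [default_initial_state()].
#' @param t_end final time (> 0).
#' @param n_out number of stored time points.
#' @param method a `deSolve` method (default `"lsoda"`, stiff-capable).
#' @param rtol,atol solver tolerances.
#' @return an object of class `trajectory`: list with `times`, `states`
#'   (matrix, one row per time point, fixed compartment ordering), `params`,
#'   and `clipped` (were any tiny negative values clipped).
#' @examples
#' sc <- case1()
#' tr <- integrate_model(sc$params, t_end = 200)
#' plot(tr)
#' @export
integrate_model <- function(params, x0 = default_initial_state(params),
                            t_end, n_out = 201L, method = "lsoda",
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(t_end > 0)
  if (abs(sum(x0) - 1) > 1e-8)
    stop("initial state must lie on the simplex", call. = FALSE)
  deriv <- function(t, x, p) list(unname(model_rhs(x, params)))
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = unname(x0), times = times, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; see deSolve diagnostics", call. = FALSE)
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- state_names(params)
  neg <- min(states)
  if (neg < -1e-12)
    warning(sprintf("trajectory left the non-negative orthant (min = %.3g)", neg),
            call. = FALSE)
  clipped <- neg < 0
  states[states < 0 & states > -1e-12] <- 0
  structure(list(times = times, states = states, params = params,
                 model = if (inherits(params, "baseline_params")) "baseline"
                         else "extended",
                 clipped = clipped),
            class = "trajectory")
}

#' Default initial condition for scenario runs
#'
#' One percent of the population acutely infected with strain 1, the rest
#' susceptible.
#'
#' @param params a `multistrain_params` object.
#' @param seed_fraction fraction acutely infected with strain 1.
#' @return state vector on the simplex.
#' @export
default_initial_state <- function(params, seed_fraction = 0.01) {
  I_A <- numeric(params$n)
  I_A[1] <- seed_fraction
  model_state(params, I_A = I_A)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s-model trajectory: %d points on [0, %g], %d compartments\n",
              x$model, length(x$times), max(x$times), ncol(x$states)))
  cat("final state:\n")
  print(round(x$states[nrow(x$states), ], 8))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, which = NULL, log = "", ...) {
  cols <- if (is.null(which)) seq_len(ncol(x$states)) else which
  graphics::matplot(x$times, x$states[, cols, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "fraction of population",
                    log = log, ...)
  graphics::legend("topright", legend = colnames(x$states)[cols],
                   col = seq_along(cols), lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Long-time steady state of the flow
#'
#' Integrates in doubling time chunks until the right-hand side falls below
#' `tol` in max-norm or the horizon `t_max` is exhausted (default 5e4, long
#' enough for the slow exp(-mu t) transients at mu = 0.025 to die out).
#'
#' @param params a `multistrain_params` object.
#' @param x0 initial state; defaults to [default_initial_state()].
#' @param t_max maximum total integration time.
#' @param tol convergence tolerance on the max-norm of the right-hand side.
#' @param ... passed to [integrate_model()].
#' @return list with `state`, `converged` flag, `t` (time reached) and
#'   `residual`.
#' @export
steady_state <- function(params, x0 = default_initial_state(params),
                         t_max = 5e4, tol = 1e-10, ...) {
  x <- x0
  t_done <- 0
  chunk <- 50
  repeat {
    res <- max(abs(model_rhs(x, params)))
    if (res < tol) return(list(state = x, converged = TRUE, t = t_done,
                               residual = res))
    if (t_done >= t_max) break
    chunk <- min(chunk * 2, t_max - t_done)
    tr <- integrate_model(params, x0 = x, t_end = chunk, n_out = 2L, ...)
    x <- tr$states[nrow(tr$states), ]
    # renormalize the tiny simplex drift accumulated by the integrator
    x <- pmax(x, 0); x <- x / sum(x)
    t_done <- t_done + chunk
  }
  res <- max(abs(model_rhs(x, params)))
  list(state = x, converged = res < tol, t = t_done, residual = res)
}
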