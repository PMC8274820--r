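#' Controlled basic reproduction number
#'
#' For the baseline model the controlled basic reproduction number has the
#' closed form
#' \deqn{R_0(u_T) = \beta_C \frac{\xi (u_T+\mu) + \gamma}{(\gamma+\mu)(u_T+\mu)},}
#' independent of the mutation matrix (neutral within-host evolution does not
#' change transmission phenotype). For the extended model
#' \deqn{R_0(u_T, u_P) = \bar\beta_C \frac{\gamma+\xi\mu}{(\gamma+\mu)\mu}
#'   \rho(Q(u_P) N(u_T)),}
#' with \eqn{\bar\beta_C = \max_i \beta_{Ci}},
#' \eqn{Q(u_P) = \bar B_C [E - P_{DFE}(u_P)\Psi]},
#' \eqn{N(u_T) = (\xi\mu E + \gamma A \Delta(u_T)) / (\gamma+\xi\mu)} and
#' \eqn{\Delta(u_T) = (Z+(\mu+u_T)E)^{-1}(Z+\mu E)}.
#'
#' @param params a `multistrain_params` object.
#' @param ... unused.
#' @return an object of class `r0_report`: list with `value`, and for the
#'   extended model the spectral pieces `rho`, `Q`, `N`, `Delta`, `beta_bar`,
#'   `B_bar`.
#' @examples
#' A <- uniform_mutation_matrix(c(0.8, 0.6))
#' r0(baseline_params(0.3, 5, 3, 0.025, u_T = 0.4, A = A))
#' @export
r0 <- function(params, ...) UseMethod("r0")

#' @rdname r0
#' @export
r0.baseline_params <- function(params, ...) {
  v <- with(params,
            beta_C * (xi * (u_T + mu) + gamma) / ((gamma + mu) * (u_T + mu)))
  structure(list(value = v, model = "baseline", rho = 1,
                 beta_bar = params$beta_C, params = params),
            class = "r0_report")
}

#' @rdname r0
#' @export
r0.extended_params <- function(params, ...) {
  pieces <- ng_pieces(params)
  v <- with(params, pieces$beta_bar * (gamma + xi * mu) /
              ((gamma + mu) * mu) * pieces$rho)
  structure(c(list(value = v, model = "extended", params = params), pieces),
            class = "r0_report")
}

# Q, N, Delta and the spectral radius of QN for an extended parameter set
ng_pieces <- function(params, u_T = params$u_T, u_P = params$u_P) {
  with(params, {
    beta_bar <- max(beta_C)
    if (beta_bar <= 0) stop("beta_C must not be identically zero", call. = FALSE)
    B_bar <- diag(beta_C / beta_bar, n)
    P_dfe <- u_P / (delta + mu + u_P)
    Q <- B_bar %*% diag(1 - P_dfe * psi, n)
    Delta <- diag((zeta + mu) / (zeta + mu + u_T), n)
    N <- (xi * mu * diag(n) + gamma * as.matrix(A) %*% Delta) / (gamma + xi * mu)
    rho <- max(abs(eigen(Q %*% N, only.values = TRUE)$values))
    list(rho = rho, Q = Q, N = N, Delta = Delta, beta_bar = beta_bar,
         B_bar = B_bar)
  })
}

#' @export
print.r0_report <- function(x, ...) {
  cat(sprintf("Controlled basic reproduction number (%s model)\n", x$model))
  cat(sprintf("  R0 = %.8g", x$value))
  if (x$model == "extended")
    cat(sprintf("   [rho(QN) = %.8g, beta_bar = %.6g]", x$rho, x$beta_bar))
  cat("\n")
  invisible(x)
}

#' Next-generation-matrix reproduction number
#'
#' Independent computation of the controlled basic reproduction number as the
#' spectral radius of \eqn{F V^{-1}}, where F collects the Jacobian of the
#' new-infection inflows over the infected compartments at the disease-free
#' equilibrium and V the remaining (linearized) transitions. Used as the
#' cross-check oracle for the closed forms returned by [r0()].
#'
#' @param params a `multistrain_params` object.
#' @return scalar reproduction number.
#' @export
r0_next_generation <- function(params) {
  n <- params$n
  A <- as.matrix(params$A)
  if (inherits(params, "baseline_params")) {
    # infected compartments: I_A (n), I_C (n); S_DFE = 1
    F_ <- rbind(cbind(params$xi * params$beta_C * diag(n), params$beta_C * A),
                matrix(0, n, 2 * n))
    V <- rbind(cbind((params$gamma + params$mu) * diag(n), matrix(0, n, n)),
               cbind(-params$gamma * diag(n),
                     (params$u_T + params$mu) * diag(n)))
  } else {
    # infected compartments: I_A, I_C, T_i; DFE has S + P split by u_P
    S_dfe <- (params$delta + params$mu) / (params$delta + params$mu + params$u_P)
    P_dfe <- params$u_P / (params$delta + params$mu + params$u_P)
    d <- params$beta_C * (S_dfe + (1 - params$psi) * P_dfe)
    F_ <- rbind(cbind(params$xi * diag(d, n), diag(d, n) %*% A, matrix(0, n, n)),
                matrix(0, 2 * n, 3 * n))
    V <- rbind(
      cbind((params$gamma + params$mu) * diag(n), matrix(0, n, n), matrix(0, n, n)),
      cbind(-params$gamma * diag(n), (params$u_T + params$mu) * diag(n),
            -diag(params$zeta, n)),
      cbind(matrix(0, n, n), -params$u_T * diag(n), diag(params$zeta + params$mu, n)))
  }
  max(abs(eigen(F_ %*% solve(V), only.values = TRUE)$values))
}

#' First-order sensitivity of R0 to the controls
#'
#' Expands the controlled basic reproduction number around zero control,
#' \eqn{R_0(u_T, u_P) = R_0 + R_{1,T} u_T + R_{1,P} u_P + O(\|u\|^2)}.
#' Baseline: \eqn{R_0 = \beta_C(\gamma+\xi\mu)/(\mu(\gamma+\mu))} and
#' \eqn{R_{1,T} = -\beta_C\gamma/(\mu^2(\gamma+\mu))} (always negative, so the
#' treatment control is unconditionally locally efficient). Extended: with
#' \eqn{w_0, v_0} the left/right dominant eigenvectors of
#' \eqn{\bar B_C \bar A}, \eqn{\bar A = (\xi\mu E + \gamma A)/(\gamma+\xi\mu)},
#' normalized so \eqn{w_0^\top v_0 = 1},
#' \deqn{R_{1,T} = -w_0^\top [R_0 E - \tfrac{\xi}{\gamma+\mu} B_C]
#'   (Z+\mu E)^{-1} v_0, \qquad
#'   R_{1,P} = -\frac{R_0}{\delta+\mu} w_0^\top \Psi v_0.}
#'
#' @param params a `multistrain_params` object; the extended form requires an
#'   irreducible mutation matrix.
#' @return an object of class `sensitivity_report` with `R0_at_zero`, `R1_T`,
#'   `R1_P`, the eigenvectors `w0`, `v0`, and the derived mean durations
#'   `theta_A` (acute stage), `tau` (on treatment, per strain) and `pro_dur`
#'   (on prophylaxis).
#' @export
r0_sensitivity <- function(params) UseMethod("r0_sensitivity")

#' @export
r0_sensitivity.baseline_params <- function(params) {
  with(params, {
    R0 <- beta_C * (gamma + xi * mu) / (mu * (gamma + mu))
    R1 <- -beta_C * gamma / (mu^2 * (gamma + mu))
    structure(list(R0_at_zero = R0, R1_T = R1, R1_P = 0,
                   w0 = rep(1, n), v0 = dominant_eigenpair(A)$v,
                   theta_A = 1 / (gamma + mu), tau = rep(1 / mu, n),
                   pro_dur = NA_real_, model = "baseline"),
              class = "sensitivity_report")
  })
}

#' @export
r0_sensitivity.extended_params <- function(params) {
  if (!is_irreducible(params$A))
    stop("sensitivity expansion requires an irreducible mutation matrix",
         call. = FALSE)
  with(params, {
    beta_bar <- max(beta_C)
    B_bar <- diag(beta_C / beta_bar, n)
    A_bar <- (xi * mu * diag(n) + gamma * as.matrix(A)) / (gamma + xi * mu)
    sp <- spectral_pair(B_bar %*% A_bar)
    c0 <- beta_bar * (gamma + xi * mu) / ((gamma + mu) * mu)
    R0 <- c0 * sp$rho
    izmu <- 1 / (zeta + mu)
    R1_T <- -sum(sp$w * (R0 - xi * beta_C / (gamma + mu)) * izmu * sp$v)
    R1_P <- -R0 / (delta + mu) * sum(sp$w * psi * sp$v)
    structure(list(R0_at_zero = R0, R1_T = R1_T, R1_P = R1_P,
                   w0 = sp$w, v0 = sp$v, rho = sp$rho,
                   theta_A = 1 / (gamma + mu), tau = izmu,
                   pro_dur = 1 / (delta + mu), model = "extended"),
              class = "sensitivity_report")
  })
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("R0 expansion at zero control (%s model)\n", x$model))
  cat(sprintf("  R0(0) = %.6g, dR0/du_T = %.6g, dR0/du_P = %.6g\n",
              x$R0_at_zero, x$R1_T, x$R1_P))
  invisible(x)
}

#' Large-control limit of R0
#'
#' As both enrollment rates grow without bound the controlled reproduction
#' number approaches
#' \eqn{\frac{\xi}{\gamma+\mu} \max_i \beta_{Ci} (1-\psi_i)}:
#' only acute-stage transmission of the least-controllable strain remains.
#'
#' @param params an `extended_params` object.
#' @return scalar limit value.
#' @export
r0_limit <- function(params) {
  if (inherits(params, "baseline_params"))
    return(with(params, xi * beta_C / (gamma + mu)))
  with(params, xi / (gamma + mu) * max(beta_C * (1 - psi)))
}

#' Control-efficiency classification
#'
#' A control is locally efficient when its first-order sensitivity coefficient
#' is negative, and globally efficient when some finite control level drives
#' R0 to 1. Treatment alone is globally efficient in the baseline model iff
#' \eqn{\xi \beta_C < \gamma + \mu}; jointly, the two controls of the extended
#' model are globally efficient iff
#' \eqn{\xi \max_i \beta_{Ci}(1-\psi_i) < \gamma + \mu}. Which control is
#' locally preferable is decided by comparing the normalized sensitivity
#' magnitudes
#' \eqn{\sum_i [1 - \xi\beta_{Ci}\theta_A/R_0] \tau_i w_{0i} v_{0i}}
#' (treatment) against
#' \eqn{\sum_i \psi_i (\delta+\mu)^{-1} w_{0i} v_{0i}} (prophylaxis).
#'
#' @param params a `multistrain_params` object.
#' @return an object of class `efficiency_verdict`.
#' @export
classify_efficiency <- function(params) {
  sens <- r0_sensitivity(params)
  lhs <- r0_limit(params)
  rhs <- 1
  if (inherits(params, "baseline_params")) {
    term_T <- -sens$R1_T / sens$R0_at_zero
    term_P <- 0
  } else {
    term_T <- -sens$R1_T / sens$R0_at_zero
    term_P <- -sens$R1_P / sens$R0_at_zero
  }
  preferred <- if (abs(term_T - term_P) <= 1e-12 * max(1, term_T, term_P)) "tie"
  else if (term_T > term_P) "treatment" else "prophylaxis"
  structure(list(
    locally_efficient_T = sens$R1_T < 0,
    locally_efficient_P = if (inherits(params, "baseline_params")) NA
                          else sens$R1_P < 0,
    globally_efficient = lhs < rhs,
    global_condition = c(limit = lhs, threshold = rhs),
    term_T = term_T, term_P = term_P,
    preferred_control = preferred, sensitivity = sens),
    class = "efficiency_verdict")
}

#' @export
print.efficiency_verdict <- function(x, ...) {
  cat("Control efficiency\n")
  cat(sprintf("  locally efficient: u_T %s, u_P %s\n",
              x$locally_efficient_T,
              if (is.na(x$locally_efficient_P)) "n/a" else x$locally_efficient_P))
  cat(sprintf("  globally efficient (large-control limit %.4g < 1): %s\n",
              x$global_condition[["limit"]], x$globally_efficient))
  cat(sprintf("  preferred control: %s (|R1_T|/R0 = %.4g vs |R1_P|/R0 = %.4g)\n",
              x$preferred_control, x$term_T, x$term_P))
  invisible(x)
}

#' Critical control level driving R0 to one
#'
#' Solves \eqn{R_0(u) = 1} for one control while the other is held fixed,
#' by bisection on the monotone map \eqn{u \mapsto R_0} (bracket \[0, 1e4\],
#' expanded geometrically if needed). Also reports the first value on a 0.01
#' grid at which R0 drops to 1 or below. Returns `NA` when even the
#' large-control limit exceeds 1 (the control is only conditionally globally
#' efficient).
#'
#' @param params a `multistrain_params` object; `u_T`/`u_P` inside it give the
#'   fixed value of the other control.
#' @param which `"u_T"` or `"u_P"` (the latter requires the extended model).
#' @param grid_step step of the reported grid scan (default 0.01).
#' @param tol bisection tolerance on |R0 - 1|.
#' @return object of class `critical_control`: list with `value` (the root or
#'   `NA`), `grid_value` (first grid multiple with R0 <= 1, or `NA`), `which`,
#'   and `grid` (data frame of u, R0 up to the crossing).
#' @export
critical_control <- function(params, which = c("u_T", "u_P"),
                             grid_step = 0.01, tol = 1e-8) {
  which <- match.arg(which)
  if (which == "u_P" && !inherits(params, "extended_params"))
    stop("u_P is only a control of the extended model", call. = FALSE)
  f <- function(u) {
    p <- params
    p[[which]] <- u
    r0(p)$value
  }
  if (f(0) <= 1)
    stop("R0 at zero control is already <= 1; nothing to solve", call. = FALSE)
  value <- NA_real_
  hi <- 1e4
  while (f(hi) > 1 && hi < 1e12) hi <- hi * 10
  if (f(hi) <= 1) {
    lo <- 0
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 1) lo <- mid else hi <- mid
      if (abs(f(mid) - 1) < tol && hi - lo < 1e-12 * max(1, hi)) break
    }
    value <- (lo + hi) / 2
  }
  grid_value <- NA_real_
  us <- numeric(0); rs <- numeric(0)
  u <- 0; i <- 0L
  u_stop <- if (is.na(value)) 10 else value + grid_step
  while (u <= u_stop + 1e-12) {
    r <- f(u)
    us <- c(us, u); rs <- c(rs, r)
    if (is.na(grid_value) && r <= 1) { grid_value <- u; break }
    i <- i + 1L
    u <- i * grid_step
  }
  structure(list(value = value, grid_value = grid_value, which = which,
                 grid = data.frame(u = us, R0 = rs)),
            class = "critical_control")
}

#' @export
print.critical_control <- function(x, ...) {
  if (is.na(x$value))
    cat(sprintf("No finite %s eliminates the infection (R0 floor > 1)\n", x$which))
  else
    cat(sprintf("Critical %s = %.8g (first 0.01-grid value with R0 <= 1: %s)\n",
                x$which, x$value, format(x$grid_value)))
  invisible(x)
}
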