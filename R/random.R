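#' Random valid model inputs
#'
#' Seeded generators for property-style checks: random column-stochastic
#' mutation matrices (strictly positive, hence irreducible, with a boosted
#' diagonal), random retention profiles, and random admissible parameter sets
#' for either model. These are testing utilities; the models themselves are
#' deterministic.
#'
#' @param n strain count.
#' @return `random_stochastic_matrix()` returns a `mutation_matrix`;
#'   `random_params()` a `multistrain_params`; `random_simplex_state()` a
#'   state vector on the simplex.
#' @export
random_stochastic_matrix <- function(n) {
  M <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  diag(M) <- diag(M) + 1
  M <- sweep(M, 2, colSums(M), "/")
  mutation_matrix(M)
}

#' @rdname random_stochastic_matrix
#' @param model `"baseline"` or `"extended"`.
#' @export
random_params <- function(n, model = c("baseline", "extended")) {
  model <- match.arg(model)
  A <- random_stochastic_matrix(n)
  gamma <- stats::runif(1, 1, 6)
  mu <- stats::runif(1, 0.01, 0.1)
  xi <- stats::runif(1, 1, 8)
  u_T <- stats::runif(1, 0, 1)
  if (model == "baseline")
    baseline_params(beta_C = stats::runif(1, 0.05, 0.6), xi = xi,
                    gamma = gamma, mu = mu, u_T = u_T, A = A)
  else
    extended_params(beta_C = stats::runif(n, 0.05, 0.6), xi = xi,
                    gamma = gamma, mu = mu, u_T = u_T,
                    u_P = stats::runif(1, 0, 1),
                    zeta = stats::runif(n, 0, 0.5),
                    psi = stats::runif(n), delta = stats::runif(1, 0, 6),
                    A = A)
}

#' @rdname random_stochastic_matrix
#' @param params a `multistrain_params` object.
#' @export
random_simplex_state <- function(params) {
  k <- length(state_names(params))
  x <- stats::rexp(k)
  x <- x / sum(x)
  names(x) <- state_names(params)
  x
}
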