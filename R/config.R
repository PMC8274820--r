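#' Read and write model configurations as YAML
#'
#' A configuration file holds the model tag, the rate block (keys named after
#' the standard parameter symbols: `beta_C`, `xi`, `gamma`, `mu`, `u_T`, and
#' for the extended model `u_P`, `zeta`, `psi`, `delta`) and the mutation
#' matrix, given either structurally as `{topology, pi}` or explicitly as
#' `{entries}` (list of rows) or `{file}` (headerless CSV path). Unknown keys
#' are rejected, as are missing required ones.
#'
#' @param path YAML file path.
#' @param params (writing) a `multistrain_params` object.
#' @return `read_model_config()` returns a `multistrain_params` object;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse_model_config(cfg, dir = dirname(path))
}

parse_model_config <- function(cfg, dir = ".") {
  check_keys(cfg, required = c("model", "parameters", "mutation_matrix"),
             optional = character(0), where = "top level")
  model <- cfg$model
  if (!model %in% c("baseline", "extended"))
    stop("model must be 'baseline' or 'extended'", call. = FALSE)
  A <- parse_matrix_block(cfg$mutation_matrix, dir)
  p <- cfg$parameters
  base_keys <- c("beta_C", "xi", "gamma", "mu", "u_T")
  if (model == "baseline") {
    check_keys(p, required = base_keys, optional = character(0),
               where = "parameters")
    baseline_params(beta_C = p$beta_C, xi = p$xi, gamma = p$gamma, mu = p$mu,
                    u_T = p$u_T, A = A)
  } else {
    check_keys(p, required = c(base_keys, "u_P", "zeta", "psi", "delta"),
               optional = character(0), where = "parameters")
    extended_params(beta_C = unlist(p$beta_C), xi = p$xi, gamma = p$gamma,
                    mu = p$mu, u_T = p$u_T, u_P = p$u_P,
                    zeta = unlist(p$zeta), psi = unlist(p$psi),
                    delta = p$delta, A = A)
  }
}

parse_matrix_block <- function(mb, dir) {
  if (!is.null(mb$topology) && mb$topology %in% c("uniform", "neighbor")) {
    check_keys(mb, required = c("topology", "pi"), optional = character(0),
               where = "mutation_matrix")
    pi <- unlist(mb$pi)
    if (mb$topology == "uniform") uniform_mutation_matrix(pi)
    else neighbor_mutation_matrix(pi)
  } else if (!is.null(mb$entries)) {
    check_keys(mb, required = "entries", optional = "topology",
               where = "mutation_matrix")
    m <- do.call(rbind, lapply(mb$entries, unlist))
    mutation_matrix(m, topology = if (is.null(mb$topology)) "general"
                                  else mb$topology)
  } else if (!is.null(mb$file)) {
    check_keys(mb, required = "file", optional = "topology",
               where = "mutation_matrix")
    path <- mb$file
    if (!file.exists(path)) path <- file.path(dir, mb$file)
    read_mutation_matrix(path, topology = if (is.null(mb$topology)) "general"
                                          else mb$topology)
  } else {
    stop("mutation_matrix must give {topology, pi}, {entries} or {file}",
         call. = FALSE)
  }
}

check_keys <- function(x, required, optional, where) {
  if (!is.list(x)) stop(sprintf("%s block must be a mapping", where), call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("missing key(s) in %s: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' @rdname read_model_config
#' @export
write_model_config <- function(params, path) {
  extended <- inherits(params, "extended_params")
  pars <- list(beta_C = unname(params$beta_C), xi = params$xi,
               gamma = params$gamma, mu = params$mu, u_T = params$u_T)
  if (extended)
    pars <- c(pars, list(u_P = params$u_P, zeta = unname(params$zeta),
                         psi = unname(params$psi), delta = params$delta))
  A <- params$A
  topo <- attr(A, "topology")
  mb <- if (topo %in% c("uniform", "neighbor") && !is.null(attr(A, "pi")))
    list(topology = topo, pi = unname(attr(A, "pi")))
  else
    list(entries = apply(unclass_matrix(as.matrix(A)), 1, as.list,
                         simplify = FALSE))
  cfg <- list(model = if (extended) "extended" else "baseline",
              parameters = pars, mutation_matrix = mb)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Serialize model states as CSV
#'
#' States are written one per row in the fixed compartment ordering with a
#' header naming the compartments (and an optional leading `time` column for
#' trajectories).
#'
#' @param x a state vector, a matrix of states, or a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_states_csv <- function(x, path) {
  if (inherits(x, "trajectory"))
    x <- cbind(time = x$times, x$states)
  if (is.null(dim(x))) x <- t(as.matrix(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
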