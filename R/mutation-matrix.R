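#' Within-host mutation matrices
#'
#' A mutation matrix \eqn{A} is an \eqn{n \times n} non-negative, column-stochastic
#' matrix whose entry \eqn{\alpha_{ij}} is the average fraction of strain-\eqn{i}
#' virus in the chronic-stage viral population of a host whose infection was
#' founded by strain \eqn{j}. Every column sums to 1 and every diagonal entry is
#' strictly positive (a founder strain never disappears completely from its own
#' host). The matrix carries a `topology` tag (`"uniform"`, `"neighbor"` or
#' `"general"`) and, for the structured topologies, the retention profile
#' \eqn{\pi} it was built from.
#'
#' @param entries numeric n-by-n matrix of \eqn{\alpha_{ij}} values.
#' @param topology one of `"uniform"`, `"neighbor"`, `"general"`.
#' @param pi optional retention profile the matrix was built from.
#' @return an object of class `mutation_matrix` (a numeric matrix with
#'   attributes `topology` and `pi`).
#' @examples
#' A <- mutation_matrix(matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2))
#' colSums(A)
#' @export
mutation_matrix <- function(entries, topology = "general", pi = NULL) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "double"
  topology <- match.arg(topology, c("uniform", "neighbor", "general"))
  validate_mutation_matrix(entries)
  structure(entries, topology = topology, pi = pi,
            class = c("mutation_matrix", "matrix", "array"))
}

validate_mutation_matrix <- function(entries, tol = 1e-12) {
  if (!is.matrix(entries) || nrow(entries) != ncol(entries))
    stop("mutation matrix must be square", call. = FALSE)
  if (nrow(entries) < 1L) stop("mutation matrix needs n >= 1", call. = FALSE)
  if (anyNA(entries)) stop("mutation matrix contains NA", call. = FALSE)
  if (any(entries < -tol) || any(entries > 1 + tol))
    stop("mutation matrix entries must lie in [0, 1]", call. = FALSE)
  cs <- colSums(entries)
  if (any(abs(cs - 1) > tol))
    stop(sprintf("columns must sum to 1 (worst deviation %.3g)",
                 max(abs(cs - 1))), call. = FALSE)
  if (any(diag(entries) <= 0))
    stop("all diagonal entries alpha_ii must be strictly positive", call. = FALSE)
  invisible(entries)
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("Within-host mutation matrix (n = %d, topology = %s)\n",
              nrow(x), attr(x, "topology")))
  print(unclass_matrix(x), ...)
  invisible(x)
}

unclass_matrix <- function(x) {
  attr(x, "topology") <- NULL
  attr(x, "pi") <- NULL
  class(x) <- NULL
  x
}

#' @export
as.matrix.mutation_matrix <- function(x, ...) unclass_matrix(x)

#' Uniform-mutation matrix
#'
#' Builds the matrix in which a host founded by strain \eqn{j} retains the
#' fraction \eqn{\pi_j} of the founder strain while the remaining mass
#' \eqn{1-\pi_j} is spread uniformly over the other \eqn{n-1} strains:
#' \eqn{\alpha_{jj} = \pi_j}, \eqn{\alpha_{ij} = (1-\pi_j)/(n-1)} for
#' \eqn{i \neq j}.
#'
#' @param pi retention probabilities, length n >= 2, each in \[0, 1\].
#' @return a `mutation_matrix` with topology `"uniform"`.
#' @examples
#' uniform_mutation_matrix(c(0.8, 0.6))
#' @export
uniform_mutation_matrix <- function(pi) {
  check_retention(pi)
  n <- length(pi)
  if (n < 2L) stop("uniform topology needs n >= 2", call. = FALSE)
  A <- matrix(rep((1 - pi) / (n - 1), each = n), n, n)
  diag(A) <- pi
  mutation_matrix(A, topology = "uniform", pi = pi)
}

#' Nearest-neighbor mutation matrix
#'
#' Strains are ordered by genetic similarity and mutation is only possible
#' between neighbors: the matrix is tridiagonal and column stochastic. Column
#' \eqn{j} keeps \eqn{\pi_j} on the diagonal; an interior column splits the
#' escaping mass \eqn{(1-\pi_j)/2} between its two neighbors, while the two
#' boundary columns give the whole mass \eqn{1-\pi_1} (resp. \eqn{1-\pi_n}) to
#' their single neighbor.
#'
#' @param pi retention probabilities, length n >= 2, each in \[0, 1\].
#' @return a `mutation_matrix` with topology `"neighbor"`.
#' @examples
#' neighbor_mutation_matrix(c(0.97, 0.83, 0.5, 0.25))
#' @export
neighbor_mutation_matrix <- function(pi) {
  check_retention(pi)
  n <- length(pi)
  if (n < 2L) stop("neighbor topology needs n >= 2", call. = FALSE)
  A <- matrix(0, n, n)
  diag(A) <- pi
  A[2, 1] <- 1 - pi[1]
  A[n - 1, n] <- 1 - pi[n]
  if (n > 2L) {
    for (j in 2:(n - 1)) {
      A[j - 1, j] <- (1 - pi[j]) / 2
      A[j + 1, j] <- (1 - pi[j]) / 2
    }
  }
  mutation_matrix(A, topology = "neighbor", pi = pi)
}

check_retention <- function(pi) {
  if (!is.numeric(pi) || anyNA(pi))
    stop("pi must be a numeric vector without NA", call. = FALSE)
  if (any(pi < 0) || any(pi > 1))
    stop("retention probabilities pi must lie in [0, 1]", call. = FALSE)
  invisible(pi)
}

#' Retention profile matching a target endemic frequency vector
#'
#' Inverts the structured-matrix parametrizations: given a strictly positive
#' strain-frequency vector `v` (normalized to sum 1) and a freely chosen
#' retention \eqn{\pi_n} for the last strain, returns the profile \eqn{\pi}
#' such that the corresponding matrix has dominant right eigenvector `v`.
#' For the uniform topology \eqn{\pi_j = 1 - (1-\pi_n) v_n / v_j}; for the
#' neighbor topology \eqn{\pi_1 = 1 - (1-\pi_n) v_n / v_1} and
#' \eqn{\pi_j = 1 - 2 (1-\pi_n) v_n / v_j} for interior \eqn{j}.
#'
#' Not every `(v, pi_n)` pair is feasible: if a computed \eqn{\pi_j} falls
#' outside \[0, 1\] an error names the offending strain.
#'
#' @param v target frequency vector, strictly positive; normalized to sum 1.
#' @param pi_n retention of strain n, in (0, 1).
#' @param topology `"neighbor"` (default) or `"uniform"`.
#' @return a numeric retention profile of the same length as `v`.
#' @examples
#' v <- c(27, 9, 3, 1) / 40
#' retention_from_frequencies(v, 0.25)  # (0.9722, 0.8333, 0.5, 0.25)
#' @export
retention_from_frequencies <- function(v, pi_n, topology = c("neighbor", "uniform")) {
  topology <- match.arg(topology)
  if (!is.numeric(v) || any(v <= 0))
    stop("v must be strictly positive", call. = FALSE)
  n <- length(v)
  if (n < 2L) stop("need at least two strains", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-8)
    stop("v must sum to 1", call. = FALSE)
  v <- v / sum(v)
  if (pi_n <= 0 || pi_n >= 1)
    stop("pi_n must lie in (0, 1)", call. = FALSE)
  m <- (1 - pi_n) * v[n]
  pi <- numeric(n)
  pi[n] <- pi_n
  if (topology == "uniform") {
    pi[seq_len(n - 1)] <- 1 - m / v[seq_len(n - 1)]
  } else {
    pi[1] <- 1 - m / v[1]
    if (n > 2L) pi[2:(n - 1)] <- 1 - 2 * m / v[2:(n - 1)]
  }
  bad <- which(pi < 0 | pi > 1)
  if (length(bad))
    stop(sprintf(paste0("infeasible target frequencies: pi_%d = %.6g falls outside ",
                        "[0, 1]; increase pi_n or flatten v"),
                 bad[1], pi[bad[1]]), call. = FALSE)
  pi
}

#' Dominant eigenpair of a mutation matrix
#'
#' Computes the Perron root and the associated right and left eigenvectors by
#' dense eigendecomposition. For a column-stochastic matrix the dominant
#' eigenvalue is 1 and the left eigenvector is proportional to the all-ones
#' vector. The right eigenvector `v` is scaled to be non-negative with
#' `sum(v) == 1`; the left eigenvector `w` is scaled so that `sum(w * v) == 1`.
#'
#' When the matrix is reducible the unit eigenvalue can fail to be simple; a
#' warning is emitted and `normal_form()` should be used to enumerate the
#' whole eigenvalue-1 eigenspace.
#'
#' @param A a `mutation_matrix` (or any column-stochastic matrix).
#' @return a list of class `spectral_pair` with components `rho`, `v`, `w`,
#'   and `simple` (logical: was the dominant eigenvalue simple).
#' @examples
#' dominant_eigenpair(uniform_mutation_matrix(c(0.8, 0.6)))$v  # (2/3, 1/3)
#' @export
dominant_eigenpair <- function(A) {
  A <- as.matrix(A)
  validate_mutation_matrix(A)
  sp <- spectral_pair(A)
  if (!sp$simple)
    warning(paste("dominant eigenvalue is not simple (matrix is reducible);",
                  "see normal_form() for the full eigenvalue-1 eigenspace"),
            call. = FALSE)
  sp
}

# dominant eigenpair of an arbitrary non-negative matrix; no stochasticity check
spectral_pair <- function(M, tol = 1e-8) {
  er <- eigen(M)
  rho <- max(abs(er$values))
  # pick the eigenvalue closest to the spectral radius on the real axis
  i <- which.min(abs(er$values - rho))
  v <- Re(er$vectors[, i])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v)
  el <- eigen(t(M))
  j <- which.min(abs(el$values - rho))
  w <- Re(el$vectors[, j])
  w <- w / sum(w * v)
  simple <- sum(abs(er$values - rho) < tol * max(1, rho)) == 1L
  structure(list(rho = Re(er$values[i]), v = v, w = w, simple = simple),
            class = "spectral_pair")
}

#' @export
print.spectral_pair <- function(x, ...) {
  cat(sprintf("Dominant eigenpair: rho = %.10g%s\n", x$rho,
              if (x$simple) "" else " (not simple)"))
  cat("v:", format(x$v, digits = 6), "\n")
  cat("w:", format(x$w, digits = 6), "\n")
  invisible(x)
}

#' Closed-form dominant eigenvector for the uniform topology
#'
#' For the uniform-mutation matrix the Perron eigenvector has the explicit
#' form \eqn{v_i \propto \prod_{j \neq i} (1 - \pi_j)}, normalized to sum 1.
#' Pairwise ratios satisfy \eqn{v_i / v_j = (1-\pi_j)/(1-\pi_i)}.
#'
#' @param pi retention profile with all entries < 1 (otherwise the matrix is
#'   reducible and the formula degenerates; use the numeric path).
#' @return frequency vector summing to 1.
#' @export
uniform_closed_form_eigenvector <- function(pi) {
  check_retention(pi)
  if (any(pi >= 1))
    stop("closed form requires all pi_i < 1 (matrix would be reducible)",
         call. = FALSE)
  q <- 1 - pi
  p <- vapply(seq_along(pi), function(i) prod(q[-i]), numeric(1))
  p / sum(p)
}

#' Test irreducibility of a mutation matrix
#'
#' A non-negative square matrix is irreducible iff the directed graph with an
#' edge \eqn{j \to i} whenever \eqn{\alpha_{ij} > 0} is strongly connected.
#' Entries below 1e-14 in absolute value are treated as structural zeros.
#'
#' @param A square non-negative matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_irreducible <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) == 1L) return(A[1, 1] > 1e-14)
  g <- igraph::graph_from_adjacency_matrix(t(abs(A) > 1e-14), mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Normal form of a (possibly reducible) mutation matrix
#'
#' Permutes the strains so that the matrix becomes block upper triangular with
#' irreducible diagonal blocks (the strongly connected components of the
#' mutation digraph), and returns a basis of the eigenvalue-1 eigenspace. A
#' column-stochastic matrix with k irreducible blocks has at most k unit
#' eigenvalues; their count q satisfies q <= k.
#'
#' @param A a `mutation_matrix`.
#' @param tol numeric tolerance for detecting unit eigenvalues.
#' @return a list of class `reducible_decomposition` with components
#'   `permutation` (strain ordering realizing the normal form), `blocks`
#'   (list of index sets, original indexing), `k`, `q`, and
#'   `unit_eigenvectors` (n-by-q matrix, columns sum to 1 where possible).
#' @export
normal_form <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  validate_mutation_matrix(A)
  n <- nrow(A)
  g <- igraph::graph_from_adjacency_matrix(t(abs(A) > 1e-14), mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  k <- comp$no
  blocks <- split(seq_len(n), comp$membership)
  # order blocks so that nonzero inter-block entries sit above the diagonal:
  # entry (i, j) != 0 requires block(i) to precede block(j)
  before <- matrix(FALSE, k, k)
  for (r in seq_len(k)) for (s in seq_len(k)) {
    if (r != s && any(A[blocks[[r]], blocks[[s]], drop = FALSE] > 1e-14))
      before[r, s] <- TRUE
  }
  order_out <- integer(0)
  remaining <- seq_len(k)
  while (length(remaining)) {
    src <- remaining[!vapply(remaining, function(r)
      any(before[setdiff(remaining, r), r]), logical(1))]
    order_out <- c(order_out, src[1])
    remaining <- setdiff(remaining, src[1])
  }
  blocks <- blocks[order_out]
  perm <- unlist(blocks, use.names = FALSE)
  er <- eigen(A)
  idx <- which(abs(er$values - 1) < tol)
  q <- length(idx)
  U <- NULL
  if (q) {
    U <- Re(er$vectors[, idx, drop = FALSE])
    for (c in seq_len(q)) {
      s <- sum(U[, c])
      if (abs(s) > 1e-10) U[, c] <- U[, c] / s
    }
  }
  structure(list(permutation = perm, blocks = blocks, k = k, q = q,
                 unit_eigenvectors = U),
            class = "reducible_decomposition")
}

#' @export
print.reducible_decomposition <- function(x, ...) {
  cat(sprintf("Normal form: k = %d irreducible block(s), q = %d unit eigenvalue(s)\n",
              x$k, x$q))
  for (b in seq_along(x$blocks))
    cat(sprintf("  block %d: strains {%s}\n", b,
                paste(x$blocks[[b]], collapse = ", ")))
  invisible(x)
}

#' Convex combination of a mutation matrix with the identity
#'
#' Returns \eqn{\alpha E + (1-\alpha) A}, which is column stochastic whenever
#' A is, and shares its left and right dominant eigenvectors with A.
#'
#' @param A a `mutation_matrix`.
#' @param alpha mixing weight in \[0, 1\].
#' @return a `mutation_matrix`.
#' @export
convex_combination <- function(A, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a scalar in [0, 1]", call. = FALSE)
  M <- as.matrix(A)
  validate_mutation_matrix(M)
  out <- alpha * diag(nrow(M)) + (1 - alpha) * M
  topo <- if (alpha == 0) attr(A, "topology") else "general"
  if (is.null(topo)) topo <- "general"
  mutation_matrix(out, topology = topo)
}

#' Read / write a mutation matrix as headerless CSV
#'
#' The file holds the raw n-by-n entries, one matrix row per line, entry
#' `(i, j)` being the fraction of strain i in hosts founded by strain j
#' (columns index the founder strain).
#'
#' @param path file path.
#' @param A a `mutation_matrix` (for writing).
#' @param topology topology tag to attach on read.
#' @return `read_mutation_matrix` returns a `mutation_matrix`;
#'   `write_mutation_matrix` returns `path` invisibly.
#' @export
read_mutation_matrix <- function(path, topology = "general") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  mutation_matrix(m, topology = topology)
}

#' @rdname read_mutation_matrix
#' @export
write_mutation_matrix <- function(A, path) {
  utils::write.table(unclass_matrix(as.matrix(A)), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
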