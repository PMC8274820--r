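test_that("structured constructors produce the expected matrices", {
  A <- uniform_mutation_matrix(c(0.8, 0.6))
  expect_equal(unname(as.matrix(A)), matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2))

  expect_equal(unname(as.matrix(uniform_mutation_matrix(c(1, 1, 1)))), diag(3))
  expect_equal(unname(as.matrix(neighbor_mutation_matrix(rep(1, 4)))), diag(4))
  expect_equal(unname(as.matrix(neighbor_mutation_matrix(c(0.5, 0.5)))),
               matrix(0.5, 2, 2))

  pi1 <- retention_from_frequencies(case1_v, 0.25)
  N <- as.matrix(neighbor_mutation_matrix(pi1))
  expect_equal(unname(N[, 3]), c(0, 0.25, 0.5, 0.25))
  expect_equal(unname(N[, 4]), c(0, 0, 0.75, 0.25))

  expect_error(uniform_mutation_matrix(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(uniform_mutation_matrix(0.5), "n >= 2")
  expect_error(mutation_matrix(matrix(c(0.5, 0.5, 1, 0), 2, 2)),
               "strictly positive")
})

test_that("column stochasticity holds for random retention profiles", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    pi <- runif(n)
    for (A in list(uniform_mutation_matrix(pi), neighbor_mutation_matrix(pi)))
      expect_lt(max(abs(colSums(as.matrix(A)) - 1)), 1e-12)
  }
})

test_that("frequency inversion recovers the target eigenvector (round trip)", {
  pi1 <- retention_from_frequencies(case1_v, 0.25)
  expect_equal(pi1, c(1 - 0.75 * 0.025 / 0.675, 1 - 1.5 * 0.025 / 0.225,
                      0.5, 0.25))
  expect_equal(dominant_eigenpair(neighbor_mutation_matrix(pi1))$v, case1_v,
               tolerance = 1e-12)

  # symmetric two-strain case
  expect_equal(retention_from_frequencies(c(0.5, 0.5), 0.5)[1], 0.5)

  # infeasible flat target with small pi_n
  expect_error(retention_from_frequencies(rep(0.25, 4), 0.25), "infeasible")

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    v <- sort(rexp(n) + 0.2, decreasing = TRUE)
    v <- v / sum(v)
    pin <- 1 - min(0.9, 0.4 * min(v[-n]) / v[n])
    for (topo in c("neighbor", "uniform")) {
      pi <- retention_from_frequencies(v, pin, topology = topo)
      A <- if (topo == "neighbor") neighbor_mutation_matrix(pi)
           else uniform_mutation_matrix(pi)
      expect_lt(max(abs(dominant_eigenpair(A)$v - v)), 1e-9)
    }
  }
})

test_that("dominant eigenpair matches closed forms and normalizations", {
  sp <- dominant_eigenpair(uniform_mutation_matrix(c(0.8, 0.6)))
  expect_equal(sp$rho, 1, tolerance = 1e-10)
  expect_equal(sp$v, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(sp$w * sp$v), 1, tolerance = 1e-12)
  # left eigenvector of a column-stochastic matrix is flat
  expect_lt(diff(range(sp$w)), 1e-10)

  expect_warning(dominant_eigenpair(mutation_matrix(diag(2))), "not simple")

  expect_equal(uniform_closed_form_eigenvector(c(0.8, 0.6)), c(2 / 3, 1 / 3))
  expect_equal(uniform_closed_form_eigenvector(rep(0.5, 3)), rep(1 / 3, 3))
  expect_error(uniform_closed_form_eigenvector(c(1, 0.5)), "reducible")

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    pi <- runif(n, 0, 0.95)
    expect_lt(max(abs(uniform_closed_form_eigenvector(pi) -
                        dominant_eigenpair(uniform_mutation_matrix(pi))$v)),
              1e-10)
  }
})

test_that("irreducibility reflects strong connectivity of the mutation graph", {
  expect_true(is_irreducible(uniform_mutation_matrix(c(0.3, 0.7, 0.5))))
  expect_false(is_irreducible(diag(3)))
  blockdiag <- rbind(cbind(matrix(0.5, 2, 2), matrix(0, 2, 2)),
                     cbind(matrix(0, 2, 2), matrix(0.5, 2, 2)))
  expect_false(is_irreducible(blockdiag))
  expect_true(is_irreducible(neighbor_mutation_matrix(c(0.5, 0.5, 0.5))))
})

test_that("normal form enumerates irreducible blocks and unit eigenvalues", {
  nf <- normal_form(neighbor_mutation_matrix(c(0.5, 0.5, 0.5)))
  expect_equal(nf$k, 1L)
  expect_equal(nf$q, 1L)

  nf_id <- normal_form(mutation_matrix(diag(3)))
  expect_equal(nf_id$k, 3L)
  expect_equal(nf_id$q, 3L)

  # two 2x2 irreducible blocks with one-way coupling: only the closed block
  # keeps a unit eigenvalue
  A <- matrix(c(0.5, 0.5, 0, 0,
                0.5, 0.5, 0, 0,
                0.1, 0, 0.8, 0.1,
                0, 0, 0.3, 0.7), 4, 4)
  nf2 <- normal_form(mutation_matrix(A))
  expect_equal(nf2$k, 2L)
  expect_lte(nf2$q, nf2$k)
  expect_equal(nf2$q, 1L)
  # the permuted matrix is block upper triangular
  P <- as.matrix(A)[nf2$permutation, nf2$permutation]
  expect_equal(unname(P[3:4, 1:2]), matrix(0, 2, 2))
  # eigenvector basis spans the eigenvalue-1 eigenspace
  U <- nf2$unit_eigenvectors
  expect_lt(max(abs(A %*% U - U)), 1e-10)
})

test_that("convex combination with the identity preserves the eigenvectors", {
  S <- mutation_matrix(matrix(c(0.2, 0.8, 0.9, 0.1), 2, 2))
  expect_equal(as.matrix(convex_combination(S, 0)), as.matrix(S))
  expect_equal(unname(as.matrix(convex_combination(S, 1))), diag(2))
  half <- convex_combination(mutation_matrix(matrix(c(0.5, 0.5, 0.5, 0.5), 2)), 0.5)
  expect_equal(unname(as.matrix(half)), matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  expect_error(convex_combination(S, 1.5), "alpha")

  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    Sig <- random_stochastic_matrix(n)
    a <- runif(1)
    Sa <- convex_combination(Sig, a)
    expect_lt(max(abs(colSums(as.matrix(Sa)) - 1)), 1e-12)
    v1 <- dominant_eigenpair(Sig)$v
    v2 <- dominant_eigenpair(Sa)$v
    u1 <- v1 / sqrt(sum(v1^2)); u2 <- v2 / sqrt(sum(v2^2))
    expect_lt(sqrt(sum((u1 - u2)^2)), 1e-8)  # ~ angle for small angles
  }
})

test_that("mutation matrices round-trip through headerless CSV", {
  A <- neighbor_mutation_matrix(retention_from_frequencies(case1_v, 0.25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mutation_matrix(A, path)
  B <- read_mutation_matrix(path, topology = "neighbor")
  expect_equal(unname(as.matrix(B)), unname(as.matrix(A)), tolerance = 1e-12)
})
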