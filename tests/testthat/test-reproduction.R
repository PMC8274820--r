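test_that("baseline R0 closed form matches hand values and limits", {
  A <- uniform_mutation_matrix(c(0.8, 0.6, 0.7, 0.9))
  p <- baseline_params(0.3, 5, 3, 0.025, 0.4, A)
  expect_equal(r0(p)$value, 0.3 * (5 * 0.425 + 3) / (3.025 * 0.425))
  expect_equal(round(r0(p)$value, 1), 1.2)

  # u_T -> infinity leaves only acute transmission
  p$u_T <- 1e12
  expect_equal(r0(p)$value, 5 * 0.3 / 3.025, tolerance = 1e-6)

  # xi = 1, u_T = 0 collapses to beta_C / mu
  p2 <- baseline_params(0.3, 1, 3, 0.025, 0, A)
  expect_equal(r0(p2)$value, 0.3 / 0.025)
})

test_that("baseline R0 does not depend on the mutation matrix", {
  set.seed(10)
  p <- baseline_params(0.3, 5, 3, 0.025, 0.4, random_stochastic_matrix(4))
  v0 <- r0(p)$value
  for (rep in 1:5) {
    p$A <- random_stochastic_matrix(4)
    expect_equal(r0(p)$value, v0, tolerance = 1e-12)
    expect_equal(r0_next_generation(p), v0, tolerance = 1e-8)
  }
})

test_that("extended R0 reduces to the baseline closed form when phenotypes are uniform", {
  sc <- case1()
  pe <- scenario_extended(sc, psi = c(1, 0.3, 0.2, 0))  # u_P = 0
  expect_equal(r0(pe)$value, r0(sc$params)$value, tolerance = 1e-12)
  pe2 <- scenario_extended(sc)
  expect_equal(r0(pe2)$value, r0(sc$params)$value, tolerance = 1e-12)
})

test_that("closed forms agree with the next-generation oracle on random draws", {
  set.seed(2024)
  draws <- 0
  for (n in c(1, 2, 4, 8)) {
    for (rep in 1:7) {
      pb <- random_params(n, "baseline")
      expect_equal(r0(pb)$value, r0_next_generation(pb), tolerance = 1e-8)
      pe <- random_params(n, "extended")
      expect_equal(r0(pe)$value, r0_next_generation(pe), tolerance = 1e-8)
      draws <- draws + 2
    }
  }
  expect_gte(draws, 50)
})

test_that("one-strain extended model matches the scalar hand computation", {
  pe <- extended_params(beta_C = 0.4, xi = 5, gamma = 3, mu = 0.025,
                        u_T = 0.4, u_P = 0.5, zeta = 0.1, psi = 0.6,
                        delta = 4, A = matrix(1))
  S_dfe <- (4 + 0.025) / (4 + 0.025 + 0.5)
  P_dfe <- 1 - S_dfe
  Delta <- (0.1 + 0.025) / (0.1 + 0.025 + 0.4)
  hand <- 0.4 * (3 + 5 * 0.025) / (3.025 * 0.025) *
    (1 - P_dfe * 0.6) * (5 * 0.025 + 3 * Delta) / (3 + 5 * 0.025)
  expect_equal(r0(pe)$value, hand, tolerance = 1e-12)
  expect_equal(r0_next_generation(pe), hand, tolerance = 1e-8)
})

test_that("R0 is non-increasing in both controls", {
  set.seed(5)
  pe <- random_params(4, "extended")
  for (other in c(0, 0.5)) {
    r_ut <- vapply(seq(0, 2, by = 0.25), function(u) r0_at(pe, ut = u, up = other),
                   numeric(1))
    r_up <- vapply(seq(0, 2, by = 0.25), function(u) r0_at(pe, ut = other, up = u),
                   numeric(1))
    expect_true(all(diff(r_ut) <= 1e-12))
    expect_true(all(diff(r_up) <= 1e-12))
  }
})

test_that("baseline sensitivity coefficients match hand values and are negative", {
  A <- uniform_mutation_matrix(c(0.8, 0.6))
  p <- baseline_params(0.25, 5, 3, 0.025, 0.4, A)
  s <- r0_sensitivity(p)
  expect_equal(s$R0_at_zero, 10.3306, tolerance = 1e-5)
  expect_equal(s$R1_T, -0.25 * 3 / (0.025^2 * 3.025))
  expect_equal(s$R1_T, -396.69, tolerance = 1e-4)
  expect_lt(s$R1_T, 0)
  expect_equal(s$theta_A, 1 / 3.025)
  # matches a finite difference of the closed form at u_T = 0
  fd <- fd_central(function(u) { p$u_T <- u; r0(p)$value }, 0, h = 1e-5)
  expect_equal(s$R1_T, fd, tolerance = 1e-5)
})

test_that("extended sensitivity coefficients match finite differences", {
  set.seed(77)
  for (rep in 1:12) {
    pe <- random_params(sample(c(2, 4), 1), "extended")
    s <- r0_sensitivity(pe)
    fd_T <- fd_central(function(u) r0_at(pe, ut = u, up = 0), 0, h = 1e-6)
    fd_P <- fd_central(function(u) r0_at(pe, ut = 0, up = u), 0, h = 1e-6)
    expect_equal(s$R1_T, fd_T, tolerance = 1e-4)
    expect_equal(s$R1_P, fd_P, tolerance = 1e-4)
    expect_lte(s$R1_T, 0)
    expect_lte(s$R1_P, 0)
  }
})

test_that("uniform-transmissibility reductions of the sensitivity hold", {
  sc <- case1()
  pe <- scenario_extended(sc, psi = c(1, 1, 1, 0), delta = 4)
  s <- r0_sensitivity(pe)
  # w0 is flat for a column-stochastic matrix
  expect_lt(diff(range(s$w0)), 1e-9)
  R0 <- s$R0_at_zero
  gamma <- 3; xi <- 5; mu <- 0.025
  expect_equal(s$R1_T, -R0 * gamma / (gamma + xi * mu) *
                 sum(s$w0 * s$v0 / mu), tolerance = 1e-9)
  expect_equal(s$R1_P, -R0 / (4 + mu) * sum(s$w0 * c(1, 1, 1, 0) * s$v0),
               tolerance = 1e-9)
  # no protection anywhere means prophylaxis has no first-order effect
  pe0 <- scenario_extended(sc, psi = 0)
  expect_equal(r0_sensitivity(pe0)$R1_P, 0)
  # reducible mutation structure is rejected
  pe_red <- extended_params(0.25, 5, 3, 0.025, 0.4, 0, 0, 0, 4, diag(2))
  expect_error(r0_sensitivity(pe_red), "irreducible")
})

test_that("large-control limit and joint global efficiency agree", {
  sc <- case1()
  bc <- calibrate_beta_C()
  pe <- scenario_extended(sc, beta_C = bc, psi = c(1, 1, 1, 0), delta = 4)
  expect_equal(r0_limit(pe), 5 * bc / 3.025, tolerance = 1e-9)
  expect_equal(r0_limit(pe), 0.49756, tolerance = 1e-4)
  expect_equal(r0_limit(scenario_extended(sc, psi = 1)), 0)
  set.seed(31)
  for (rep in 1:10) {
    pe <- random_params(3, "extended")
    lim <- r0_at(pe, ut = 1e6, up = 1e6)
    expect_equal(lim, r0_limit(pe), tolerance = 1e-3)
    verdict <- classify_efficiency(pe)
    expect_equal(verdict$globally_efficient, r0_limit(pe) < 1)
  }
})

test_that("efficiency classification reproduces the governing inequalities", {
  A <- uniform_mutation_matrix(c(0.8, 0.6, 0.7, 0.9))
  p <- baseline_params(0.25, 5, 3, 0.025, 0.4, A)
  v <- classify_efficiency(p)
  expect_true(v$locally_efficient_T)
  expect_true(v$globally_efficient)  # xi*beta_C = 1.25 < gamma+mu = 3.025

  # full protection with instant prophylaxis turnover: treatment preferred
  sc <- case1()
  pe <- scenario_extended(sc, psi = 1, delta = 1e9)
  expect_equal(classify_efficiency(pe)$preferred_control, "treatment")

  # xi = 1, perfect durable prophylaxis: prophylaxis preferred, and the
  # comparison collapses to gamma/((gamma+mu)mu) vs 1/mu
  pe2 <- extended_params(beta_C = 0.25, xi = 1, gamma = 3, mu = 0.025,
                         u_T = 0.4, u_P = 0, zeta = 0, psi = 1, delta = 0,
                         A = sc$A)
  v2 <- classify_efficiency(pe2)
  expect_equal(v2$preferred_control, "prophylaxis")
  expect_equal(v2$term_T, 3 / (3.025 * 0.025), tolerance = 1e-9)
  expect_equal(v2$term_P, 1 / 0.025, tolerance = 1e-9)
})

test_that("critical control levels solve R0 = 1 and respect the floor", {
  A <- uniform_mutation_matrix(c(0.8, 0.6, 0.7, 0.9))
  # floor above 1: no finite treatment level eliminates the infection
  p_hot <- baseline_params(0.7, 5, 3, 0.025, 0, A)
  cc <- critical_control(p_hot, "u_T")
  expect_true(is.na(cc$value))

  bc <- calibrate_beta_C()
  p <- baseline_params(bc, 5, 3, 0.025, 0, A)
  cc2 <- critical_control(p, "u_T")
  p$u_T <- cc2$value
  expect_equal(r0(p)$value, 1, tolerance = 1e-8)
  # closed-form inversion of the R0 expression as the oracle
  ut_star <- bc * 3 / (3.025 - 5 * bc) - 0.025
  expect_equal(cc2$value, ut_star, tolerance = 1e-6)

  sc <- case1()
  pe <- scenario_extended(sc, psi = c(1, 1, 1, 0), delta = 4)
  cc3 <- critical_control(pe, "u_P")
  expect_equal(cc3$grid_value, 0.88, tolerance = 1e-12)
  expect_lt(abs(cc3$value - 0.88), 0.01)
  expect_error(critical_control(scenario_extended(case1(beta = "printed")), "u_P"),
               "already")
})
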