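# shared fixtures and numeric helpers for the test suite

case1_v <- c(27, 9, 3, 1) / 40

# central finite difference of f at x
fd_central <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# R0 of an extended parameter set at controls (ut, up), bypassing
# re-validation so that tiny negative control values are allowed
r0_at <- function(params, ut = params$u_T, up = params$u_P) {
  params$u_T <- ut
  params$u_P <- up
  r0(params)$value
}

expect_state_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(unname(a) - unname(b))), tol)
}
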