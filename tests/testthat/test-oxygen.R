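p <- fixed_parameters()

test_that("unified exchange is zero at equilibrium, linear and antisymmetric", {
  expect_equal(o2_exchange_unified(p$O2_far, p), 0)
  expect_gt(o2_exchange_unified(0.5 * p$O2_far, p), 0)   # influx
  expect_lt(o2_exchange_unified(2 * p$O2_far, p), 0)     # outflux
  d1 <- 0.05
  expect_equal(o2_exchange_unified(p$O2_far - d1, p),
               -o2_exchange_unified(p$O2_far + d1, p), tolerance = 1e-12)
  expect_equal(o2_exchange_unified(p$O2_far - 2 * d1, p),
               2 * o2_exchange_unified(p$O2_far - d1, p), tolerance = 1e-12)
})

test_that("halving epsilon halves the flux in the membrane-dominated limit", {
  pa <- fixed_parameters(epsilon = 1e-6)
  pb <- fixed_parameters(epsilon = 5e-7)
  ra <- o2_exchange_unified(0, pa)
  rb <- o2_exchange_unified(0, pb)
  expect_equal(rb / ra, 0.5, tolerance = 0.01)
})

test_that("degenerate geometry is rejected", {
  expect_error(fixed_parameters(R = -1), "'R'")
  bad <- fixed_parameters()
  bad$L_b <- -1
  expect_error(o2_exchange_unified(0.1, bad), "geometry")
})

test_that("constant-source steady state matches the closed form", {
  # dO2/dt = S + T(O2) settles at O2_far + S/g; integrate as the oracle
  S <- 0.5
  sol <- deSolve::ode(
    y = c(O2 = p$O2_far), times = c(0, 600),
    func = function(t, y, parms) list(S + o2_exchange_unified(max(y, 0), p)),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  o2_ss <- unname(sol[2, "O2"])
  g <- o2_exchange_unified(0, p) / p$O2_far   # conductance, s^-1
  expect_equal(o2_ss, p$O2_far + S / g, tolerance = 1e-6)
  expect_equal(o2_exchange_unified(o2_ss, p), -S, tolerance = 1e-4)
})

test_that("segregated exchange conserves O2 through the mixed layer", {
  ox0 <- o2_exchange_segregated(p$O2_far, p$O2_far, p)
  expect_equal(ox0$flux_D, 0)
  expect_equal(ox0$flux_P, 0)
  expect_equal(ox0$flux_env, 0)
  expect_equal(ox0$O2_mixed, p$O2_far)

  # P supersaturated, D depleted: outflux from P, influx to D
  ox <- o2_exchange_segregated(0.02, 0.5, p)
  expect_gt(ox$flux_D, 0)
  expect_lt(ox$flux_P, 0)
  expect_true(ox$O2_mixed > 0.02 && ox$O2_mixed < 0.5)

  # volume-weighted cell fluxes equal the net environment flux
  set.seed(11)
  for (i in 1:20) {
    o2d <- runif(1, 0, 1); o2p <- runif(1, 0, 1)
    ox <- o2_exchange_segregated(o2d, o2p, p)
    expect_equal(p$f_D * ox$flux_D + (1 - p$f_D) * ox$flux_P,
                 ox$flux_env, tolerance = 1e-12)
  }
})
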