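p <- fixed_parameters()
f <- default_optimized_parameters()

test_that("sensitivity grid is a pure function of its inputs", {
  cfg <- fast_config()
  g1 <- sensitivity_grid(p, f, cfg, kO2NF_grid = 1e-2, epsilon_grid = 1e-4)
  g2 <- sensitivity_grid(p, f, cfg, kO2NF_grid = 1e-2, epsilon_grid = 1e-4)
  expect_identical(g1, g2)
  expect_named(g1, c("kO2NF", "epsilon", "CN_ratio", "G", "O2_max",
                     "vRP_max", "reoptimized"))
  expect_error(sensitivity_grid(p, f, cfg, kO2NF_grid = 1),
               "kO2NF_grid")
})

test_that("membrane permeability controls RP carbon consumption", {
  cfg <- fast_config()
  lo <- sensitivity_grid(p, f, cfg, kO2NF_grid = 1e-2, epsilon_grid = 1e-4)
  hi <- sensitivity_grid(p, f, cfg, kO2NF_grid = 1e-2, epsilon_grid = 1e-3)
  # a leakier membrane lets more O2 in: more carbon burned in RP, higher C:N
  expect_gt(hi$CN_ratio, lo$CN_ratio)
  # a tighter membrane traps photosynthetic O2: higher intracellular maxima
  vlo <- sensitivity_grid(p, f, cfg, kO2NF_grid = 1e-2, epsilon_grid = 1e-5)
  expect_gt(vlo$O2_max, lo$O2_max)
})

test_that("the vCS_max sweep reproduces the standard run at fraction 1", {
  cfg <- fast_config()
  sw <- vcs_sweep(p, f, cfg, fractions = c(0.5, 1, 2))
  r <- integrate_diel(p, f, cfg)
  i1 <- which(sw$fraction == 1)
  expect_equal(sw$G[i1], r$G, tolerance = 1e-10)
  expect_equal(sw$rp_C[i1], r$integrals$rp_C, tolerance = 1e-10)
  # realized growth is the smaller of the C- and N-based rates
  expect_equal(sw$G, pmin(sw$G_C, sw$G_N), tolerance = 1e-10)
  # slower skeleton synthesis delays the N2-fixation peak driver
  expect_true(all(diff(sw$peak_t_NF) <= 0) || all(diff(sw$peak_t_NF) >= 0))
})

test_that("ablation experiments move the O2 economy in the expected direction", {
  cfg <- fast_config()
  aet <- ablate_aet_run(p, f, cfg)
  expect_gt(aet$rel_change[["o2_production"]], 0)
  expect_lt(aet$rel_change[["G"]], 0)
  rp <- ablate_rp_run(p, f, cfg)
  expect_lt(rp$rel_change[["gross_N"]], -0.5)
  expect_lt(rp$rel_change[["G"]], 0)
  # without RP the intracellular O2 never dips below ambient
  expect_gt(rp$ablated$integrals$O2_min, p$O2_far * 0.99)
})

test_that("calibration is self-consistent and reports every tuned constant", {
  cfg <- fast_config()
  r <- integrate_diel(p, f, cfg)
  # targets set to the model's own outcomes: residuals stay ~0
  cal <- suppressWarnings(calibrate_unknowns(
    p, f, cfg,
    targets = c(G = r$G, CN_ratio = r$integrals$CN_ratio),
    segregated_targets = NULL,
    unknowns = c("alpha_I", "beta"),
    maxit = 2L   # the iteration cap itself triggers a solver notice
  ))
  expect_false(cal$failed)
  expect_lt(max(abs(cal$residuals$rel_residual)), 1e-3)
  expect_equal(cal$report$constant, c("alpha_I", "beta"))
  expect_true(all(c("before", "after") %in% names(cal$report)))
  expect_s3_class(cal$params, "trd_fixed")
})
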