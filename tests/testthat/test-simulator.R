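p <- fixed_parameters()
f <- default_optimized_parameters()
cfg <- run_config()

test_that("assembled derivatives match an independent recomputation", {
  # hand-written chain from the model equations, independent of the package's
  # flux assembly
  t <- 4 * 3600
  st <- c(CH2O = 0.10, CS = 0.05, N = 0.02, O2 = 0.05)
  I <- p$I_max * sin(pi * t / p$T_light)
  lf <- 1 - exp(-p$alpha_I * I)
  v_rp <- f$vRP_max * st[["O2"]] / (st[["O2"]] + p$kO2NF) * lf *
    st[["CS"]] / (st[["CS"]] + f$kCSNF) * (p$N_max - st[["N"]]) / p$N_max
  v_pet <- p$vPET_max * lf * exp(-p$beta * v_rp)
  v_nf_max <- v_pet * (1.3 / 3) * 0.5 / 3
  v_nf_req <- v_nf_max * st[["CS"]] / (st[["CS"]] + f$kCSNF) *
    (p$N_max - st[["N"]]) / p$N_max * p$kO2NF / (st[["O2"]] + p$kO2NF)
  v_nf <- min(v_nf_req, 0.65 * v_pet / (1.1 * 9))
  v_cf <- max(0, (0.65 * v_pet / 1.1 - 9 * v_nf) / 3.8)
  f_aet <- 1 - (3 * v_nf + 2 * v_cf) / (0.5 * v_pet)
  v_cs <- f$vCS_max * st[["CH2O"]] / (st[["CH2O"]] + f$kCH2O_CS) *
    (p$CS_max - st[["CS"]]) / p$CS_max
  rho <- 1e4 * log((p$R + p$L_g) / p$R) +
    log((p$R + p$L_g + p$L_b) / (p$R + p$L_g))
  t_o2 <- (2 * p$d_O2 / p$R^2) / rho * (p$O2_far - st[["O2"]])
  expected <- c(CH2O = v_cf - v_cs - v_rp, CS = v_cs, N = v_nf,
                O2 = (0.25 * (1 - f_aet) * v_pet - v_rp) * p$QC + t_o2)

  got <- derivatives(t, st, p, f, cfg)[[1]]
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("dark limit and empty start produce no spurious fluxes", {
  st0 <- c(CH2O = 0, CS = 0, N = 0, O2 = p$O2_far)
  expect_equal(unname(derivatives(0, st0, p, f, cfg)[[1]]), rep(0, 4))
  # O2 above ambient in the dark relaxes back by diffusion only
  st1 <- c(CH2O = 0, CS = 0, N = 0, O2 = 2 * p$O2_far)
  d1 <- derivatives(0, st1, p, f, cfg)[[1]]
  expect_equal(unname(d1[1:3]), rep(0, 3))
  expect_lt(d1[["O2"]], 0)
})

test_that("biosynthesis solves the coupled mass-energy balance", {
  # closed form: Bio_C = (CH2O + CS) / 1.44 with the default quotas
  b <- biosynthesis(0.2, 0.088, 1, p)
  expect_equal(b$Bio_C, 0.2, tolerance = 1e-12)
  expect_false(b$capped)
  # independent numeric solve of the 2x2 system as oracle
  ch2o <- 0.31; cs <- 0.07
  resp <- uniroot(function(x) {
    (ch2o - x + cs) * p$qBIO_ATP * (1 + p$gamma_MT) - x * p$qRESP_ATP
  }, c(0, ch2o))$root
  b2 <- biosynthesis(ch2o, cs, 1, p)
  expect_equal(b2$CH2O_resp, resp, tolerance = 1e-8)
  expect_equal(b2$Bio_C, ch2o - resp + cs, tolerance = 1e-8)

  expect_equal(biosynthesis(0.2, 0.1, 0, p)$Bio, 0)     # no N, no biomass
  expect_equal(biosynthesis(0, 0, 0.05, p)$Bio_C, 0)    # no C, no biomass

  # respiration demand above the carbohydrate pool: capped and flagged
  b3 <- biosynthesis(0.01, 0.1, 1, p)
  expect_true(b3$capped)
  expect_equal(b3$CH2O_resp, 0.01)
  expect_equal(b3$Bio_C, min(0.01 * p$qRESP_ATP / (p$qBIO_ATP * 1.1), 0.1),
               tolerance = 1e-12)
})

test_that("growth rate is the log relative biomass increase per day", {
  expect_equal(growth_rate(0), 0)
  expect_equal(growth_rate(exp(1) - 1), 1)
  expect_equal(growth_rate(exp(0.25) - 1), 0.25)
})

test_that("a standard unified run conserves mass and closes every budget", {
  r <- std_run("unified")
  ig <- r$integrals
  # carbon: gross fixed C ends up in pools plus respiratory protection
  pools <- r$state_end[["CH2O"]] + r$state_end[["CS"]]
  expect_equal(pools + ig$rp_C, ig$gross_C, tolerance = 1e-4)
  # nitrogen: all fixed N is stored (no losses in the unified trichome)
  expect_equal(r$state_end[["N"]], ig$gross_N, tolerance = 1e-4)
  # O2: production - consumption + diffusion accounts for the storage change
  dO2 <- (r$series$O2[nrow(r$series)] - r$series$O2[1]) / p$QC
  expect_equal(ig$o2_production - ig$o2_rp + ig$o2_diffusion, dO2,
               tolerance = 1e-4 * ig$o2_production)
  # instantaneous currency closure on the whole grid
  with(r$series, {
    expect_equal(ATP_NF + ATP_CF_CCM + ATP_MT, ATP_supply,
                 tolerance = 1e-10)
    expect_equal(NADPH_NF + NADPH_CF, NADPH_supply, tolerance = 1e-10)
  })
  # budget fractions close
  b <- daily_budgets(r)
  expect_equal(sum(b$carbon), 1, tolerance = 1e-6)
  expect_equal(sum(b$atp), 1, tolerance = 1e-6)
  expect_equal(sum(b$atp_source), 1, tolerance = 1e-6)
  expect_equal(sum(b$nadph), 1, tolerance = 1e-6)
})

test_that("the diel rhythm shows temporal segregation and a low-O2 window", {
  r <- std_run("unified")
  ig <- r$integrals
  expect_lt(ig$peak_t_CF, p$T_light / 4)          # morning C-fixation peak
  expect_gt(ig$peak_t_NF, p$T_light / 4)          # N2 fixation later
  expect_lt(ig$peak_t_NF, p$T_light)
  # intracellular O2 drops below ambient while N2 fixation is active
  i_nf <- which.max(r$series$V_NF)
  expect_lt(r$series$O2[i_nf], p$O2_far)
})

test_that("the growth rate is stable against tighter solver tolerances", {
  r <- std_run("unified")
  tight <- integrate_diel(p, f, run_config(rtol = cfg$rtol / 10,
                                           atol = cfg$atol / 10))
  expect_equal(tight$G, r$G, tolerance = 1e-3)
})
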