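p <- fixed_parameters()

test_that("irradiance follows the half-sine light period", {
  expect_equal(irradiance(0, p), 0)
  expect_equal(irradiance(p$T_light, p), 0, tolerance = 1e-9)
  expect_equal(irradiance(p$T_light / 2, p), p$I_max)
  expect_equal(irradiance(p$T_light / 6, p), 0.5 * p$I_max)
  expect_error(irradiance(-1, p), "light period")
  expect_error(irradiance(p$T_light + 1, p), "light period")
})

test_that("PET light response saturates exponentially", {
  expect_equal(pet_light_potential(0, p), 0)
  expect_equal(pet_light_potential(1e9, p), p$vPET_max)
  expect_equal(pet_light_potential(log(2) / p$alpha_I, p), 0.5 * p$vPET_max)
  I <- seq(0, 3000, by = 100)
  expect_true(all(diff(pet_light_potential(I, p)) > 0))
})

test_that("respiratory protection inhibits PET exponentially", {
  expect_equal(pet_rate(1e-3, 0, p), 1e-3)
  expect_equal(pet_rate(1e-3, log(2) / p$beta, p), 0.5e-3)
  expect_equal(pet_rate(0, 1e-4, p), 0)
})

test_that("required AET fraction reproduces the printed stoichiometric values", {
  expect_equal(as.numeric(required_aet_fraction(3, p)), 1 - 1.3 / 3,
               tolerance = 1e-12)
  expect_equal(round(100 * as.numeric(required_aet_fraction(3, p)), 1), 56.7)
  expect_equal(as.numeric(required_aet_fraction(1.9, p)), 1 - 1.3 / 1.9,
               tolerance = 1e-12)
  expect_equal(round(100 * as.numeric(required_aet_fraction(1.9, p)), 1), 31.6)
  expect_equal(as.numeric(required_aet_fraction(1.3, p)), 0)
  low <- required_aet_fraction(1.1, p)
  expect_equal(as.numeric(low), 0)
  expect_equal(attr(low, "limitation"), "NADPH_limited")
})

test_that("energy allocation closes both currencies with N2-fixation priority", {
  V_PET <- 6e-4
  s <- 1 + p$gamma_MT

  # no energy -> nothing happens
  none <- allocate_energy(0, 1e-5, p)
  expect_equal(none$V_NF + none$V_CF + none$f_AET, 0)
  expect_equal(none$limitation_flag, "light_limited")

  # NF requested beyond the ATP budget is capped, CF gets nothing
  cap <- p$qLPET_ATP * V_PET / (s * p$qNF_ATP)
  al <- allocate_energy(V_PET, 1, p)
  expect_equal(al$V_NF, cap)
  expect_equal(al$V_CF, 0)
  # pure-NF endpoint: supply ratio must be the NF ratio with the maintenance
  # load, f = 1 - 1.3 / (1.1 * 3)
  expect_equal(al$f_AET, 1 - (p$qLPET_ATP / p$qLPET_NADPH) /
                 (s * p$qNF_ATP / p$qNF_NADPH), tolerance = 1e-12)

  # pure-CF endpoint
  al0 <- allocate_energy(V_PET, 0, p)
  expect_equal(al0$V_NF, 0)
  expect_equal(al0$f_AET, 1 - (p$qLPET_ATP / p$qLPET_NADPH) /
                 (s * (p$qCF_ATP + p$qCCM_ATP) / p$qCF_NADPH),
               tolerance = 1e-12)

  # exact two-currency closure and continuity across the NF range
  req <- seq(0, cap, length.out = 21)
  f_prev <- al0$f_AET
  for (v in req) {
    a <- allocate_energy(V_PET, v, p)
    expect_equal(a$ATP_NF + a$ATP_CF_CCM + a$ATP_MT, a$ATP_supply,
                 tolerance = 1e-12)
    expect_equal(a$NADPH_NF + a$NADPH_CF, a$NADPH_supply, tolerance = 1e-12)
    expect_equal(a$O2_evolution, p$qLPET_O2 * (1 - a$f_AET) * V_PET)
    expect_gte(a$f_AET + 1e-12, f_prev)   # monotone in the NF share
    f_prev <- a$f_AET
  }

  # maintenance is the surcharge on process ATP
  a <- allocate_energy(V_PET, cap / 2, p)
  expect_equal(a$ATP_MT, p$gamma_MT * (a$ATP_NF + a$ATP_CF_CCM))
})

test_that("ablating AET pins f_AET at zero and boosts O2 evolution", {
  a <- allocate_energy(6e-4, 5e-6, p, ablate_AET = TRUE)
  expect_equal(a$f_AET, 0)
  expect_equal(a$O2_evolution, p$qLPET_O2 * 6e-4)
  # ATP still closes; NADPH now runs a surplus that is discarded
  expect_equal(a$ATP_NF + a$ATP_CF_CCM + a$ATP_MT, a$ATP_supply,
               tolerance = 1e-12)
  expect_gt(a$NADPH_supply, a$NADPH_NF + a$NADPH_CF)
})
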