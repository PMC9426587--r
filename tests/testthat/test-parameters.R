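test_that("fixed parameter defaults carry the published constants", {
  p <- fixed_parameters()
  expect_equal(p$qLPET_ATP, 0.65)
  expect_equal(p$qLPET_NADPH, 0.5)
  expect_equal(p$qLPET_O2, 0.25)
  expect_equal(p$qNF_ATP, 9)
  expect_equal(p$qNF_NADPH, 3)
  expect_equal(p$qCF_ATP + p$qCCM_ATP, 3.8)
  expect_equal(p$QC, 18333)
  expect_equal(p$O2_far, 0.213)
  expect_equal(p$f_D, 0.15)
  expect_equal(p$T_light, 43200)
  # derived geometry
  expect_equal(p$V, pi * p$R^2 * p$L)
  expect_equal(p$L_b, p$k_b * (p$R + p$L_g))
})

test_that("validation rejects bad values and inconsistent geometry, never clamps", {
  expect_error(fixed_parameters(qNF_ATP = -1), "qNF_ATP")
  expect_error(fixed_parameters(f_D = 1.2), "f_D")
  expect_error(fixed_parameters(nonsense = 1), "unknown fixed parameter")
  v <- with(fixed_parameters(), pi * R^2 * L)
  expect_error(fixed_parameters(V = 2 * v), "inconsistent")
  # volume within 0.1% of the cylinder is accepted
  expect_silent(fixed_parameters(V = v * 1.0005))
})

test_that("free parameters enforce the published search bounds", {
  expect_error(free_parameters(0.06, 3.7e-6, 0.58, 6e-4), "vRP_max")
  expect_error(free_parameters(1.5, 3.7e-6, 0.58, 4.5e-4), "kCSNF")
  f <- free_parameters(0, 0, 0, 0)
  expect_s3_class(f, "trd_free")
})

test_that("published optima differ only in vRP_max between variants", {
  u <- default_optimized_parameters("unified")
  s <- default_optimized_parameters("segregated")
  expect_equal(u$kCSNF, 0.06)
  expect_equal(u$vCS_max, 3.7e-6)
  expect_equal(u$kCH2O_CS, 0.58)
  expect_equal(u$vRP_max, 4.5e-4)
  expect_equal(s$vRP_max, 4.0e-4)
  expect_equal(u[c("kCSNF", "vCS_max", "kCH2O_CS")],
               s[c("kCSNF", "vCS_max", "kCH2O_CS")])
})

test_that("run configuration validates the experiment switches", {
  expect_error(run_config(transfer_loss = 0.9), "transfer_loss")
  expect_error(run_config(variant = "unified", transfer_loss = 0.2),
               "segregated")
  cfg <- run_config(variant = "segregated", transfer_loss = 0.5)
  expect_equal(cfg$transfer_loss, 0.5)
})

test_that("config files load with defaults, provenance and range checks", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("kO2NF: 1.0e-2", "epsilon: 1.0e-4", "variant: unified"), path)
  got <- load_config(path)
  expect_equal(got$fixed$kO2NF, 1e-2)
  expect_equal(got$fixed$epsilon, 1e-4)
  expect_equal(got$fixed$f_D, 0.15)      # default fills the omitted field
  expect_equal(got$provenance[["kO2NF"]], "file")
  expect_equal(got$provenance[["f_D"]], "default")
  # free parameters default to the published optima for the variant
  expect_equal(got$free$vRP_max, 4.5e-4)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("vRP_max: 6.0e-4", bad)
  expect_error(load_config(bad), "vRP_max")
  unk <- withr::local_tempfile(fileext = ".yaml")
  writeLines("vRPmax: 1.0e-4", unk)
  expect_error(load_config(unk), "unknown config key")
})

test_that("serialize/load round-trips every field exactly", {
  fixed <- fixed_parameters(alpha_I = 1 / 3, beta = exp(1) * 1e3)
  free <- default_optimized_parameters("segregated")
  config <- run_config(variant = "segregated", transfer_loss = 0.3)
  # JSON serialization round-trips bit-exactly
  path <- withr::local_tempfile(fileext = ".json")
  serialize_config(fixed, free, config, path)
  got <- load_config(path)
  expect_identical(unclass(got$fixed), unclass(fixed))
  expect_identical(unclass(got$free), unclass(free))
  expect_identical(got$config$transfer_loss, config$transfer_loss)
  # YAML (human-edited format) round-trips to emitter precision
  ypath <- withr::local_tempfile(fileext = ".yaml")
  serialize_config(fixed, free, config, ypath)
  ygot <- load_config(ypath)
  expect_equal(unclass(ygot$fixed), unclass(fixed), tolerance = 1e-12)
})
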