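test_that("mono-exponential attenuation matches analytic values", {
  expect_equal(mono_attenuation(500e-6, 8000), exp(-4))
  # remaining-signal percentages at b = 8000, to one decimal
  expect_equal(round(100 * mono_attenuation(500e-6, 8000), 1), 1.8)
  expect_equal(round(100 * mono_attenuation(10e-6, 8000), 1), 92.3)
  expect_equal(round(100 * mono_attenuation(2000e-6, 8000), 1), 0.0)
  expect_equal(mono_attenuation(0.123, 0), 1.0)
  expect_error(mono_attenuation(-1e-6, 100), "adc")
  expect_error(mono_attenuation(1e-6, -100), "b")
})

test_that("model evaluation reproduces hand-computed values", {
  # frozen from independent arithmetic evaluation of the closed forms
  expect_equal(eval_biexp(biexp_params(0.6, 600e-6, 2000e-6), 1000),
               0.6 * exp(-0.6) + 0.4 * exp(-2))
  expect_equal(round(eval_biexp(biexp_params(0.6, 600e-6, 2000e-6), 1000),
                     4), 0.3834)
  expect_equal(eval_triexp(
    triexp_params(0.15, 0.55, 100e-6, 600e-6, 2000e-6), 1000),
    0.15 * exp(-0.1) + 0.55 * exp(-0.6) + 0.30 * exp(-2))
  expect_equal(eval_triexp(
    triexp_params(0.15, 0.55, 100e-6, 600e-6, 2000e-6), 1000),
    0.47817, tolerance = 1e-5)
  expect_equal(round(eval_modtriexp(
    modtriexp_params(0.15, 0.55, 600e-6, 2000e-6), 8000), 5), 0.15453)
  # degenerate cases
  expect_equal(eval_biexp(biexp_params(1, 500e-6, 500e-6), 8000), exp(-4))
  expect_equal(eval_modtriexp(modtriexp_params(1, 0, 0, 0), 12345), 1.0)
})

test_that("all models return 1 at b = 0 and decay monotonically", {
  set.seed(42)
  bgrid <- c(0, 10, 50, 200, 1000, 3000, 5000, 8000)
  for (i in 1:30) {
    f1 <- runif(1, 0, 0.5); f2 <- runif(1, 0, 1 - f1)
    d <- sort(runif(3, 0, 4000e-6))
    ps <- list(biexp_params(f1, d[1], d[2]),
               triexp_params(f1, f2, d[1], d[2], d[3]),
               modtriexp_params(f1, f2, d[1], d[2]))
    for (p in ps) {
      v <- signal_model(p, bgrid)
      expect_equal(v[1], 1.0, tolerance = 1e-14)
      expect_true(all(v > 0 & v <= 1))
      expect_true(all(diff(v) <= 1e-15))
    }
  }
})

test_that("model nesting identities hold to machine precision", {
  set.seed(7)
  bgrid <- c(0, 100, 700, 2000, 5000, 8000)
  for (i in 1:20) {
    f1 <- runif(1, 0, 0.4); f2 <- runif(1, 0.1, 1 - f1)
    ds <- runif(1, 200e-6, 1500e-6); df <- runif(1, 1500e-6, 4000e-6)
    # triexp with zero very-slow ADC == modtriexp with f0 = f_very_slow
    expect_equal(eval_triexp(triexp_params(f1, f2, 0, ds, df), bgrid),
                 eval_modtriexp(modtriexp_params(f1, f2, ds, df), bgrid),
                 tolerance = 1e-15)
    # modtriexp with f0 = 0 == biexp
    expect_equal(eval_modtriexp(modtriexp_params(0, f2, ds, df), bgrid),
                 eval_biexp(biexp_params(f2, ds, df), bgrid),
                 tolerance = 1e-15)
  }
})

test_that("output increases with the diffusion-limited fraction f0", {
  b <- 3000
  f0s <- seq(0, 0.4, by = 0.05)
  vals <- vapply(f0s, function(f0)
    eval_modtriexp(modtriexp_params(f0, 0.4, 600e-6, 2000e-6), b),
    numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("parameter validation rejects invariant violations", {
  expect_error(biexp_params(1.2, 500e-6, 2000e-6), "f_slow")
  expect_error(biexp_params(0.5, 2000e-6, 500e-6), "adc_fast")
  expect_error(triexp_params(0.6, 0.6, 1e-6, 2e-6, 3e-6), "fractions")
  expect_error(triexp_params(0.1, 0.5, 5e-4, 1e-4, 1e-3), "ADCs")
  expect_error(modtriexp_params(-0.1, 0.5, 1e-4, 1e-3), "fractions")
})

test_that("predict_curve is consistent with pointwise evaluation", {
  sch <- default_bvalue_scheme()
  p <- wm_truth()
  cv <- predict_curve(p, sch)
  expect_s3_class(cv, "decay_curve")
  expect_identical(cv$s_over_s0[1], 1.0)
  expect_equal(cv$s_over_s0[17], eval_modtriexp(p, 8000))
  # pure limited compartment never decays
  ones <- predict_curve(modtriexp_params(1, 0, 0, 0), sch)
  expect_equal(ones$s_over_s0, rep(1, 17))
  ones2 <- predict_curve(biexp_params(1, 0, 0), sch)
  expect_equal(ones2$s_over_s0, rep(1, 17))
  expect_error(predict_curve(p, sch, model = "biexp"), "match")
})

test_that("normalization divides by S0 and guards against bad voxels", {
  sch <- bvalue_scheme(c(0, 1000, 3000), c(1L, 3L, 5L))
  cv <- normalize_signal(c(100, 50, 20), sch)
  expect_equal(cv$s_over_s0, c(1, 0.5, 0.2))
  expect_equal(cv$s0, 100)
  expect_equal(normalize_signal(c(7, 7, 7), sch)$s_over_s0, rep(1, 3))
  expect_error(normalize_signal(c(0, 50, 20), sch),
               class = "triexpdwi_unfittable")
  expect_error(normalize_signal(c(100, NA, 20), sch),
               class = "triexpdwi_unfittable")
})

test_that("parameters round-trip through flat config and YAML", {
  for (p in list(biexp_params(0.37, 410e-6, 2200e-6),
                 triexp_params(0.12, 0.48, 90e-6, 640e-6, 2100e-6),
                 wm_truth())) {
    cfg <- params_to_config(p)
    expect_equal(params_from_config(cfg), p)
    # model id also inferred from keys alone
    cfg$model <- NULL
    expect_equal(params_from_config(cfg), p)
    f <- tempfile(fileext = ".yaml")
    write_params_yaml(p, f)
    expect_equal(read_params_yaml(f), p, tolerance = 1e-9)
    unlink(f)
  }
})

test_that("b-value scheme validates and round-trips through sidecars", {
  expect_error(bvalue_scheme(c(10, 20), c(1, 1)), "first")
  expect_error(bvalue_scheme(c(0, 20, 20), c(1, 1, 1)), "increasing")
  expect_error(bvalue_scheme(c(0, 20), c(1, 0)), "NSA")
  sch <- default_bvalue_scheme()
  expect_length(sch$b_values, 17)
  expect_identical(sch$nsa[17], 12L)
  f <- tempfile()
  write_bvalue_table(sch, f)
  rt <- read_bvalue_table(f)
  expect_equal(rt$b_values, sch$b_values)
  expect_equal(rt$nsa, sch$nsa)
  # FSL-style single-row file: NSA defaults to 1
  writeLines("0 10 100 1000", f)
  fsl <- read_bvalue_table(f)
  expect_equal(fsl$nsa, rep(1L, 4))
  unlink(f)
})
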