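test_that("default initial values follow the voxel-wise protocol", {
  b <- default_init("biexp")
  expect_equal(b$f_slow, 0.50)
  expect_equal(b$adc_slow, 600e-6)
  expect_equal(b$adc_fast, 2000e-6)
  m <- default_init("modtriexp")
  expect_equal(m$f0, 0.10)
  expect_equal(m$f_slow, 0.50)
  t <- default_init("triexp")
  expect_equal(t$f_very_slow, 0.10)
  expect_equal(t$adc_very_slow, 100e-6)
  expect_error(default_init("monoexp"))
})

test_that("noise-free curves are recovered to numerical precision", {
  sch <- default_bvalue_scheme()
  truth <- c(f0 = 0.15, f_slow = 0.58, adc_slow = 816e-6,
             adc_fast = 4525e-6)
  fit <- fit_voxel("modtriexp", predict_curve(wm_truth(), sch))
  expect_lt(fit$rss, 1e-10)
  expect_lt(rel_err(fit$params, truth), 1e-3)
  expect_equal(fit$n_points, 16L)
  expect_equal(fit$k, 4L)
})

test_that("fitting the richer model to nested truth zeroes the extra term", {
  sch <- default_bvalue_scheme()
  cv <- predict_curve(biexp_params(0.6, 600e-6, 2000e-6), sch)
  fit <- fit_voxel("modtriexp", cv)
  expect_lte(fit$params$f0, 1e-3)
  expect_lt(fit$rss, 1e-10)
})

test_that("accepted descent iterations never increase the objective", {
  cv <- sim_voxel_curve(wm_truth(), seed = 11)
  fit <- fit_voxel("modtriexp", cv, init = default_init("modtriexp"),
                   trace = TRUE)
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("fit results always satisfy the parameter invariants", {
  set.seed(20)
  for (i in 1:10) {
    cv <- sim_voxel_curve(random_modtriexp(), seed = 100 + i)
    for (m in c("biexp", "triexp", "modtriexp")) {
      fit <- fit_voxel(m, cv)
      p <- fit$params
      expect_s3_class(validate_params(p), "dwi_params")  # would error
      expect_gte(f_fast(p), -1e-12)
      expect_lte(p$adc_slow, p$adc_fast)
      expect_gte(fit$rss, 0)
    }
  }
})

test_that("the grid oracle brackets and the descent fit matches it", {
  sch <- default_bvalue_scheme()
  cv <- predict_curve(wm_truth(), sch)
  # single-point lattice returns that point's RSS
  pt <- list(f0 = 0.15, f_slow = 0.58, adc_slow = 816e-6,
             adc_fast = 4525e-6)
  o1 <- grid_oracle("modtriexp", cv, lapply(pt, identity), polish = FALSE)
  expect_lt(o1$rss, 1e-20)
  # lattice containing the truth finds it
  gs <- list(f0 = c(0.05, 0.15, 0.3), f_slow = c(0.4, 0.58, 0.7),
             adc_slow = c(400e-6, 816e-6), adc_fast = c(2000e-6, 4525e-6))
  o2 <- grid_oracle("modtriexp", cv, gs, polish = FALSE)
  expect_lt(o2$rss, 1e-20)
  expect_error(grid_oracle("modtriexp", cv,
                           list(f0 = 2, f_slow = 2, adc_slow = 1,
                                adc_fast = 0.5)), "lattice")
  # on noisy curves the descent fit is never above the polished oracle
  for (i in 1:5) {
    cvn <- sim_voxel_curve(random_modtriexp(), seed = 200 + i)
    for (m in c("biexp", "modtriexp")) {
      expect_lte(fit_voxel(m, cvn)$rss,
                 grid_oracle(m, cvn)$rss + 1e-8)
    }
  }
})

test_that("richer nested models never fit worse (oracle-polished)", {
  for (i in 1:5) {
    cv <- sim_voxel_curve(random_modtriexp(), seed = 300 + i)
    # best-found optima: grid-polished plus descents seeded by embedding
    # the nested model's optimum into the richer model
    fb <- fit_voxel("biexp", cv)
    r_bi <- min(grid_oracle("biexp", cv)$rss, fb$rss)
    embed_bi <- modtriexp_params(0, fb$params$f_slow, fb$params$adc_slow,
                                 fb$params$adc_fast)
    fm <- fit_voxel("modtriexp", cv)
    r_mod <- min(grid_oracle("modtriexp", cv)$rss, fm$rss,
                 fit_voxel("modtriexp", cv, init = embed_bi)$rss)
    embed_mod <- triexp_params(fm$params$f0, fm$params$f_slow, 0,
                               fm$params$adc_slow, fm$params$adc_fast)
    r_tri <- min(grid_oracle("triexp", cv)$rss,
                 fit_voxel("triexp", cv, init = embed_mod)$rss)
    expect_lte(r_mod, r_bi + 1e-8)
    expect_lte(r_tri, r_mod + 1e-8)
  }
})

test_that("random-initialization stability: one optimum from any start", {
  sch <- default_bvalue_scheme()
  cv <- predict_curve(wm_truth(), sch)
  st <- stability_experiment("modtriexp", cv, n_sets = 8, seed = 3)
  expect_true(all(st$sd < 1e-4 * abs(st$mean)))
  expect_setequal(st$parameter,
                  c("f0", "f_slow", "adc_slow", "adc_fast", "f_fast"))
  # deterministic given the seed
  st2 <- stability_experiment("modtriexp", cv, n_sets = 8, seed = 3)
  expect_identical(st, st2)
  expect_error(stability_experiment("modtriexp", cv, n_sets = 1), "n_sets")
  expect_error(stability_experiment("modtriexp", cv,
                                    ranges = list(f0 = c(0.2, 0.1)),
                                    n_sets = 2), "bound")
})

test_that("volume fitting produces display-unit maps and handles bad voxels", {
  sch <- default_bvalue_scheme()
  clean <- 560 * predict_curve(wm_truth(), sch)$s_over_s0
  data <- array(rep(clean, each = 4), c(2, 2, 1, 17))
  maps <- fit_volume("modtriexp", data, sch)
  # uniform input -> constant maps equal to the single-voxel fit
  expect_equal(max(maps$f0) - min(maps$f0), 0)
  expect_equal(maps$f0[1, 1, 1], 15, tolerance = 1e-3)       # percent
  expect_equal(maps$adc_slow[1, 1, 1], 816, tolerance = 1e-3) # 1e-6 mm^2/s
  expect_equal(maps$f_fast[1, 1, 1], 27, tolerance = 1e-3)
  expect_identical(attr(maps, "n_unfittable"), 0L)
  # a dead voxel (S0 = 0) is NA and counted, others unaffected
  data[1, 1, 1, ] <- 0
  maps2 <- fit_volume("modtriexp", data, sch)
  expect_true(is.na(maps2$f0[1, 1, 1]))
  expect_identical(attr(maps2, "n_unfittable"), 1L)
  expect_equal(maps2$f0[2, 2, 1], 15, tolerance = 1e-3)
  # empty mask warns
  expect_warning(fit_volume("modtriexp", data, sch,
                            mask = array(FALSE, c(2, 2, 1))), "no voxels")
  expect_error(fit_volume("modtriexp", data[, , , 1:5], sch), "4th")
})
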