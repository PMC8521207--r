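test_that("background subtraction nets readings and invalidates instead of clamping", {
  bg <- list(bg_sup = 30, bg_lys = 70)
  out <- subtract_background(c(130, 20, NA), c(270, 100, 100), bg)
  expect_equal(out$fi_sup_net[1], 100)
  expect_equal(out$fi_lys_net[1], 200)
  expect_true(out$valid[1])
  expect_false(out$valid[2])
  expect_equal(out$invalid_reason[2], "negative net supernatant")
  expect_false(out$valid[3])
  expect_equal(out$invalid_reason[3], "missing supernatant read")
})

test_that("per-well CEC is the supernatant share of total and is exactly gain invariant", {
  expect_equal(cec_per_well(30, 70), 30)
  expect_equal(cec_per_well(0, 50), 0)
  expect_true(is.na(cec_per_well(0, 0)))

  withr::with_seed(11, {
    sup <- stats::runif(200, 0, 1e4)
    lys <- stats::runif(200, 1, 1e4)
    base <- cec_per_well(sup, lys)
    # power-of-two gains scale both reads exactly: bit-identical result
    for (g in c(0.5, 2, 1024, 2^-20)) {
      expect_identical(cec_per_well(g * sup, g * lys), base)
    }
    # arbitrary positive gains: invariant to machine precision
    for (g in c(1e-6, 0.37, 3, 1e7)) {
      expect_equal(cec_per_well(g * sup, g * lys), base, tolerance = 1e-13)
    }
    # conservation: supernatant share + lysate share = 100
    expect_equal(base + 100 * lys / (sup + lys), rep(100, 200),
                 tolerance = 1e-13)
  })
})

test_that("t0 CEC references the plate t0 mean, flags over-range, fails on bad reference", {
  expect_equal(as.numeric(cec_t0(25, 100)), 25)
  over <- cec_t0(c(110, 90), 100)
  expect_equal(as.numeric(over), c(110, 90))
  expect_identical(attr(over, "over_range"), c(TRUE, FALSE))
  expect_error(cec_t0(50, 0), "t0 reference")
  expect_error(cec_t0(50, -5), "t0 reference")

  # t0 CEC is gain invariant when numerator and reference share the gain
  withr::with_seed(12, {
    sup <- stats::runif(50, 0, 500)
    expect_identical(as.numeric(cec_t0(4 * sup, 4 * 250)),
                     as.numeric(cec_t0(sup, 250)))
    expect_equal(as.numeric(cec_t0(3 * sup, 3 * 250)),
                 as.numeric(cec_t0(sup, 250)), tolerance = 1e-13)
  })
})

test_that("plate context arithmetic: t0 reference, t0 CV, passive means", {
  rec <- data.frame(
    plate_id = "P01",
    well = c("A1", "B1", "C1", "D1", "E1", "F1"),
    role = c(rep("t0_control", 3), rep("passive", 3)),
    fi_sup_raw = c(95, 100, 105, 4, 5, 6),
    fi_lys_raw = c(NA, NA, NA, 96, 95, 94))
  ctx <- plate_context(rec, bg = list(bg_sup = 0, bg_lys = 0))
  expect_equal(ctx$t0_reference, 100)
  expect_equal(ctx$t0_cv, 5)           # n-1 SD convention
  expect_equal(ctx$passive_cec_perwell, 5)
  expect_equal(ctx$passive_cec_t0, 5)
  expect_false(ctx$t0_failed)
  expect_error(plate_context(rec[1:4, ], bg = list(bg_sup = 0, bg_lys = 0)),
               "passive")
})

test_that("passive subtraction is a plain shift retaining negatives", {
  expect_equal(finalize_well_cec(30, 5), 25)
  expect_equal(finalize_well_cec(5, 5), 0)
  expect_equal(finalize_well_cec(3, 5), -2)
})

test_that("noise-free simulation recovers passive efflux and background exactly", {
  cfg <- nf_config(passive_frac = 0.05, lysis_residual = 0,
                   background_level = 40, rng_seed = 17L)
  run <- simulate_run(cfg, samples_per_plate = 6)
  wt <- compute_wells(run_records(run))
  expect_equal(wt$plates$passive_cec_perwell, 5, tolerance = 1e-12)
  expect_equal(wt$plates$bg_sup, 40, tolerance = 1e-12)
})

test_that("background estimate recovers the simulated level within 3 standard errors", {
  cfg <- sim_config(meas_cv = 0.05, background_level = 50, rng_seed = 19L)
  run <- simulate_run(cfg, samples_per_plate = 6)
  wt <- compute_wells(run_records(run))
  se <- 50 * 0.05 / sqrt(3)
  expect_lt(abs(wt$plates$bg_sup - 50), 3 * se)
})

test_that("doubling seeded cells at a fixed t0 reference doubles mean t0 CEC", {
  cfg <- nf_config(efflux_km = 0, background_level = 0, rng_seed = 23L)
  base <- withr::with_seed(1, run_design(cfg, samples_per_plate = 6,
                                         emax_shifts = rep(1, 6)))
  doubled <- base
  doubled$seed_multiplier[doubled$role == "sample"] <- 2
  m <- vapply(list(base, doubled), function(d) {
    wt <- compute_wells(run_records(simulate_run(cfg, design = d)))
    mean(wt$wells$cec_t0_raw[wt$wells$role == "sample"])
  }, numeric(1))
  expect_equal(m[2] / m[1], 2, tolerance = 1e-12)
})

test_that("resazurin net ratio follows the 570/600 blank-subtracted definition", {
  expect_equal(resazurin_ratio(1.2, 0.8, 0.1), 1.4)
  expect_equal(resazurin_ratio(0.9, 0.9, 1.0), 0)
  expect_true(is.na(resazurin_ratio(1.2, 0, 0.1)))
})

test_that("resazurin normalization rescales to the plate mean and inflates per-well interassay CV", {
  expect_equal(normalize_to_resazurin(20, 1, 1), 20)
  expect_equal(normalize_to_resazurin(20, 2, 1), 10)

  st <- std_study()
  wt <- st$pipeline$wells
  mon <- wt$wells[wt$wells$role == "monitoring_control", ]
  pm <- wt$plates$resazurin_plate_mean[match(mon$plate_id, wt$plates$plate_id)]
  mon$norm <- normalize_to_resazurin(mon$cec_per_well,
                                     mon$resazurin_net_ratio, pm)
  for (ctrl in unique(mon$sample_id)) {
    g <- mon[mon$sample_id == ctrl, ]
    plain <- tapply(g$cec_per_well, g$plate_id, mean, na.rm = TRUE)
    norm <- tapply(g$norm, g$plate_id, mean, na.rm = TRUE)
    expect_gt(interassay_cv(norm), interassay_cv(plain))
  }
})
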