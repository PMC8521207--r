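mk_wells <- function(..., plate_id = "P01", role = "sample") {
  reps <- list(...)
  do.call(rbind, lapply(names(reps), function(sid) {
    v <- reps[[sid]]
    data.frame(plate_id = plate_id, sample_id = sid, role = role,
               cec_per_well_raw = v, cec_per_well = v,
               valid_per_well = !is.na(v))
  }))
}

test_that("replicate aggregation applies the strict >15% CV rejection rule", {
  cfg <- qc_config()
  w <- mk_wells(tight = c(10, 10, 10),
                boundary = c(8.5, 10, 11.5),   # CV exactly 15.0%
                wide = c(8, 10, 12),           # CV 20%
                short = c(9, 10, NA))
  res <- aggregate_samples(w, "per_well", cfg)
  res <- res[match(c("tight", "boundary", "wide", "short"), res$sample_id), ]

  expect_equal(res$cv, c(0, 15, 20, cv_pct(c(9, 10))))
  expect_equal(res$rejected, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$reject_reason[3], "replicate CV above threshold")
  expect_equal(res$reject_reason[4], "insufficient wells")
  expect_equal(res$mean_cec[2], 10)
  expect_equal(res$sd_cec[2], 1.5)
})

test_that("rejection rate is rejected over total in percent to two decimals", {
  expect_equal(rejection_rate(68, 506), 13.44)
  expect_equal(rejection_rate(24, 506), 4.74)
  expect_equal(rejection_rate(0, 321), 0)
  expect_error(rejection_rate(1, 0), "n_total")
})

test_that("the four-control factor is the mean relative deviation and divides out", {
  obs <- mk_wells(CC1 = c(9, 9, 9), CC2 = c(9, 9, 9), CC3 = c(9, 9, 9),
                  CC4 = c(9, 9, 9), S1 = c(18, 18, 18),
                  role = "correction_control")
  obs$role[obs$sample_id == "S1"] <- "sample"
  agg <- aggregate_samples(obs, "per_well")
  pc <- plate_corrections(agg, expected = c(CC1 = 10, CC2 = 10,
                                            CC3 = 10, CC4 = 10))
  expect_equal(pc$plates$factor, 0.9)
  expect_equal(pc$samples$corrected_cec[pc$samples$sample_id == "S1"],
               18 / 0.9)

  pc2 <- plate_corrections(agg, expected = c(CC1 = 9, CC2 = 9,
                                             CC3 = 9, CC4 = 9))
  expect_equal(pc2$plates$factor, 1)
  expect_equal(pc2$samples$corrected_cec, pc2$samples$mean_cec)
})

test_that("noise-free multiplicative plate effects are corrected exactly", {
  # multiplicative bias on active efflux maps to a multiplicative bias on
  # passive-subtracted CEC only with full label recovery at lysis
  cfg <- nf_config(plate_efflux_sd = 0.15, lysis_residual = 0,
                   n_plates = 4, rng_seed = 29L)
  run <- simulate_run(cfg, samples_per_plate = 6)
  wt <- compute_wells(run_records(run))
  for (m in c("per_well", "t0")) {
    agg <- aggregate_samples(wt, m)
    pc <- plate_corrections(agg)
    mon <- pc$samples[pc$samples$role == "monitoring_control", ]
    for (ctrl in unique(mon$sample_id)) {
      x <- mon$corrected_cec[mon$sample_id == ctrl]
      expect_lt(interassay_cv(x), 1e-10)
    }
    # correction never changes within-plate ratios
    s <- pc$samples[pc$samples$plate_id == "P02" & pc$samples$role == "sample", ]
    expect_equal(s$corrected_cec / s$corrected_cec[1],
                 s$mean_cec / s$mean_cec[1], tolerance = 1e-12)
  }
})

test_that("a rejected control drops to three with a warning, below three leaves the plate uncorrected", {
  w <- mk_wells(CC1 = c(10, 10, 10), CC2 = c(10, 10, 10),
                CC3 = c(10, 10, 10), CC4 = c(5, 10, 15),  # CV 50% -> rejected
                role = "correction_control")
  agg <- aggregate_samples(w, "per_well")
  expect_warning(pc <- plate_corrections(agg, expected = c(
    CC1 = 10, CC2 = 10, CC3 = 10, CC4 = 10)), "3 controls")
  expect_equal(pc$plates$n_controls, 3)
  expect_equal(pc$plates$factor, 1)

  w2 <- mk_wells(CC1 = c(10, 10, 10), CC2 = c(10, 10, 10),
                 CC3 = c(5, 10, 15), CC4 = c(5, 10, 15),
                 role = "correction_control")
  agg2 <- aggregate_samples(w2, "per_well")
  expect_warning(pc2 <- plate_corrections(agg2, expected = c(
    CC1 = 10, CC2 = 10, CC3 = 10, CC4 = 10)), "uncorrected")
  expect_true(pc2$plates$uncorrected)
})

test_that("interassay CV uses the n-1 SD over plates", {
  expect_equal(interassay_cv(rep(7.3, 10)), 0)
  expect_equal(interassay_cv(c(9, 10, 11)), 10)
})

test_that("relative reductions are whole percents, half-up", {
  expect_equal(relative_reduction(13.44, 4.74), 65)
  expect_equal(relative_reduction(5.28, 4.48), 15)
  expect_equal(relative_reduction(7, 7), 0)
  expect_equal(relative_reduction(10, 11), -10)
  expect_true(is.na(relative_reduction(0, 1)))
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(35.5), 36)
})

test_that("the performance report assembles both methods with comparisons", {
  st <- std_study()
  rep <- st$pipeline$report
  expect_named(rep$methods, c("per_well", "t0"))
  for (m in rep$methods) {
    expect_equal(m$rejection_rate,
                 rejection_rate(m$n_rejected, m$n_total))
    expect_true(is.finite(m$intra_assay_cv))
    expect_equal(nrow(m$interassay), 2)
    expect_true(all(is.finite(m$interassay$cv_corrected)))
  }
  cmp <- rep$comparison
  expect_equal(cmp$rejection_rate,
               relative_reduction(rep$methods$t0$rejection_rate,
                                  rep$methods$per_well$rejection_rate))
  expect_equal(nrow(cmp$interassay), 2)
})
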