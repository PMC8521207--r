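test_that("Bland-Altman bias and 2-SD limits of agreement", {
  ident <- bland_altman(c(10, 12, 14), c(10, 12, 14))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_high - ident$loa_low, 0)

  ba <- bland_altman(c(1, 0), c(0, 1))   # diffs (1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, -2 * sqrt(2))
  expect_equal(ba$loa_high, 2 * sqrt(2))

  expect_error(bland_altman(5, 4), "2 complete pairs")
  expect_error(bland_altman(c(5, NA), c(4, 3)), "2 complete pairs")
})

test_that("Bland-Altman is antisymmetric in the measurement order", {
  withr::with_seed(41, {
    for (i in 1:5) {
      m1 <- stats::rnorm(20, 10, 2); m2 <- stats::rnorm(20, 9, 2)
      a <- bland_altman(m1, m2); b <- bland_altman(m2, m1)
      expect_equal(a$mean_diff, -b$mean_diff)
      expect_equal(a$loa_low, -b$loa_high)
      expect_equal(a$loa_high, -b$loa_low)
    }
  })
})

test_that("saturation fit recovers exact Michaelis-Menten parameters", {
  A <- c(0.25, 0.5, 1, 2, 4)
  y <- 12 * A / (1 + A)
  fit <- fit_saturation(A, y)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 12, tolerance = 1e-6)
  expect_equal(fit$km, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_error(fit_saturation(c(1, 2), c(3, 4)), "3 distinct")
})

test_that("saturation fit matches a 200x200 grid-search oracle on noisy data", {
  A <- c(0.25, 0.5, 1, 2, 4, 8)
  y <- 10 * A / (0.8 + A) + c(0.21, -0.34, 0.12, -0.05, 0.3, -0.17)
  fit <- fit_saturation(A, y)

  vgrid <- seq(5, 20, length.out = 200)
  kgrid <- seq(0.05, 4, length.out = 200)
  rss <- outer(vgrid, kgrid, function(v, k)
    vapply(seq_along(v), function(i)
      sum((y - v[i] * A / (k[i] + A))^2), numeric(1)))
  best <- arrayInd(which.min(rss), dim(rss))
  expect_lt(abs(fit$vmax - vgrid[best[1]]), diff(vgrid[1:2]) + 1e-9)
  expect_lt(abs(fit$km - kgrid[best[2]]), diff(kgrid[1:2]) + 1e-9)
  expect_lte(fit$rss, min(rss) + 1e-9)
})

test_that("flat dose-response collapses to the saturated boundary", {
  fit <- fit_saturation(c(0.5, 1, 2, 4), rep(7, 4))
  expect_equal(fit$vmax, 7, tolerance = 1e-4)
  expect_true(fit$km_boundary)
})

test_that("simulated acceptor sweeps reproduce the saturating curve and its parameters", {
  cfg <- nf_config(lysis_residual = 0, background_level = 0, rng_seed = 37L)
  run <- simulate_run(cfg, design = acceptor_sweep_design(cfg))
  wt <- compute_wells(run_records(run))
  w <- wt$wells[wt$wells$role == "sample", ]
  m <- tapply(w$cec_per_well, w$acceptor_pct, mean)
  A <- as.numeric(names(m))
  ord <- order(A)
  expect_true(all(diff(m[ord]) > 0))   # monotone saturating rise
  fit <- fit_saturation(A, as.numeric(m))
  expect_equal(fit$vmax, cfg$efflux_emax, tolerance = 1e-6)
  expect_equal(fit$km, cfg$efflux_km, tolerance = 1e-6)
})

test_that("seeding-bias regression estimates the common slope per SD with per-sample intercepts", {
  # identical CEC everywhere: slope exactly 0
  r <- rep(c(1, 2, 3), 4)
  sid <- rep(c("S1", "S2"), each = 6)
  flat <- seeding_bias(rep(10, 12), r, sid)
  expect_equal(flat$slope_per_sd, 0, tolerance = 1e-12)

  # constructed noise-free slope of 3 per SD, distinct intercepts
  z <- (r - mean(r)) / stats::sd(r)
  cec <- ifelse(sid == "S1", 8, 12) + 3 * z
  fit <- seeding_bias(cec, r, sid)
  expect_equal(fit$slope_per_sd, 3, tolerance = 1e-10)
  expect_lt(fit$ci95_high - fit$ci95_low, 1e-8)
  expect_equal(unname(sort(fit$intercepts)), c(8, 12), tolerance = 1e-10)

  # slope invariant to shifting all ratios by a constant
  shifted <- seeding_bias(cec, r + 5, sid)
  expect_equal(shifted$slope_per_sd, fit$slope_per_sd, tolerance = 1e-10)

  expect_error(seeding_bias(cec[1:6], r[1:6], sid[1:6]), ">= 2 samples")
  expect_error(seeding_bias(cec, rep(1, 12), sid), "zero variance")
})

test_that("the seeding-error design biases t0 CEC up and per-well CEC down per SD of resazurin", {
  st <- seed_study()
  w <- st$wells$wells[st$wells$wells$role == "sample", ]
  t0 <- seeding_bias(w$cec_t0, w$resazurin_net_ratio, w$sample_id)
  pw <- seeding_bias(w$cec_per_well, w$resazurin_net_ratio, w$sample_id)
  expect_gt(t0$slope_per_sd, 0)
  expect_gt(t0$ci95_low, 0)
  expect_lt(pw$slope_per_sd, 0)
  expect_lt(pw$ci95_high, 0)
})

test_that("cAMP contrast is the Welch difference of condition means", {
  expect_error(camp_contrast(c(10, 8), c("cAMP", "no_cAMP")), ">= 2 samples")
  same <- camp_contrast(c(10, 10, 10, 10), c("cAMP", "cAMP", "no_cAMP", "no_cAMP"))
  expect_equal(same$diff, 0)
  expect_equal(same$ci95_low, 0)
  expect_equal(same$ci95_high, 0)

  cfg <- sim_config(rng_seed = 43L)
  run <- simulate_run(cfg, samples_per_plate = 12,
                      condition = c("cAMP", "no_cAMP"))
  agg <- aggregate_samples(compute_wells(run_records(run)), "per_well")
  smp <- agg[agg$role == "sample", ]
  d <- unique(run$design[run$design$role == "sample",
                         c("sample_id", "condition")])
  cond <- d$condition[match(smp$sample_id, d$sample_id)]
  ct <- camp_contrast(smp$mean_cec, cond)
  expect_gt(ct$diff, 0)
  expect_gt(ct$ci95_low, 0)
})
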