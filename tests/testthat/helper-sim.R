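# Shared fixtures: a noise-free configuration builder and a cached
# standard-scale simulated study, so expensive objects are built once per
# test run.

nf_config <- function(...) {
  defaults <- list(seeding_cv = 0, stain_cv = 0, plate_gain_sd = 0,
                   plate_efflux_sd = 0, t0_mismatch_sd = 0, meas_cv = 0,
                   detach_rate = 0, sample_cv = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# 25 plates x 20 samples: the scaled-down cohort-style study
std_study <- function() {
  fixture("std_study", function() {
    cfg <- sim_config(n_plates = 25, rng_seed = 101L)
    run <- simulate_run(cfg, samples_per_plate = 20)
    list(cfg = cfg, run = run,
         pipeline = suppressWarnings(run_pipeline(run)))
  })
}

# deliberate seeding-error plate (0.5/0.75/1/1.5 x standard cells)
seed_study <- function() {
  fixture("seed_study", function() {
    cfg <- sim_config(rng_seed = 303L)
    run <- simulate_run(cfg, design = seeding_design(cfg))
    wt <- suppressWarnings(compute_wells(run_records(run)))
    list(cfg = cfg, run = run, wells = wt)
  })
}
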