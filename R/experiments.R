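#' Repeat-measurement agreement experiment
#'
#' Simulates the same set of sera measured on two occasions (a second run
#' some weeks later, with its own plates and a run-level efflux bias),
#' processes both days jointly — so the four-control plate correction
#' sees all plates of the study — and quantifies day-1 vs day-2 agreement
#' by Bland-Altman analysis before and after correction. Pairs in which
#' either day's result is rejected are excluded.
#'
#' @param config A [sim_config()]; `config$rng_seed` drives both days
#'   (day 2 uses `rng_seed + 1` for its measurement noise, with the same
#'   true per-sample efflux shifts).
#' @param n_plates_per_day Plates per measurement day.
#' @param samples_per_plate Study samples per plate.
#' @param day2_bias Run-level multiplicative efflux bias of day 2
#'   relative to day 1 (default 0.92, a typical batch drift).
#' @param method Referencing method(s) to evaluate.
#' @param qc A [qc_config()].
#' @return List per method: `uncorrected` and `corrected`
#'   [bland_altman()] objects plus `n_pairs`.
#' @export
repeat_experiment <- function(config, n_plates_per_day = 2,
                              samples_per_plate = 14, day2_bias = 0.92,
                              method = c("both", "per_well", "t0"),
                              qc = qc_config()) {
  method <- match.arg(method)
  n_samples <- n_plates_per_day * samples_per_plate
  shifts <- withr::with_seed(config$rng_seed + 1000L,
                             rlnorm_cv(n_samples, config$sample_cv))

  mk_cfg <- function(seed, bias) {
    cfg <- config
    cfg$rng_seed <- as.integer(seed)
    cfg$run_efflux_bias <- config$run_efflux_bias * bias
    cfg
  }
  day1 <- simulate_run(mk_cfg(config$rng_seed, 1),
                       design = NULL, n_plates = n_plates_per_day,
                       samples_per_plate = samples_per_plate,
                       emax_shifts = shifts, plate_prefix = "A")
  day2 <- simulate_run(mk_cfg(config$rng_seed + 1L, day2_bias),
                       design = NULL, n_plates = n_plates_per_day,
                       samples_per_plate = samples_per_plate,
                       emax_shifts = shifts, plate_prefix = "B")

  records <- rbind(run_records(day1), run_records(day2))
  wt <- compute_wells(records, method = method)
  methods <- if (method == "both") c("per_well", "t0") else method

  out <- lapply(methods, function(m) {
    agg <- aggregate_samples(wt, method = m, cfg = qc)
    pc <- plate_corrections(agg, cfg = qc)
    st <- pc$samples[pc$samples$role == "sample", , drop = FALSE]
    st$key <- substring(st$sample_id, 2)
    st$day <- substr(st$sample_id, 1, 1)
    d1 <- st[st$day == "A", ]; d2 <- st[st$day == "B", ]
    i <- match(d1$key, d2$key)
    keep <- !is.na(i) & !d1$rejected & !d2$rejected[i]
    d1 <- d1[keep, ]; d2 <- d2[i[keep], ]
    list(uncorrected = bland_altman(d2$mean_cec, d1$mean_cec),
         corrected = bland_altman(d2$corrected_cec, d1$corrected_cec),
         n_pairs = nrow(d1))
  })
  stats::setNames(out, methods)
}
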