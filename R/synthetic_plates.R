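#' Simulation configuration for synthetic CEC plates
#'
#' Defines the generative model of one assay run: cells are seeded with
#' lognormal well-to-well variation, stained with a fluorescent
#' cholesterol label proportionally to cell number, and release a
#' fraction of the label to the acceptor following a saturating
#' (Michaelis-Menten) dose-response in acceptor concentration. Reader
#' output is the labelled signal under a per-plate gain with
#' multiplicative measurement noise plus an additive background shared by
#' unstained wells. Lognormal (rather than normal) noise keeps counts and
#' signals positive even at high CV.
#'
#' Per-plate effects are of two kinds: a fluorescence *gain* (which both
#' referencing methods cancel exactly) and a multiplicative *efflux bias*
#' (plate-to-plate differences in efflux efficiency itself, the component
#' the four-control plate correction targets). Sporadic partial cell-loss
#' events (`detach_rate`) model wells that lose part of their monolayer
#' before efflux: supernatant and lysate shrink together, so per-well
#' referencing absorbs them while t0 referencing does not — the
#' heavy-tailed error that drives triplicate rejection in practice.
#'
#' @param n_plates Number of plates in the default run design.
#' @param wells_per_sample Replicates per sample (default 3).
#' @param seed_cells Intended cells per well (default 7e4).
#' @param seeding_cv Well-to-well CV of seeded cell number (default 0.03;
#'   set ~0.30 to emulate a gross deliberate seeding error).
#' @param stain_per_cell Fluorescence units of label per cell.
#' @param stain_cv CV of per-well staining efficiency.
#' @param efflux_emax Saturating active efflux, percent of total label,
#'   for the cAMP-treated condition.
#' @param efflux_km Acceptor concentration (% apoB-depleted serum) at
#'   half-maximal active efflux; `0` makes efflux acceptor-saturated at
#'   any dose.
#' @param no_camp_factor Multiplier on `efflux_emax` for untreated
#'   (`no_cAMP`) wells.
#' @param passive_frac Fraction of total label released without acceptor.
#' @param lysis_residual Fraction of cell label not recovered by lysis
#'   (cholic acid ~0.024, sodium hydroxide ~0.061).
#' @param plate_gain_sd CV of the per-plate multiplicative reader gain.
#' @param plate_efflux_sd CV of the per-plate multiplicative efflux bias.
#' @param t0_mismatch_sd CV of the per-plate factor by which the
#'   t0-control wells' recovered label deviates from the incubated
#'   wells' — t0 wells are lysed at time zero and skip the 4-h
#'   incubation and washes, so their surrogate total drifts from the
#'   plate's true per-well total. This error hits only t0 referencing;
#'   per-well referencing cancels it by construction.
#' @param run_efflux_bias Run-level multiplier on the efflux bias (a
#'   day/batch effect, e.g. for repeat-measurement experiments).
#' @param meas_cv Per-read multiplicative measurement CV.
#' @param background_level Additive background fluorescence (units).
#' @param detach_rate Probability a well loses part of its cell layer
#'   before efflux.
#' @param detach_mean,detach_sdlog Lognormal parameters of the retained
#'   cell fraction in a detachment event (capped at 1).
#' @param sample_cv Between-sample CV of true efflux (lognormal shift on
#'   the active component), used when designs draw sample effects.
#' @param resazurin_per_cell Net 570/600 absorbance ratio per cell.
#' @param blank_ratio 570/600 ratio of a cell-free well.
#' @param a600_base Baseline 600 nm absorbance.
#' @param rng_seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return A validated list of class `cec_sim_config`.
#' @export
sim_config <- function(n_plates = 1,
                       wells_per_sample = 3,
                       seed_cells = 7e4,
                       seeding_cv = 0.03,
                       stain_per_cell = 0.02,
                       stain_cv = 0.02,
                       efflux_emax = 18,
                       efflux_km = 1.5,
                       no_camp_factor = 0.35,
                       passive_frac = 0.04,
                       lysis_residual = 0.024,
                       plate_gain_sd = 0.10,
                       plate_efflux_sd = 0.06,
                       t0_mismatch_sd = 0.08,
                       run_efflux_bias = 1,
                       meas_cv = 0.03,
                       background_level = 20,
                       detach_rate = 0.03,
                       detach_mean = 0.7,
                       detach_sdlog = 0.3,
                       sample_cv = 0.12,
                       resazurin_per_cell = 2e-5,
                       blank_ratio = 0.75,
                       a600_base = 0.8,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  frac <- c("seeding_cv", "stain_cv", "passive_frac", "lysis_residual",
            "plate_gain_sd", "plate_efflux_sd", "t0_mismatch_sd", "meas_cv",
            "detach_rate", "sample_cv")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1)
      stopf("%s must be a fraction in [0, 1), got %s", f, format(v))
  }
  pos <- c("seed_cells", "stain_per_cell", "efflux_emax", "run_efflux_bias",
           "detach_mean", "resazurin_per_cell", "blank_ratio", "a600_base")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0)
      stopf("%s must be > 0, got %s", f, format(v))
  }
  if (efflux_km < 0) stopf("efflux_km must be >= 0")
  if (background_level < 0) stopf("background_level must be >= 0")
  if (n_plates < 1) stopf("n_plates must be >= 1")
  if (wells_per_sample < 2) stopf("wells_per_sample must be >= 2")
  if (efflux_emax + 100 * passive_frac > 100)
    stopf("efflux_emax + passive contribution exceed 100%% of total label")
  cfg$rng_seed <- as.integer(rng_seed)
  class(cfg) <- "cec_sim_config"
  cfg
}

CC_SHIFTS <- c(CC1 = 1.10, CC2 = 1.00, CC3 = 0.95, CC4 = 0.88)
PC_SHIFTS <- c(PC1 = 1.05, PC2 = 0.92)

# wells in column-major order A1, B1, ..., H12
all_wells <- function() paste0(rep(PLATE_ROWS, 12), rep(PLATE_COLS, each = 8))

design_row <- function(plate_id, well, role, sample_id = "", replicate = NA,
                       condition = "cAMP", acceptor_pct = 2,
                       emax_shift = 1, seed_multiplier = 1) {
  data.frame(plate_id = plate_id, well = well, role = role,
             sample_id = sample_id, replicate = replicate,
             condition = condition, acceptor_pct = acceptor_pct,
             emax_shift = emax_shift, seed_multiplier = seed_multiplier,
             stringsAsFactors = FALSE)
}

control_block <- function(plate_id, wells, include_correction,
                          acceptor_pct = 2) {
  out <- list()
  take <- function(n) { w <- wells[seq_len(n)]; wells <<- wells[-seq_len(n)]; w }
  if (include_correction) {
    for (cc in names(CC_SHIFTS))
      out[[length(out) + 1]] <- design_row(plate_id, take(3),
        "correction_control", cc, 1:3, "cAMP", acceptor_pct, CC_SHIFTS[[cc]])
    for (pc in names(PC_SHIFTS))
      out[[length(out) + 1]] <- design_row(plate_id, take(3),
        "monitoring_control", pc, 1:3, "cAMP", acceptor_pct, PC_SHIFTS[[pc]])
  }
  out[[length(out) + 1]] <- design_row(plate_id, take(3), "t0_control",
                                       acceptor_pct = 0)
  out[[length(out) + 1]] <- design_row(plate_id, take(3), "passive",
                                       acceptor_pct = 0)
  out[[length(out) + 1]] <- design_row(plate_id, take(3),
                                       "unstained_background",
                                       acceptor_pct = acceptor_pct)
  out[[length(out) + 1]] <- design_row(plate_id, take(2), "no_cell_blank",
                                       acceptor_pct = 0)
  do.call(rbind, out)
}

#' Default multi-plate run design
#'
#' One plate holds `samples_per_plate` study samples in triplicate plus
#' the full control complement: four correction controls and two
#' monitoring controls (the same six sera on every plate, with fixed true
#' efflux shifts), t0 controls, passive wells, unstained-background wells
#' and no-cell blanks. Study samples are distinct across plates; their
#' true efflux shifts are drawn lognormally with CV `config$sample_cv`
#' from the active RNG stream unless supplied.
#'
#' @param config A [sim_config()].
#' @param n_plates Plates in the run (default `config$n_plates`).
#' @param samples_per_plate Study samples per plate (max 20 with the full
#'   control complement).
#' @param condition Condition label(s) recycled over samples.
#' @param emax_shifts Optional vector of true per-sample efflux shifts
#'   (length `n_plates * samples_per_plate`).
#' @param include_correction Include correction/monitoring controls.
#' @param plate_prefix Prefix for plate ids.
#' @return Design data frame (layout columns plus `emax_shift`,
#'   `seed_multiplier`).
#' @export
run_design <- function(config, n_plates = config$n_plates,
                       samples_per_plate = 20, condition = "cAMP",
                       emax_shifts = NULL, include_correction = TRUE,
                       plate_prefix = "P") {
  wps <- config$wells_per_sample
  n_ctrl <- if (include_correction) 29 else 11
  if (samples_per_plate * wps + n_ctrl > 96)
    stopf("%d samples x %d wells + %d control wells exceed one plate",
          samples_per_plate, wps, n_ctrl)
  n_samples <- n_plates * samples_per_plate
  if (is.null(emax_shifts))
    emax_shifts <- rlnorm_cv(n_samples, config$sample_cv)
  if (length(emax_shifts) != n_samples)
    stopf("need %d emax_shifts, got %d", n_samples, length(emax_shifts))
  condition <- rep(condition, length.out = samples_per_plate)

  plates <- lapply(seq_len(n_plates), function(p) {
    pid <- sprintf("%s%02d", plate_prefix, p)
    wells <- all_wells()
    rows <- list()
    for (s in seq_len(samples_per_plate)) {
      sid <- sprintf("%s_S%02d", pid, s)
      w <- wells[seq_len(wps)]; wells <- wells[-seq_len(wps)]
      rows[[s]] <- design_row(pid, w, "sample", sid, seq_len(wps),
                              condition[s], 2,
                              emax_shifts[(p - 1) * samples_per_plate + s])
    }
    rbind(do.call(rbind, rows),
          control_block(pid, wells, include_correction))
  })
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  attr(out, "wells_per_sample") <- wps
  out
}

#' Deliberate seeding-error design
#'
#' One plate, `n_samples` sera, each seeded at every multiplier of the
#' standard cell number in triplicate (the classic 0.5/0.75/1/1.5 sweep),
#' plus t0, passive, unstained and blank wells. With `multipliers`
#' spanning 0.5-1.5 the realised cell-number CV is ~30-37%, the gross
#' seeding error used to expose referencing bias.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of sera (default 5).
#' @param multipliers Seeding multipliers (default `c(0.5, 0.75, 1, 1.5)`).
#' @param emax_shifts Per-serum efflux shifts; defaults to a fixed
#'   geometric spread around 1.
#' @return Design data frame; its `wells_per_sample` attribute is
#'   `3 * length(multipliers)` since each serum occupies one triplicate
#'   per seeding level.
#' @export
seeding_design <- function(config, n_samples = 5,
                           multipliers = c(0.5, 0.75, 1, 1.5),
                           emax_shifts = NULL) {
  if (is.null(emax_shifts))
    emax_shifts <- exp(seq(-0.12, 0.12, length.out = n_samples))
  stopifnot(length(emax_shifts) == n_samples)
  if (n_samples * 3 * length(multipliers) + 11 > 96)
    stopf("seeding design does not fit on one plate")
  pid <- "SEED01"
  wells <- all_wells()
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (m in multipliers) {
      w <- wells[1:3]; wells <- wells[-(1:3)]
      rows[[length(rows) + 1]] <-
        design_row(pid, w, "sample", sprintf("S%d", s), 1:3, "cAMP", 2,
                   emax_shifts[s], m)
    }
  }
  out <- rbind(do.call(rbind, rows),
               control_block(pid, wells, include_correction = FALSE))
  rownames(out) <- NULL
  attr(out, "wells_per_sample") <- 3 * length(multipliers)
  out
}

#' Acceptor saturation sweep design
#'
#' One serum (or several) measured in triplicate at each acceptor
#' concentration, for Michaelis-Menten saturation fitting. Each
#' (serum, concentration) pair is its own triplicate sample.
#'
#' @param config A [sim_config()].
#' @param acceptor_pcts Acceptor concentrations (% apoB-depleted serum).
#' @param n_samples Number of sera.
#' @param emax_shifts Per-serum efflux shifts (default all 1).
#' @return Design data frame.
#' @export
acceptor_sweep_design <- function(config,
                                  acceptor_pcts = c(0.25, 0.5, 1, 2, 4),
                                  n_samples = 1, emax_shifts = NULL) {
  if (is.null(emax_shifts)) emax_shifts <- rep(1, n_samples)
  if (n_samples * 3 * length(acceptor_pcts) + 11 > 96)
    stopf("acceptor sweep does not fit on one plate")
  pid <- "SAT01"
  wells <- all_wells()
  rows <- list()
  for (s in seq_len(n_samples)) {
    for (a in acceptor_pcts) {
      w <- wells[1:3]; wells <- wells[-(1:3)]
      rows[[length(rows) + 1]] <-
        design_row(pid, w, "sample", sprintf("S%d_A%g", s, a), 1:3, "cAMP",
                   a, emax_shifts[s])
    }
  }
  out <- rbind(do.call(rbind, rows),
               control_block(pid, wells, include_correction = FALSE))
  rownames(out) <- NULL
  attr(out, "wells_per_sample") <- config$wells_per_sample
  out
}

#' Simulate one assay run
#'
#' Generates plate-reader grids (supernatant and lysate fluorescence,
#' 570/600 nm absorbance), layouts, and a ground-truth table for every
#' plate of a design. All randomness comes from one RNG stream seeded
#' with `config$rng_seed`; the draw order is: design sample effects (when
#' the design is generated here), then per plate its gain, efflux bias
#' and t0-surrogate mismatch, then one vectorised block per quantity over wells in
#' design order (cell counts; detachment; staining; supernatant noise and
#' background; lysate noise and background; absorbance noise).
#'
#' The per-well generative model (active efflux saturating in acceptor
#' `A`, with half-saturation scaled by the relative cell number so the
#' acceptor:cell ratio drives seeding bias):
#' \deqn{f = passive + b_p \, s \, \frac{E_{max}}{100}
#'       \frac{A}{K_m (c/c_0) + A}}
#' supernatant reads \eqn{g_p f T \epsilon + bkg}, lysate reads
#' \eqn{g_p (1-f) T (1-\lambda) \epsilon + bkg}, and t0-control wells read
#' \eqn{g_p T (1-\lambda) \epsilon + bkg} (lysed at time zero), where `T`
#' is total label, \eqn{g_p} plate gain, \eqn{\lambda} the lysis
#' residual.
#'
#' @param config A [sim_config()].
#' @param design A design data frame from [run_design()],
#'   [seeding_design()] or [acceptor_sweep_design()]; built with
#'   `run_design(config, ...)` when `NULL`.
#' @param ... Passed to [run_design()] when `design` is `NULL`.
#' @return Object of class `cec_run`: `grids` (per plate, a list of
#'   [plate_grid()]s), `layouts` (per plate), `truth` (per-well ground
#'   truth: cell count, total label, efflux fraction), `design`,
#'   `config`.
#' @export
simulate_run <- function(config, design = NULL, ...) {
  stopifnot(inherits(config, "cec_sim_config"))
  withr::with_seed(config$rng_seed, {
    if (is.null(design)) design <- run_design(config, ...)
    simulate_run_impl(config, design)
  })
}

simulate_run_impl <- function(config, design) {
  wps <- attr(design, "wells_per_sample") %||% config$wells_per_sample
  plate_ids <- unique(design$plate_id)
  grids <- list(); layouts <- list(); truth <- list()
  layout_cols <- c("plate_id", "well", "role", "sample_id", "replicate",
                   "condition", "acceptor_pct")

  for (pid in plate_ids) {
    d <- design[design$plate_id == pid, , drop = FALSE]
    layout <- plate_layout(d[layout_cols], wells_per_sample = wps,
                           check_roles = TRUE,
                           require_correction =
                             any(d$role == "correction_control"))
    n <- nrow(d)
    gain <- rlnorm_cv(1, config$plate_gain_sd)
    bias <- config$run_efflux_bias * rlnorm_cv(1, config$plate_efflux_sd)
    t0_mis <- rlnorm_cv(1, config$t0_mismatch_sd)

    has_cells <- !d$role %in% c("no_cell_blank", "empty")
    stained <- d$role %in% c(CEC_ROLES, "t0_control", "passive")

    cells <- rlnorm_mean_cv(n, config$seed_cells, config$seeding_cv) *
      d$seed_multiplier
    cells[!has_cells] <- 0
    if (config$detach_rate > 0) {
      hit <- stats::runif(n) < config$detach_rate & has_cells
      if (any(hit)) {
        keep <- pmin(1, stats::rlnorm(sum(hit),
                                      meanlog = log(config$detach_mean),
                                      sdlog = config$detach_sdlog))
        cells[hit] <- cells[hit] * keep
      }
    }
    total <- config$stain_per_cell * cells * rlnorm_cv(n, config$stain_cv)
    total[!stained] <- 0

    rel <- ifelse(cells > 0, cells / config$seed_cells, 1)
    emax <- config$efflux_emax *
      ifelse(d$condition == "no_cAMP", config$no_camp_factor, 1)
    A <- d$acceptor_pct
    active <- ifelse(A > 0,
                     bias * d$emax_shift * (emax / 100) *
                       A / (config$efflux_km * rel + A),
                     0)
    f <- config$passive_frac + active
    f[d$role == "t0_control"] <- 0   # lysed before efflux
    if (any(f < 0 | f >= 1))
      stopf("plate '%s': efflux fraction outside [0, 1); check emax/shift/bias",
            pid)

    bgdraw <- function() config$background_level * rlnorm_cv(n, config$meas_cv)
    noise <- function() rlnorm_cv(n, config$meas_cv)

    sup_sig <- gain * f * total
    sup_sig[d$role == "t0_control"] <-
      (gain * t0_mis * total * (1 - config$lysis_residual))[d$role == "t0_control"]
    fi_sup <- sup_sig * noise() + bgdraw()

    lys_sig <- gain * (1 - f) * total * (1 - config$lysis_residual)
    lys_sig[d$role == "t0_control"] <- 0  # already read out at t0
    fi_lys <- lys_sig * noise() + bgdraw()

    alive <- has_cells & d$role != "t0_control"
    ratio_true <- config$blank_ratio +
      config$resazurin_per_cell * ifelse(alive, cells, 0)
    a600 <- config$a600_base * noise()
    a570 <- ratio_true * a600 * noise()

    to_grid <- function(vals, type) {
      m <- matrix(NA_real_, 8, 12)
      m[well_index(d$well)] <- vals
      plate_grid(pid, type, m, gain_tag = sprintf("G%.6f", gain))
    }
    grids[[pid]] <- list(sup = to_grid(fi_sup, "supernatant_fi"),
                         lys = to_grid(fi_lys, "lysate_fi"),
                         a570 = to_grid(a570, "absorbance_570"),
                         a600 = to_grid(a600, "absorbance_600"))
    layouts[[pid]] <- layout
    truth[[pid]] <- data.frame(plate_id = pid, well_id = d$well,
                               role = d$role, sample_id = d$sample_id,
                               cell_count = cells,
                               total_fluorescence = total,
                               efflux_fraction = f,
                               plate_gain = gain, plate_efflux_bias = bias)
  }
  out <- list(grids = grids, layouts = layouts,
              truth = do.call(rbind, c(truth, make.row.names = FALSE)),
              design = design, config = config)
  class(out) <- "cec_run"
  out
}

#' @export
print.cec_run <- function(x, ...) {
  cat(sprintf("<cec_run> %d plate(s), %d wells, seed %d\n",
              length(x$grids), nrow(x$truth), x$config$rng_seed))
  invisible(x)
}

#' Collect raw well records from a simulated run
#'
#' Joins every simulated plate's grids with its layout, exactly as
#' [read_manifest()] plus [join_layout()] would after a file round trip.
#'
#' @param run A [simulate_run()] result.
#' @return Row-bound raw well records for all plates.
#' @export
run_records <- function(run) {
  stopifnot(inherits(run, "cec_run"))
  wps <- attr(run$design, "wells_per_sample") %||% run$config$wells_per_sample
  recs <- lapply(names(run$grids), function(pid)
    join_layout(unname(run$grids[[pid]]), run$layouts[[pid]],
                wells_per_sample = wps))
  do.call(rbind, c(recs, make.row.names = FALSE))
}

#' Write a simulated run to disk
#'
#' One grid CSV per plate and read type, one layout CSV per plate, the
#' ground-truth table as tidy CSV, and a manifest YAML tying them
#' together, in the dialects [read_plate_grid()], [read_layout()] and
#' [read_manifest()] read back.
#'
#' @param run A [simulate_run()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "cec_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suffix <- c(sup = "sup", lys = "lys", a570 = "a570", a600 = "a600")
  plates <- lapply(names(run$grids), function(pid) {
    files <- vapply(names(run$grids[[pid]]), function(k) {
      f <- sprintf("%s_%s.csv", pid, suffix[[k]])
      write_plate_grid(run$grids[[pid]][[k]], file.path(dir, f))
      f
    }, character(1))
    lf <- sprintf("%s_layout.csv", pid)
    write_layout(run$layouts[[pid]], file.path(dir, lf))
    list(plate_id = pid, grids = as.list(unname(files)), layout = lf)
  })
  utils::write.csv(run$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(plates = plates), manifest)
  invisible(manifest)
}
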