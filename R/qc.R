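#' Quality-control configuration
#'
#' @param replicate_cv_max Replicate CV (percent) above which a sample is
#'   rejected; the rule is strictly greater-than, so a CV of exactly the
#'   threshold passes (default 15).
#' @param min_replicates Minimum valid wells a sample needs; with fewer it
#'   counts as rejected with reason `"insufficient wells"` (default 3).
#' @param correction_enabled Apply the four-control plate correction.
#' @param cv_on_raw Compute the rejection CV on raw (pre-passive-
#'   subtraction) replicate CEC (default `TRUE`). Passive subtraction
#'   shifts the mean toward zero and would inflate the CV of low-efflux
#'   samples for unchanged absolute scatter.
#' @return List of class `cec_qc_config`.
#' @export
qc_config <- function(replicate_cv_max = 15, min_replicates = 3,
                      correction_enabled = TRUE, cv_on_raw = TRUE) {
  if (replicate_cv_max <= 0) stopf("replicate_cv_max must be > 0")
  if (min_replicates < 2) stopf("min_replicates must be >= 2")
  structure(list(replicate_cv_max = replicate_cv_max,
                 min_replicates = min_replicates,
                 correction_enabled = correction_enabled,
                 cv_on_raw = cv_on_raw),
            class = "cec_qc_config")
}

#' Aggregate replicate wells into sample results
#'
#' Per sample and plate: the mean, SD and CV of its replicate CEC values
#' under one referencing method, and the rejection flag. The CV is
#' computed on raw (pre-passive) CEC by default (see [qc_config()]); the
#' reported `mean_cec` is post-passive. A sample is rejected when its
#' replicate CV strictly exceeds `replicate_cv_max`, or when fewer than
#' `min_replicates` wells are valid.
#'
#' @param wells A `cec_well_table` from [compute_wells()], or its `wells`
#'   data frame.
#' @param method `"per_well"` or `"t0"`.
#' @param cfg A [qc_config()].
#' @return Data frame, one row per (plate, sample): `plate_id`,
#'   `sample_id`, `role`, `method`, `n_wells`, `n_valid`, `mean_cec`,
#'   `sd_cec`, `cv`, `rejected`, `reject_reason`.
#' @export
aggregate_samples <- function(wells, method = c("per_well", "t0"),
                              cfg = qc_config()) {
  method <- match.arg(method)
  if (inherits(wells, "cec_well_table")) wells <- wells$wells
  raw_col <- paste0("cec_", method, "_raw")
  fin_col <- paste0("cec_", method)
  ok_col <- paste0("valid_", method)

  w <- wells[wells$role %in% CEC_ROLES, , drop = FALSE]
  key <- interaction(w$plate_id, w$sample_id, drop = TRUE)
  rows <- lapply(split(w, key), function(g) {
    v <- g[[ok_col]]
    raw <- g[[raw_col]][v]
    fin <- g[[fin_col]][v]
    n_valid <- sum(v)
    cvv <- if (cfg$cv_on_raw) cv_pct(raw) else cv_pct(fin)
    insufficient <- n_valid < cfg$min_replicates
    high_cv <- !insufficient && is.finite(cvv) && cvv > cfg$replicate_cv_max
    data.frame(plate_id = g$plate_id[1], sample_id = g$sample_id[1],
               role = g$role[1], method = method,
               n_wells = nrow(g), n_valid = n_valid,
               mean_cec = if (n_valid) mean(fin) else NA_real_,
               sd_cec = if (n_valid >= 2) stats::sd(fin) else NA_real_,
               cv = cvv,
               rejected = insufficient || high_cv,
               reject_reason = if (insufficient) "insufficient wells"
                 else if (high_cv) "replicate CV above threshold"
                 else NA_character_)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$plate_id, out$role, out$sample_id), , drop = FALSE]
}

#' Sample rejection rate
#'
#' Rejected samples divided by total samples, as a percent reported to
#' two decimals.
#'
#' @param n_rejected,n_total Counts.
#' @return Percent, rounded half-up to 2 decimals.
#' @export
#' @examples
#' rejection_rate(68, 506) # 13.44
rejection_rate <- function(n_rejected, n_total) {
  if (n_total <= 0) stopf("n_total must be > 0")
  round_half_up(100 * n_rejected / n_total, 2)
}

#' Four-control plate-to-plate correction
#'
#' For each plate, the relative difference between the expected and the
#' observed CEC of each of the four correction-control samples is
#' averaged into a correction factor
#' `factor = 1 + mean((observed - expected) / expected)`, and every CEC
#' on the plate is divided by it. Expected values default to each
#' control's mean observed CEC across all plates of the run (two-pass),
#' so the factors average ~1; externally calibrated reference values can
#' be supplied instead. The correction is multiplicative: it preserves
#' positivity, the percent-of-total scale, and all within-plate ratios.
#'
#' A rejected control drops out; with three valid controls the factor is
#' still computed (with a warning), with fewer the plate stays
#' uncorrected and is flagged.
#'
#' @param samples Output of [aggregate_samples()] (one method) containing
#'   the `correction_control` rows.
#' @param expected Optional named vector of reference CEC per control
#'   sample id.
#' @param cfg A [qc_config()].
#' @return List: `samples` (input with `corrected_cec` and
#'   `correction_factor` columns) and `plates` (per plate: factor,
#'   number of controls used, `uncorrected` flag, per-control relative
#'   differences as a nested data frame `detail`).
#' @export
plate_corrections <- function(samples, expected = NULL, cfg = qc_config()) {
  cc <- samples[samples$role == "correction_control" & !samples$rejected &
                  is.finite(samples$mean_cec), , drop = FALSE]
  if (!nrow(cc)) stopf("no valid correction-control results; cannot correct")
  if (is.null(expected)) {
    expected <- tapply(cc$mean_cec, cc$sample_id, mean)
    expected <- stats::setNames(as.numeric(expected), names(expected))
  }
  if (any(expected <= 0)) stopf("expected control CEC values must be > 0")

  plates <- unique(samples$plate_id)
  detail <- list()
  fac <- vapply(plates, function(pid) {
    p <- cc[cc$plate_id == pid & cc$sample_id %in% names(expected), ,
            drop = FALSE]
    exp_v <- expected[p$sample_id]
    rel_diff <- (exp_v - p$mean_cec) / exp_v
    detail[[pid]] <<- data.frame(plate_id = pid, control_id = p$sample_id,
                                 expected = as.numeric(exp_v),
                                 observed = p$mean_cec,
                                 rel_diff = as.numeric(rel_diff))
    n <- nrow(p)
    if (n < 3) return(NA_real_)
    if (n < 4)
      warnf("plate '%s': correction from %d controls (one rejected)", pid, n)
    1 + mean(-rel_diff)
  }, numeric(1))

  uncorrected <- !is.finite(fac) | fac <= 0
  if (any(uncorrected))
    warnf("plate(s) left uncorrected (fewer than 3 valid controls or non-positive factor): %s",
          paste(plates[uncorrected], collapse = ", "))

  out <- samples
  out$correction_factor <- fac[match(out$plate_id, plates)]
  out$corrected_cec <- ifelse(is.finite(out$correction_factor) &
                                out$correction_factor > 0,
                              out$mean_cec / out$correction_factor,
                              out$mean_cec)
  list(samples = out,
       plates = data.frame(plate_id = plates, factor = fac,
                           n_controls = vapply(detail[plates], function(d)
                             if (is.null(d)) 0L else nrow(d), integer(1)),
                           uncorrected = uncorrected, row.names = NULL),
       detail = do.call(rbind, c(detail, make.row.names = FALSE)),
       expected = expected)
}

#' Interassay coefficient of variation
#'
#' CV (percent, n-1 SD) of a monitoring control's per-plate CEC across
#' plates. Monitoring controls are disjoint from the correction controls,
#' so corrected and uncorrected interassay CVs are comparable without
#' circularity.
#'
#' @param x Vector of one control's mean CEC, one value per plate.
#' @return CV in percent.
#' @export
interassay_cv <- function(x) cv_pct(x)

#' Relative reduction between two performance values
#'
#' `100 * (a - b) / a`, rounded half-up to a whole percent — the
#' convention used for method- and correction-comparison tables.
#'
#' @param a Reference value (e.g. t0 method, or uncorrected).
#' @param b Comparison value (e.g. per-well method, or corrected).
#' @return Whole-percent reduction (negative if `b > a`).
#' @export
#' @examples
#' relative_reduction(rejection_rate(68, 506), rejection_rate(24, 506)) # 65
relative_reduction <- function(a, b) {
  if (!is.finite(a) || a == 0) return(NA_real_)
  round_half_up(100 * (a - b) / a, 0)
}

method_performance <- function(samples, cfg) {
  st <- samples[samples$role == "sample", , drop = FALSE]
  n_total <- nrow(st); n_rejected <- sum(st$rejected)
  retained <- st[!st$rejected, , drop = FALSE]
  mon <- samples[samples$role == "monitoring_control" & !samples$rejected, ,
                 drop = FALSE]
  inter <- lapply(split(mon, mon$sample_id), function(g) {
    un <- interassay_cv(g$mean_cec)
    co <- if ("corrected_cec" %in% names(g)) interassay_cv(g$corrected_cec)
          else NA_real_
    data.frame(control_id = g$sample_id[1], n_plates = nrow(g),
               cv_uncorrected = un, cv_corrected = co,
               reduction_by_correction = relative_reduction(un, co))
  })
  list(n_rejected = n_rejected, n_total = n_total,
       rejection_rate = rejection_rate(n_rejected, n_total),
       intra_assay_cv = mean(retained$cv[is.finite(retained$cv)]),
       interassay = do.call(rbind, c(inter, make.row.names = FALSE)))
}

#' Assay performance report
#'
#' Summarises one or both referencing methods: sample rejection rate
#' (with counts), intra-assay CV (mean replicate CV of retained samples),
#' and per-monitoring-control interassay CV before and after plate
#' correction, together with the relative-reduction comparisons (per-well
#' vs t0, corrected vs uncorrected) as whole percents.
#'
#' @param per_well,t0 Sample tables for the respective method —
#'   [aggregate_samples()] output, or the `samples` element of
#'   [plate_corrections()] when corrected CVs are wanted. Either may be
#'   `NULL`.
#' @param cfg A [qc_config()].
#' @return List of class `cec_performance_report`: `methods` (per-method
#'   summaries) and `comparison` (relative reductions by the per-well
#'   method, when both methods are present).
#' @export
performance_report <- function(per_well = NULL, t0 = NULL,
                               cfg = qc_config()) {
  if (is.null(per_well) && is.null(t0))
    stopf("at least one method's sample table is required")
  unwrap <- function(x) if (is.list(x) && !is.data.frame(x)) x$samples else x
  methods <- list()
  if (!is.null(per_well))
    methods$per_well <- method_performance(unwrap(per_well), cfg)
  if (!is.null(t0))
    methods$t0 <- method_performance(unwrap(t0), cfg)

  comparison <- NULL
  if (!is.null(methods$per_well) && !is.null(methods$t0)) {
    a <- methods$t0; b <- methods$per_well
    inter <- merge(a$interassay, b$interassay, by = "control_id",
                   suffixes = c("_t0", "_per_well"))
    comparison <- list(
      rejection_rate = relative_reduction(a$rejection_rate, b$rejection_rate),
      intra_assay_cv = relative_reduction(a$intra_assay_cv, b$intra_assay_cv),
      interassay = data.frame(
        control_id = inter$control_id,
        uncorrected = mapply(relative_reduction, inter$cv_uncorrected_t0,
                             inter$cv_uncorrected_per_well),
        corrected = mapply(relative_reduction, inter$cv_corrected_t0,
                           inter$cv_corrected_per_well)))
  }
  structure(list(methods = methods, comparison = comparison, cfg = cfg),
            class = "cec_performance_report")
}

#' @export
print.cec_performance_report <- function(x, ...) {
  for (m in names(x$methods)) {
    p <- x$methods[[m]]
    cat(sprintf("%s method: rejection %.2f%% (%d/%d), intra-assay CV %.2f%%\n",
                m, p$rejection_rate, p$n_rejected, p$n_total, p$intra_assay_cv))
    if (!is.null(p$interassay) && nrow(p$interassay))
      for (i in seq_len(nrow(p$interassay)))
        cat(sprintf("  interassay CV %s: %.2f%% uncorrected, %.2f%% corrected (-%s%%)\n",
                    p$interassay$control_id[i], p$interassay$cv_uncorrected[i],
                    p$interassay$cv_corrected[i],
                    format(p$interassay$reduction_by_correction[i])))
  }
  if (!is.null(x$comparison))
    cat(sprintf("per-well vs t0: rejection -%s%%, intra-assay CV -%s%%\n",
                format(x$comparison$rejection_rate),
                format(x$comparison$intra_assay_cv)))
  invisible(x)
}
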