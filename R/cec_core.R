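#' Per-plate background fluorescence from unstained wells
#'
#' The background of each read type is the mean reading of that plate's
#' unstained-cell wells; it is estimated per plate because reader gain is
#' set per plate. Requires at least 3 unstained wells.
#'
#' @param records Raw well records of one plate (from [join_layout()]).
#' @return List with `bg_sup`, `bg_lys` and the well count `n_unstained`.
#' @export
background_set <- function(records) {
  un <- records[records$role == "unstained_background", , drop = FALSE]
  if (nrow(un) < 3)
    stopf("plate '%s' has %d unstained-background well(s), needs >= 3",
          records$plate_id[1], nrow(un))
  bg_sup <- mean(un$fi_sup_raw, na.rm = TRUE)
  bg_lys <- mean(un$fi_lys_raw, na.rm = TRUE)
  if (!is.finite(bg_sup)) stopf("no supernatant readings in unstained wells")
  list(bg_sup = bg_sup, bg_lys = bg_lys, n_unstained = nrow(un))
}

#' Background subtraction with validity flagging
#'
#' Net fluorescence is raw minus the matching background. A negative net
#' value invalidates the well rather than being clamped to zero: clamping
#' would bias CEC upward, and a reading below background indicates a
#' failed well, not zero efflux.
#'
#' @param raw_sup,raw_lys Raw supernatant / lysate readings (vectors).
#' @param bg A [background_set()] list.
#' @param need_lys If `FALSE`, a missing lysate read does not invalidate
#'   the well (t0-only processing).
#' @return Data frame with `fi_sup_net`, `fi_lys_net`, `valid`,
#'   `invalid_reason`.
#' @export
subtract_background <- function(raw_sup, raw_lys, bg, need_lys = TRUE) {
  n <- length(raw_sup)
  out <- data.frame(fi_sup_net = raw_sup - bg$bg_sup,
                    fi_lys_net = raw_lys - bg$bg_lys,
                    valid = rep(TRUE, n),
                    invalid_reason = rep(NA_character_, n))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    out$valid[cond] <<- FALSE
    set <- cond & is.na(out$invalid_reason)
    out$invalid_reason[set] <<- why
  }
  flag(is.na(raw_sup), "missing supernatant read")
  if (need_lys) flag(is.na(raw_lys), "missing lysate read")
  flag(out$fi_sup_net < 0, "negative net supernatant")
  if (need_lys) flag(out$fi_lys_net < 0, "negative net lysate")
  out
}

#' CEC, per-well referencing
#'
#' Percent of the well's own total recovered fluorescence found in the
#' supernatant: `100 * FI_sup / (FI_sup + FI_lys)`, before passive-efflux
#' subtraction. Exactly invariant to any common gain on the two reads.
#'
#' @param fi_sup_net,fi_lys_net Background-corrected readings (vectors).
#' @return Raw per-well CEC in percent; `NA` where either net is missing,
#'   negative, or the total is zero.
#' @export
#' @examples
#' cec_per_well(30, 70) # 30
cec_per_well <- function(fi_sup_net, fi_lys_net) {
  tot <- fi_sup_net + fi_lys_net
  out <- ifelse(is.na(tot) | tot <= 0 | fi_sup_net < 0 | fi_lys_net < 0,
                NA_real_, 100 * fi_sup_net / tot)
  # 0/positive total is a legitimate 0% CEC; only total == 0 is undefined
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' CEC, time-zero referencing
#'
#' Supernatant fluorescence as a percent of the plate's t0 reference (the
#' mean of control wells lysed at time zero, a surrogate for the total
#' label loaded per well): `100 * FI_sup / FI_t0_control`, before
#' passive-efflux subtraction. Values above 100 are arithmetically legal
#' (a well holding more label than the t0 controls) and are returned
#' as-is; callers flag them via the `over_range` attribute.
#'
#' @param fi_sup_net Background-corrected supernatant readings.
#' @param t0_reference Positive plate-level t0 reference.
#' @return Raw t0 CEC in percent with attribute `over_range` (logical
#'   vector, `TRUE` where CEC > 100).
#' @export
cec_t0 <- function(fi_sup_net, t0_reference) {
  if (!is.finite(t0_reference) || t0_reference <= 0)
    stopf("t0 reference must be positive, got %s; plate unusable for the t0 method",
          format(t0_reference))
  out <- ifelse(is.na(fi_sup_net) | fi_sup_net < 0, NA_real_,
                100 * fi_sup_net / t0_reference)
  attr(out, "over_range") <- !is.na(out) & out > 100
  out
}

#' Plate context: t0 reference and passive efflux
#'
#' From one plate's records and background, computes the t0 reference
#' (mean background-corrected reading of the t0-control wells, with its
#' CV), and the passive efflux under each method (mean raw CEC of the
#' acceptor-free passive wells). Passive efflux is label released to
#' medium without acceptor; it is subtracted from every sample CEC.
#'
#' @param records One plate's raw well records.
#' @param bg A [background_set()] for that plate.
#' @param need_t0 If `FALSE` (per-well-only processing), missing t0 wells
#'   are tolerated and `t0_reference` is `NA`.
#' @param t0_cv_max Warn when the t0 triplicate CV exceeds this (percent).
#' @return List: `t0_reference`, `t0_cv`, `t0_failed`,
#'   `passive_cec_perwell`, `passive_cec_t0`, `n_t0`, `n_passive`.
#' @export
plate_context <- function(records, bg, need_t0 = TRUE, t0_cv_max = 15) {
  t0w <- records[records$role == "t0_control", , drop = FALSE]
  pw  <- records[records$role == "passive", , drop = FALSE]
  if (nrow(pw) < 3)
    stopf("plate '%s' has %d passive well(s), needs >= 3",
          records$plate_id[1], nrow(pw))
  if (need_t0 && nrow(t0w) < 3)
    stopf("plate '%s' has %d t0-control well(s), needs >= 3 for the t0 method",
          records$plate_id[1], nrow(t0w))

  t0_reference <- NA_real_; t0_cv <- NA_real_; t0_failed <- FALSE
  if (nrow(t0w) >= 3) {
    t0_net <- t0w$fi_sup_raw - bg$bg_sup
    t0_reference <- mean(t0_net, na.rm = TRUE)
    t0_cv <- cv_pct(t0_net)
    if (!is.finite(t0_reference) || t0_reference <= 0) {
      t0_failed <- TRUE
      if (need_t0)
        warnf("plate '%s': non-positive t0 reference; plate unusable for the t0 method",
              records$plate_id[1])
    } else if (is.finite(t0_cv) && t0_cv > t0_cv_max) {
      warnf("plate '%s': t0-control CV %.2f%% exceeds %.1f%%",
            records$plate_id[1], t0_cv, t0_cv_max)
    }
  } else t0_failed <- TRUE

  psub <- subtract_background(pw$fi_sup_raw, pw$fi_lys_raw, bg,
                              need_lys = FALSE)
  passive_cec_perwell <-
    mean(cec_per_well(psub$fi_sup_net, psub$fi_lys_net), na.rm = TRUE)
  passive_cec_t0 <- if (!t0_failed)
    mean(as.numeric(cec_t0(psub$fi_sup_net, t0_reference)), na.rm = TRUE)
  else NA_real_

  list(t0_reference = t0_reference, t0_cv = t0_cv, t0_failed = t0_failed,
       passive_cec_perwell = passive_cec_perwell,
       passive_cec_t0 = passive_cec_t0,
       n_t0 = nrow(t0w), n_passive = nrow(pw))
}

#' Passive-efflux subtraction
#'
#' Final CEC is the raw CEC minus the plate's passive efflux under the
#' same method. Negative results are retained (a sample can sit below the
#' acceptor-free baseline), not clamped.
#'
#' @param raw_cec Raw CEC values (percent).
#' @param passive_cec Plate passive CEC for the matching method (percent).
#' @return Final CEC values (percent).
#' @export
finalize_well_cec <- function(raw_cec, passive_cec) raw_cec - passive_cec

#' Resazurin net absorbance ratio
#'
#' The 570/600 nm absorbance ratio of a well minus the blank ratio of a
#' cell-free well. The net ratio is proportional to the number of
#' metabolically active cells and serves as the cell-seeding proxy.
#'
#' @param a570,a600 Absorbance readings.
#' @param blank_ratio Ratio of the no-cell blank (mean over blank wells).
#' @return Net ratio; `NA` where `a600` is missing or non-positive.
#' @export
#' @examples
#' resazurin_ratio(1.2, 0.8, 0.1) # 1.4
resazurin_ratio <- function(a570, a600, blank_ratio) {
  ifelse(is.na(a600) | a600 <= 0 | is.na(a570), NA_real_,
         a570 / a600 - blank_ratio)
}

#' Normalize CEC to the plate-relative resazurin signal
#'
#' Divides CEC by the well's resazurin net ratio relative to the plate
#' mean, i.e. rescales each well to the plate's average cell number. The
#' identity when the well sits at the plate mean.
#'
#' @param cec CEC values (percent).
#' @param r_well Well resazurin net ratio.
#' @param r_plate_mean Plate mean net ratio over analyzed wells.
#' @return Normalized CEC (percent).
#' @export
normalize_to_resazurin <- function(cec, r_well, r_plate_mean) {
  ifelse(is.na(r_well) | r_well <= 0, NA_real_, cec / (r_well / r_plate_mean))
}

CEC_ROLES <- c("sample", "correction_control", "monitoring_control")

#' Compute well-level CEC for one or more plates
#'
#' The plate-level driver: per plate, estimates background from unstained
#' wells, forms the t0 reference and passive efflux, computes raw CEC under
#' the requested referencing method(s), subtracts passive efflux, and
#' attaches resazurin net ratios where absorbance reads exist.
#'
#' @param records Raw well records (one or several plates row-bound).
#' @param method `"both"` (default), `"per_well"` or `"t0"`.
#' @param t0_cv_max Warning threshold for the t0 triplicate CV (percent).
#' @return List of class `cec_well_table`: `wells` (one row per
#'   CEC-bearing well with net fluorescences, raw and final CEC under both
#'   methods, validity flags and resazurin net ratio) and `plates` (one
#'   row per plate: background, t0 reference and CV, passive CEC values,
#'   resazurin blank and plate mean).
#' @export
compute_wells <- function(records, method = c("both", "per_well", "t0"),
                          t0_cv_max = 15) {
  method <- match.arg(method)
  need_t0 <- method %in% c("both", "t0")
  need_lys <- method %in% c("both", "per_well")
  if (need_lys && all(is.na(records$fi_lys_raw)))
    stopf("per-well method requested but no lysate readings present")
  if (need_t0 && !any(records$role == "t0_control"))
    stopf("t0 method requested but layout has no t0_control wells")

  wells_out <- list(); plates_out <- list()
  for (pid in unique(records$plate_id)) {
    rec <- records[records$plate_id == pid, , drop = FALSE]
    bg <- background_set(rec)
    ctx <- plate_context(rec, bg, need_t0 = need_t0, t0_cv_max = t0_cv_max)

    w <- rec[rec$role %in% CEC_ROLES, , drop = FALSE]
    sb <- subtract_background(w$fi_sup_raw, w$fi_lys_raw, bg,
                              need_lys = need_lys)
    w$fi_sup_net <- sb$fi_sup_net
    w$fi_lys_net <- sb$fi_lys_net
    w$invalid_reason <- sb$invalid_reason

    w$cec_per_well_raw <- cec_per_well(sb$fi_sup_net, sb$fi_lys_net)
    w$valid_per_well <- need_lys & sb$valid & !is.na(w$cec_per_well_raw)
    w$cec_per_well <- ifelse(w$valid_per_well,
                             finalize_well_cec(w$cec_per_well_raw,
                                               ctx$passive_cec_perwell),
                             NA_real_)

    sup_ok <- !is.na(sb$fi_sup_net) & sb$fi_sup_net >= 0
    if (need_t0 && !ctx$t0_failed) {
      t0raw <- cec_t0(sb$fi_sup_net, ctx$t0_reference)
      w$cec_t0_raw <- as.numeric(t0raw)
      w$over_range_t0 <- attr(t0raw, "over_range")
      w$valid_t0 <- sup_ok & !is.na(w$cec_t0_raw)
      w$cec_t0 <- ifelse(w$valid_t0,
                         finalize_well_cec(w$cec_t0_raw, ctx$passive_cec_t0),
                         NA_real_)
    } else {
      w$cec_t0_raw <- NA_real_; w$cec_t0 <- NA_real_
      w$valid_t0 <- FALSE; w$over_range_t0 <- FALSE
    }

    # resazurin: blank from no-cell wells, net ratio for cell-bearing wells
    blanks <- rec[rec$role == "no_cell_blank", , drop = FALSE]
    blank_ratio <- NA_real_; r_plate_mean <- NA_real_
    if (nrow(blanks) >= 1 && any(!is.na(blanks$a600_raw))) {
      blank_ratio <- mean(blanks$a570_raw / blanks$a600_raw, na.rm = TRUE)
      w$resazurin_net_ratio <- resazurin_ratio(w$a570_raw, w$a600_raw,
                                               blank_ratio)
      r_plate_mean <- mean(w$resazurin_net_ratio, na.rm = TRUE)
    } else {
      w$resazurin_net_ratio <- NA_real_
    }

    wells_out[[pid]] <- w
    plates_out[[pid]] <- data.frame(
      plate_id = pid, bg_sup = bg$bg_sup, bg_lys = bg$bg_lys,
      t0_reference = ctx$t0_reference, t0_cv = ctx$t0_cv,
      t0_failed = ctx$t0_failed,
      passive_cec_perwell = ctx$passive_cec_perwell,
      passive_cec_t0 = ctx$passive_cec_t0,
      resazurin_blank_ratio = blank_ratio,
      resazurin_plate_mean = r_plate_mean)
  }
  out <- list(wells = do.call(rbind, c(wells_out, make.row.names = FALSE)),
              plates = do.call(rbind, c(plates_out, make.row.names = FALSE)),
              method = method)
  class(out) <- "cec_well_table"
  out
}

#' @export
print.cec_well_table <- function(x, ...) {
  cat(sprintf("<cec_well_table> %d wells on %d plate(s), method '%s'\n",
              nrow(x$wells), nrow(x$plates), x$method))
  invisible(x)
}
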