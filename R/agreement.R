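#' Bland-Altman agreement between paired measurements
#'
#' Differences are `m1 - m2`; the bias is their mean and the 95% limits
#' of agreement are the bias plus/minus exactly 2 sample SDs of the
#' differences. Pairs with a missing value on either side are dropped.
#'
#' @param m1,m2 Paired measurement vectors of equal length.
#' @return List of class `cec_bland_altman`: `n_pairs`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, and the per-pair `means` and
#'   `diffs` for plotting.
#' @export
#' @examples
#' bland_altman(c(10, 12, 14), c(10, 12, 14))$mean_diff # 0
bland_altman <- function(m1, m2) {
  if (length(m1) != length(m2)) stopf("m1 and m2 must have equal length")
  ok <- is.finite(m1) & is.finite(m2)
  m1 <- m1[ok]; m2 <- m2[ok]
  if (length(m1) < 2) stopf("Bland-Altman needs >= 2 complete pairs, got %d",
                            length(m1))
  diffs <- m1 - m2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(n_pairs = length(m1), mean_diff = bias, sd_diff = s,
                 loa_low = bias - 2 * s, loa_high = bias + 2 * s,
                 means = (m1 + m2) / 2, diffs = diffs),
            class = "cec_bland_altman")
}

#' @export
print.cec_bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d, bias %.3f, LoA [%.3f, %.3f]\n",
              x$n_pairs, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Michaelis-Menten saturation fit of CEC versus acceptor concentration
#'
#' Least-squares fit of `cec = vmax * A / (km + A)` with deterministic
#' initialisation: `vmax0` is the largest observed CEC and `km0` the
#' acceptor concentration at half-maximum by linear interpolation of the
#' observed curve. Optimisation uses Levenberg-Marquardt
#' (\pkg{minpack.lm}) with non-negativity bounds, a relative tolerance of
#' 1e-8 on the residual sum of squares and at most 500 iterations.
#'
#' @param acceptor_pct Acceptor concentrations (% apoB-depleted serum),
#'   at least 3 distinct positive levels.
#' @param cec Mean CEC at each concentration (percent).
#' @return List of class `cec_saturation_fit`: `vmax`, `km`, `rss`,
#'   `converged`, `km_boundary` (`TRUE` when the fit collapsed to the
#'   saturated limit km ~ 0), `fitted`.
#' @export
fit_saturation <- function(acceptor_pct, cec) {
  ok <- is.finite(acceptor_pct) & is.finite(cec)
  A <- acceptor_pct[ok]; y <- cec[ok]
  if (length(unique(A)) < 3)
    stopf("saturation fit needs >= 3 distinct acceptor concentrations")
  if (any(A <= 0)) stopf("acceptor concentrations must be > 0")

  vmax0 <- max(y)
  s <- order(A)
  km0 <- suppressWarnings(
    stats::approx(y[s], A[s], xout = vmax0 / 2, ties = "ordered",
                  rule = 2)$y)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(A)

  fit <- minpack.lm::nls.lm(
    par = c(vmax = vmax0, km = km0), lower = c(0, 0),
    fn = function(p) y - p[["vmax"]] * A / (p[["km"]] + A),
    control = minpack.lm::nls.lm.control(ftol = 1e-8, maxiter = 500))
  cf <- fit$par
  pred <- cf[["vmax"]] * A / (cf[["km"]] + A)
  out <- list(vmax = cf[["vmax"]], km = cf[["km"]],
              rss = sum((y - pred)^2),
              converged = fit$info %in% 1:4,
              km_boundary = cf[["km"]] < 1e-4 * max(A),
              fitted = pred)
  class(out) <- "cec_saturation_fit"
  out
}

#' @export
print.cec_saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> vmax %.4f, km %.4f, rss %.3g%s%s\n",
              x$vmax, x$km, x$rss,
              if (x$converged) "" else " (not converged)",
              if (x$km_boundary) " (km at boundary)" else ""))
  invisible(x)
}

#' Cell-seeding bias of CEC on the resazurin signal
#'
#' Fixed-effects regression of well-level CEC on the z-scored resazurin
#' net ratio with one intercept per sample and a common slope: the change
#' in CEC per 1 SD increase of the cell-number proxy. The z-score is
#' taken over all analyzed wells, so the slope is invariant to adding a
#' constant to every ratio. The 95% CI uses the t distribution on the
#' residual degrees of freedom. (With a handful of samples in triplicate
#' a random-effects variance is weakly identified, so the per-sample
#' intercepts are fixed effects; the estimand — the common slope — is
#' unchanged.)
#'
#' @param cec Well-level CEC (percent).
#' @param resazurin Well-level resazurin net ratio.
#' @param sample_id Sample identifier per well.
#' @return List of class `cec_seeding_bias`: `slope_per_sd`, `ci95_low`,
#'   `ci95_high`, `p_value`, `intercepts`, `n_wells`, `df_residual`.
#' @export
seeding_bias <- function(cec, resazurin, sample_id) {
  ok <- is.finite(cec) & is.finite(resazurin) & !is.na(sample_id)
  cec <- cec[ok]; resazurin <- resazurin[ok]
  sample_id <- factor(sample_id[ok])
  if (nlevels(sample_id) < 2) stopf("seeding_bias needs >= 2 samples")
  if (min(table(sample_id)) < 3) stopf("each sample needs >= 3 wells")
  sdr <- stats::sd(resazurin)
  if (!is.finite(sdr) || sdr == 0)
    stopf("resazurin ratios have zero variance; slope not identifiable")
  z <- (resazurin - mean(resazurin)) / sdr
  fit <- stats::lm(cec ~ 0 + sample_id + z)
  cf <- stats::coef(fit)
  if (is.na(cf["z"])) stopf("slope not identifiable (collinear design)")
  dfres <- fit$df.residual
  # slope SE from the QR factorisation directly (summary.lm warns on an
  # exact fit, which is a legitimate input here)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  sigma2 <- sum(stats::resid(fit)^2) / dfres
  se <- sqrt(diag(xtx_inv) * sigma2)[length(cf)]
  tcrit <- stats::qt(0.975, dfres)
  tval <- if (se > 0) cf[["z"]] / se else Inf
  structure(list(slope_per_sd = cf[["z"]],
                 ci95_low = cf[["z"]] - tcrit * se,
                 ci95_high = cf[["z"]] + tcrit * se,
                 p_value = if (se > 0) 2 * stats::pt(-abs(tval), dfres)
                           else 0,
                 intercepts = cf[names(cf) != "z"],
                 n_wells = length(cec), df_residual = dfres),
            class = "cec_seeding_bias")
}

#' @export
print.cec_seeding_bias <- function(x, ...) {
  cat(sprintf("<seeding_bias> %+.3f %%CEC per 1 SD resazurin (95%% CI %.3f, %.3f; n=%d)\n",
              x$slope_per_sd, x$ci95_low, x$ci95_high, x$n_wells))
  invisible(x)
}

#' cAMP-dependency contrast
#'
#' Welch contrast of sample-mean CEC between cAMP-treated and untreated
#' conditions: difference of means (cAMP minus no_cAMP) with a 95% CI.
#' Degenerate zero-variance data return the point difference with a
#' zero-width CI.
#'
#' @param mean_cec Sample-level mean CEC values.
#' @param condition `"cAMP"` / `"no_cAMP"` per sample.
#' @return List: `diff`, `ci95_low`, `ci95_high`, `p_value`, `n`.
#' @export
camp_contrast <- function(mean_cec, condition) {
  ok <- is.finite(mean_cec) & condition %in% c("cAMP", "no_cAMP")
  x <- mean_cec[ok & condition == "cAMP"]
  y <- mean_cec[ok & condition == "no_cAMP"]
  if (length(x) < 2 || length(y) < 2)
    stopf("camp_contrast needs >= 2 samples per condition (got %d cAMP, %d no_cAMP)",
          length(x), length(y))
  d <- mean(x) - mean(y)
  v <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (v == 0)
    return(list(diff = d, ci95_low = d, ci95_high = d, p_value = NA_real_,
                n = c(cAMP = length(x), no_cAMP = length(y))))
  tt <- stats::t.test(x, y)
  list(diff = d, ci95_low = tt$conf.int[1], ci95_high = tt$conf.int[2],
       p_value = tt$p.value, n = c(cAMP = length(x), no_cAMP = length(y)))
}
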