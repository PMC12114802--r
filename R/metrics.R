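#' Area under the concentration-time curve
#'
#' Trapezoidal integral of the venous blood concentration over `[t0, t1]`.
#' With both limits omitted the "full-profile" AUC is returned: integration
#' runs from the start of the profile to the first time after the peak where
#' the concentration has fallen below 0.1% of Cmax (or the end of the grid
#' if it never does).
#'
#' @param profile an `fu_profile` from [simulate_profile()].
#' @param t0,t1 integration limits (h) within the profile's time grid, or
#'   `NULL` for the full-profile AUC.
#' @return AUC in mg.h/L.
#' @examples
#' prof <- simulate_profile(dosing_regimen(dose_mg = 4612, duration_h = 24),
#'                          physiology = default_physiology(49))
#' pk_auc(prof)          # full profile
#' pk_auc(prof, 0, 24)   # over the infusion
#' @export
pk_auc <- function(profile, t0 = NULL, t1 = NULL) {
  tt <- profile$time_h
  cc <- profile$c_venous_mg_per_L
  if (length(tt) < 2) stop("profile too short to integrate")
  if (is.null(t0) != is.null(t1))
    stop("give both t0 and t1, or neither")
  if (is.null(t0)) {
    ipk <- which.max(cc)
    below <- which(seq_along(cc) > ipk & cc < 1e-3 * cc[ipk])
    iend <- if (length(below)) below[1] else length(tt)
    return(.fu_trapz(tt[1:iend], cc[1:iend]))
  }
  eps <- 1e-9
  if (t0 >= t1) stop("t0 must be less than t1")
  if (t0 < tt[1] - eps || t1 > tt[length(tt)] + eps)
    stop("integration interval lies outside the profile's time grid")
  # interpolate the endpoints so limits need not be grid points
  keep <- tt > t0 & tt < t1
  x <- c(t0, tt[keep], t1)
  y <- c(stats::approx(tt, cc, t0)$y, cc[keep], stats::approx(tt, cc, t1)$y)
  .fu_trapz(x, y)
}

.fu_trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Peak concentration
#'
#' Maximum venous blood concentration over the profile's grid.
#'
#' @param profile an `fu_profile`.
#' @return Cmax in mg/L.
#' @export
pk_cmax <- function(profile) {
  if (is.null(profile$c_venous_mg_per_L) || nrow(profile) == 0)
    stop("empty profile")
  max(profile$c_venous_mg_per_L)
}

#' Steady-state concentration from an AUC
#'
#' The model-independent estimate used in therapeutic drug monitoring:
#' \eqn{C_{ss} = AUC / \text{infusion time}}. Applied to a whole-course AUC
#' this slightly overstates the plateau value because the pre-plateau hours
#' are included; no correction is applied.
#'
#' @param auc_mg_h_per_L AUC in mg.h/L, measured over the infusion.
#' @param infusion_time_h infusion duration in h, positive.
#' @return Css in mg/L.
#' @examples
#' css_from_auc(40, 24)    # 1.667 mg/L: the conventional 40 mg.h/L target
#' css_from_auc(77.5, 24)  # 3.229 mg/L
#' @export
css_from_auc <- function(auc_mg_h_per_L, infusion_time_h) {
  if (any(infusion_time_h <= 0)) stop("infusion time must be positive")
  if (any(auc_mg_h_per_L < 0)) stop("AUC must be non-negative")
  auc_mg_h_per_L / infusion_time_h
}

# single-infusion bookkeeping: the one event of a constant-rate regimen
.fu_single_infusion <- function(profile) {
  reg <- attr(profile, "regimen")
  if (is.null(reg) || nrow(reg) != 1 || reg$duration_h[1] <= 0)
    stop("this operation requires a profile of a single constant-rate infusion")
  list(start = reg$start_h[1], end = reg$start_h[1] + reg$duration_h[1],
       duration = reg$duration_h[1], rate = reg$dose_mg[1] / reg$duration_h[1])
}

#' Observed (plateau) steady-state concentration
#'
#' Mean venous concentration over a window at the end of a constant-rate
#' infusion, the model-based analogue of the monitored Css. The default
#' window is the final 10% of the infusion. If the concentration still
#' drifts by more than 1%/h relative to its mean over the window, the value
#' carries the attribute `no_plateau = TRUE`.
#'
#' @param profile an `fu_profile` of a single constant-rate infusion.
#' @param window_h averaging window (h) ending at infusion end; must lie in
#'   the final third of the infusion. Default: 10% of the duration.
#' @return Css in mg/L, with logical attribute `no_plateau`.
#' @export
css_observed <- function(profile, window_h = NULL) {
  inf <- .fu_single_infusion(profile)
  if (is.null(window_h)) window_h <- 0.1 * inf$duration
  if (window_h <= 0 || window_h > inf$duration / 3)
    stop("window must be positive and lie within the infusion's final third")
  t0 <- inf$end - window_h
  tt <- profile$time_h
  cc <- profile$c_venous_mg_per_L
  sel <- tt >= t0 - 1e-9 & tt <= inf$end + 1e-9
  if (sum(sel) < 2) stop("window outside the profile grid")
  css <- mean(cc[sel])
  c0 <- stats::approx(tt, cc, t0)$y
  c1 <- stats::approx(tt, cc, inf$end)$y
  rel_slope <- abs(c1 - c0) / window_h / css
  structure(css, no_plateau = is.na(rel_slope) || rel_slope > 0.01)
}

#' Fraction of steady state attained at a time point
#'
#' For a constant-rate infusion that reaches a plateau, the ratio of the
#' venous concentration at time `t` to the plateau concentration. One hour
#' into a standard 24-h 5-FU infusion this is about one half, which is what
#' makes the early "dynamic" concentration usable to forecast Css.
#'
#' @param profile an `fu_profile` of a single constant-rate infusion with
#'   rate below the metabolic capacity Vmax.
#' @param t time (h) at which to evaluate the fraction, within the infusion.
#' @return dimensionless fraction in `[0, ~1]`.
#' @export
fraction_of_steady_state <- function(profile, t) {
  inf <- .fu_single_infusion(profile)
  substance <- attr(profile, "substance")
  if (!is.null(substance) && inf$rate >= substance$vmax_mg_per_h)
    stop("no steady state: infusion rate exceeds metabolic capacity")
  if (t < inf$start - 1e-9 || t > inf$end + 1e-9)
    stop("t must lie within the infusion")
  css <- as.numeric(css_observed(profile))
  ct <- stats::approx(profile$time_h, profile$c_venous_mg_per_L, t)$y
  ct / css
}

#' Forecast Css from an early (dynamic) concentration
#'
#' Inverts the attainment fraction: a concentration `cdyn` sampled when a
#' fraction `fraction` of steady state has been reached forecasts
#' \eqn{C_{ss} = C_{dyn} / fraction}. With the default 0.5 (the 1-h fraction
#' of a 24-h infusion), a 1-h sample above 1.5 mg/L forecasts a Css above
#' 3 mg/L, and above 3 mg/L forecasts a Css above 6 mg/L.
#'
#' @param cdyn_mg_per_L concentration at the early sampling time (mg/L).
#' @param fraction fraction of steady state attained at that time, in (0, 1].
#' @return forecast Css in mg/L.
#' @export
predict_css_from_cdyn <- function(cdyn_mg_per_L, fraction = 0.5) {
  if (any(fraction <= 0) || any(fraction > 1))
    stop("fraction must lie in (0, 1]")
  if (any(cdyn_mg_per_L < 0)) stop("cdyn must be non-negative")
  cdyn_mg_per_L / fraction
}

#' Exposure summary of a profile
#'
#' The PK metrics argued over in 5-FU monitoring, in one row: peak
#' concentration, full-profile AUC, plateau Css (single-infusion profiles
#' only, `NA` otherwise) and the dynamic concentration at an early sampling
#' time.
#'
#' @param profile an `fu_profile`.
#' @param cdyn_time_h sampling time (h) for the dynamic concentration,
#'   measured from the profile origin; default 1 h.
#' @return A one-row `data.frame`: `cmax_mg_per_L`, `auc_mg_h_per_L`,
#'   `css_mg_per_L`, `no_plateau`, `cdyn_mg_per_L`, `t_sample_h`.
#' @export
exposure_summary <- function(profile, cdyn_time_h = 1.0) {
  css <- tryCatch(css_observed(profile), error = function(e) NA_real_)
  cdyn <- stats::approx(profile$time_h, profile$c_venous_mg_per_L,
                        cdyn_time_h)$y
  data.frame(cmax_mg_per_L = pk_cmax(profile),
             auc_mg_h_per_L = pk_auc(profile),
             css_mg_per_L = as.numeric(css),
             no_plateau = isTRUE(attr(css, "no_plateau")),
             cdyn_mg_per_L = cdyn,
             t_sample_h = cdyn_time_h)
}
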