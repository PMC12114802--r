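#' Intravenous dosing regimen
#'
#' Describes a schedule of iv events. Each event is a dose (mg) starting at
#' `start_h` and delivered at constant rate over `duration_h`; a duration of
#' 0 marks a bolus, which the solver realizes as a 1-minute constant-rate
#' infusion into venous blood. Doses may instead be given per body surface
#' area (mg/m2) together with a BSA, and are resolved to mg at construction.
#'
#' @param dose_mg dose(s) in mg. Mutually exclusive with `dose_per_m2`.
#' @param start_h event start time(s) in h (default 0).
#' @param duration_h infusion duration(s) in h; 0 means bolus (default 0).
#' @param dose_per_m2 dose(s) in mg per m2 body surface area.
#' @param bsa_m2 body surface area (m2) used to resolve `dose_per_m2`;
#'   default 1.8. See [bsa_dubois()].
#'
#' @return An object of class `fu_regimen`: a data.frame of events with
#'   columns `dose_mg`, `start_h`, `duration_h` plus a `dose_total_mg`
#'   attribute. Events must not overlap in time.
#' @examples
#' dosing_regimen(dose_mg = 4612, duration_h = 24)        # 24-h infusion
#' dosing_regimen(dose_per_m2 = 1000, bsa_m2 = 1.7, duration_h = 24)
#' @export
dosing_regimen <- function(dose_mg = NULL, start_h = 0, duration_h = 0,
                           dose_per_m2 = NULL, bsa_m2 = 1.8) {
  if (is.null(dose_mg) && is.null(dose_per_m2))
    stop("one of dose_mg or dose_per_m2 is required")
  if (!is.null(dose_mg) && !is.null(dose_per_m2))
    stop("give dose_mg or dose_per_m2, not both")
  if (is.null(dose_mg)) {
    if (!is.numeric(bsa_m2) || any(bsa_m2 <= 0)) stop("bsa_m2 must be positive")
    dose_mg <- dose_per_m2 * bsa_m2
  }
  n <- max(length(dose_mg), length(start_h), length(duration_h))
  dose_mg <- rep_len(as.numeric(dose_mg), n)
  start_h <- rep_len(as.numeric(start_h), n)
  duration_h <- rep_len(as.numeric(duration_h), n)
  if (any(!is.finite(dose_mg)) || any(dose_mg < 0)) stop("dose_mg must be >= 0")
  if (any(!is.finite(start_h)) || any(start_h < 0)) stop("start_h must be >= 0")
  if (any(!is.finite(duration_h)) || any(duration_h < 0))
    stop("duration_h must be >= 0")
  ev <- data.frame(dose_mg = dose_mg, start_h = start_h,
                   duration_h = duration_h)
  ev <- ev[order(ev$start_h), , drop = FALSE]
  rownames(ev) <- NULL
  # overlap check uses realized durations (bolus = 1 min)
  ends <- ev$start_h + pmax(ev$duration_h, .fu_bolus_duration_h)
  if (nrow(ev) > 1 && any(ev$start_h[-1] < ends[-nrow(ev)] - 1e-9))
    stop("dosing events overlap in time")
  structure(ev, dose_total_mg = sum(ev$dose_mg),
            class = c("fu_regimen", "data.frame"))
}

# realized length of an iv bolus (h): 1 minute
.fu_bolus_duration_h <- 1 / 60

# events with bolus durations replaced by the 1-minute realization, plus
# the constant infusion rate of each event
.fu_realized_events <- function(regimen) {
  ev <- as.data.frame(regimen)
  ev$duration_h <- pmax(ev$duration_h, .fu_bolus_duration_h)
  ev$rate_mg_per_h <- ifelse(ev$dose_mg > 0, ev$dose_mg / ev$duration_h, 0)
  ev$end_h <- ev$start_h + ev$duration_h
  ev
}

#' Body surface area by the DuBois formula
#'
#' \eqn{BSA = 0.007184 \, H^{0.725} \, W^{0.425}} with height in cm and
#' weight in kg.
#'
#' @param height_cm height (cm).
#' @param weight_kg weight (kg).
#' @return BSA in m2.
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' @export
print.fu_regimen <- function(x, ...) {
  cat(sprintf("iv dosing regimen: %d event(s), total dose %.1f mg\n",
              nrow(x), attr(x, "dose_total_mg")))
  print(as.data.frame(x))
  invisible(x)
}
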