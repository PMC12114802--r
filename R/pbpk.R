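#' Hepatic Michaelis-Menten metabolic rate
#'
#' Rate of amount metabolized (RAM, mg/h) as a function of the concentration
#' in the venous blood leaving the liver:
#' \eqn{RAM = V_{max} C_V / (K_m + C_V)} with \eqn{C_V = C_{liver}/P_{liver}}.
#'
#' @param cv_liver liver venous (outflow) concentration, mg/L; non-negative.
#' @param substance an `fu_substance` object, see [substance_parameters()].
#' @return metabolic rate in mg/h.
#' @examples
#' metabolic_rate(11.7, default_substance())  # half saturation: Vmax/2
#' @export
metabolic_rate <- function(cv_liver, substance = default_substance()) {
  if (any(!is.finite(cv_liver)) || any(cv_liver < 0))
    stop("cv_liver must be a non-negative finite concentration")
  substance$vmax_mg_per_h * cv_liver / (substance$km_mg_per_L + cv_liver)
}

# state vector layout helpers ------------------------------------------------

.fu_state_names <- function(physiology) {
  c(paste0("c_", physiology$tissues$name), "c_venous", "c_arterial",
    "amount_metabolized")
}

#' PBPK model derivatives (reference implementation)
#'
#' Rate of change of the model state. Non-metabolizing tissues follow
#' \eqn{V_T \, dC_T/dt = Q_T (C_A - C_T/P_T)}; the liver additionally loses
#' drug at the Michaelis-Menten rate driven by its venous-equilibrium
#' concentration \eqn{C_{liver}/P_{liver}} (well-stirred, flow-limited
#' reading). Venous blood collects all tissue outflows plus the iv input;
#' arterial blood receives the total tissue flow at venous concentration
#' (lungs and heart close the circulation as a zero-volume pass-through).
#' The last state element accumulates the amount metabolized (mg).
#'
#' This R function is the readable reference used in tests; [simulate_profile()]
#' integrates the identical equations in compiled code.
#'
#' @param t time (h); unused, present for the deSolve signature.
#' @param state numeric state: one concentration per tissue (in physiology
#'   order), then venous and arterial blood concentrations, then cumulative
#'   amount metabolized.
#' @param physiology an `fu_physiology` object.
#' @param substance an `fu_substance` object.
#' @param input_rate iv input rate into venous blood at time `t` (mg/h),
#'   either a single number or a function of `t`.
#' @return A list whose first element is the derivative of `state` (deSolve
#'   convention).
#' @export
pbpk_derivatives <- function(t, state, physiology, substance,
                             input_rate = 0) {
  tis <- physiology$tissues
  nt <- nrow(tis)
  if (length(state) != nt + 3)
    stop(sprintf("state must have length %d (tissues + venous + arterial + metabolized), got %d",
                 nt + 3, length(state)))
  rate <- if (is.function(input_rate)) input_rate(t) else input_rate
  if (!is.finite(rate) || rate < 0) stop("input_rate must be >= 0")
  ct <- state[seq_len(nt)]
  cv <- state[nt + 1]
  ca <- state[nt + 2]
  cvt <- ct / tis$partition
  dct <- tis$flow_L_per_h * (ca - cvt) / tis$volume_L
  imet <- which(tis$metabolizing)
  ram <- metabolic_rate(max(cvt[imet], 0), substance)
  dct[imet] <- dct[imet] - ram / tis$volume_L[imet]
  dcv <- (sum(tis$flow_L_per_h * cvt) - physiology$total_flow_L_per_h * cv +
            rate) / physiology$venous_blood_volume_L
  dca <- physiology$total_flow_L_per_h * (cv - ca) /
    physiology$arterial_blood_volume_L
  list(c(dct, dcv, dca, ram))
}

#' Analytic steady state of a constant-rate infusion
#'
#' At steady state the whole infusion rate is metabolized, so the liver
#' venous concentration solves \eqn{rate = V_{max} C_V/(K_m + C_V)}, i.e.
#' \eqn{C_V = rate \cdot K_m / (V_{max} - rate)}, and the arterial (= venous)
#' blood concentration is \eqn{C_A = C_V + rate/Q_{liver}}. No finite steady
#' state exists when the infusion rate reaches the metabolic capacity
#' \eqn{V_{max}}: the concentration then grows without bound, which is the
#' kinetic root of the danger of high-rate infusions.
#'
#' @param rate_mg_per_h constant infusion rate (mg/h), `0 < rate < Vmax`.
#' @param physiology an `fu_physiology` object.
#' @param substance an `fu_substance` object.
#' @return A list with `cv_liver`, `c_arterial` and `c_venous` (mg/L;
#'   arterial and venous agree at steady state).
#' @examples
#' steady_state_analytic(4612 / 24)  # planned patient schedule: ~4.12 mg/L
#' @export
steady_state_analytic <- function(rate_mg_per_h,
                                  physiology = default_physiology(),
                                  substance = default_substance()) {
  if (rate_mg_per_h <= 0) stop("infusion rate must be positive")
  if (rate_mg_per_h >= substance$vmax_mg_per_h)
    stop("no finite steady state: infusion rate exceeds metabolic capacity")
  cv <- rate_mg_per_h * substance$km_mg_per_L /
    (substance$vmax_mg_per_h - rate_mg_per_h)
  imet <- which(physiology$tissues$metabolizing)
  q_liver <- physiology$tissues$flow_L_per_h[imet]
  ca <- cv + rate_mg_per_h / q_liver
  list(cv_liver = cv, c_arterial = ca, c_venous = ca)
}

# flatten physiology+substance into the compiled model's parameter vector
.fu_c_parms <- function(physiology, substance, rate) {
  tis <- physiology$tissues
  c(tis$volume_L, tis$flow_L_per_h, tis$partition,
    physiology$venous_blood_volume_L, physiology$arterial_blood_volume_L,
    physiology$total_flow_L_per_h, substance$vmax_mg_per_h,
    substance$km_mg_per_L, rate, which(tis$metabolizing)[1] - 1)
}

#' Simulate a concentration-time profile
#'
#' Integrates the PBPK model over an iv dosing schedule. The integration is
#' split at every event boundary so the input rate is constant on each
#' segment (boluses are realized as 1-minute infusions); within segments the
#' stiff-capable `lsoda` solver is used with a fixed output grid so that
#' trapezoidal AUCs are reproducible. Mass balance (dose delivered = amount
#' in body + amount metabolized) is checked at the end of the run.
#'
#' @param regimen an `fu_regimen`, see [dosing_regimen()].
#' @param physiology an `fu_physiology` object.
#' @param substance an `fu_substance` object.
#' @param t_end_h end of simulation (h); default: last event end + 24 h.
#' @param dt_dosing_h output grid step while any infusion runs (default
#'   0.01 h).
#' @param dt_washout_h output grid step outside dosing (default 0.05 h).
#' @param rtol,atol relative/absolute solver tolerances (defaults 1e-8,
#'   1e-10 mg/L).
#' @param engine `"auto"` (compiled C right-hand side when the physiology has
#'   the standard 9-tissue layout, R otherwise), `"compiled"`, or `"R"`.
#' @param mass_balance_tol maximum tolerated relative mass-balance error
#'   (default 1e-3); exceeding it is an error naming the regimen.
#'
#' @return An `fu_profile`: a data.frame with columns `time_h`,
#'   `c_venous_mg_per_L`, `c_arterial_mg_per_L`, one `c_<tissue>_mg_per_L`
#'   column per tissue and `amount_metabolized_mg`, with attributes
#'   `regimen`, `physiology`, `substance`, `dose_total_mg`,
#'   `last_event_end_h` and `mass_balance_rel_error`.
#' @examples
#' prof <- simulate_profile(dosing_regimen(dose_mg = 4612, duration_h = 24),
#'                          physiology = default_physiology(49))
#' pk_cmax(prof)
#' @export
simulate_profile <- function(regimen,
                             physiology = default_physiology(),
                             substance = default_substance(),
                             t_end_h = NULL,
                             dt_dosing_h = 0.01, dt_washout_h = 0.05,
                             rtol = 1e-8, atol = 1e-10,
                             engine = c("auto", "compiled", "R"),
                             mass_balance_tol = 1e-3) {
  if (!inherits(regimen, "fu_regimen")) stop("`regimen` must be an fu_regimen")
  engine <- match.arg(engine)
  tis <- physiology$tissues
  nt <- nrow(tis)
  use_c <- switch(engine,
                  compiled = TRUE,
                  R = FALSE,
                  auto = nt == 9 && sum(tis$metabolizing) == 1)
  if (use_c && (nt != 9 || sum(tis$metabolizing) != 1))
    stop("the compiled model requires the standard 9-tissue layout; use engine = \"R\"")

  ev <- .fu_realized_events(regimen)
  last_end <- if (nrow(ev)) max(ev$end_h) else 0
  if (is.null(t_end_h)) t_end_h <- last_end + 24
  if (t_end_h <= last_end && nrow(ev) && any(ev$dose_mg > 0))
    stop("t_end_h must lie beyond the last dosing event")

  # piecewise-constant input rate: segment boundaries at event starts/ends
  bounds <- sort(unique(c(0, ev$start_h, ev$end_h, t_end_h)))
  bounds <- bounds[bounds <= t_end_h + 1e-12]
  seg <- data.frame(from = head(bounds, -1), to = tail(bounds, -1))
  seg$rate <- vapply(seq_len(nrow(seg)), function(i) {
    mid <- (seg$from[i] + seg$to[i]) / 2
    hit <- ev$start_h <= mid & mid < ev$end_h
    if (any(hit)) sum(ev$rate_mg_per_h[hit]) else 0
  }, numeric(1))
  seg$dosing <- seg$rate > 0 | seg$to <= last_end + 1e-12

  state <- stats::setNames(rep(0, nt + 3), .fu_state_names(physiology))
  rows <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    dt <- if (seg$dosing[i]) dt_dosing_h else dt_washout_h
    times <- seq(seg$from[i], seg$to[i], by = dt)
    if (seg$to[i] - times[length(times)] > 1e-9) {
      times <- c(times, seg$to[i])
    } else {
      times[length(times)] <- seg$to[i]
    }
    out <- tryCatch({
      if (use_c) {
        deSolve::lsoda(y = unname(state), times = times, func = "fupbpk_derivs",
                       parms = .fu_c_parms(physiology, substance, seg$rate[i]),
                       dllname = "fupbpk", initfunc = "fupbpk_initmod",
                       rtol = rtol, atol = atol)
      } else {
        deSolve::lsoda(y = unname(state), times = times,
                       func = function(t, y, p)
                         pbpk_derivatives(t, y, physiology, substance, p),
                       parms = seg$rate[i], rtol = rtol, atol = atol)
      }
    }, error = function(e) e)
    if (inherits(out, "error") || nrow(out) < length(times))
      stop(sprintf("solver failed on regimen (total dose %.1f mg) in segment [%.3f, %.3f] h: %s",
                   attr(regimen, "dose_total_mg"), seg$from[i], seg$to[i],
                   if (inherits(out, "error")) conditionMessage(out) else "incomplete integration"))
    state <- out[nrow(out), -1]
    rows[[i]] <- out[if (i > 1) -1 else TRUE, , drop = FALSE]
  }
  res <- do.call(rbind, rows)

  conc <- res[, 1 + seq_len(nt + 2), drop = FALSE]
  if (any(conc < -1e-6))
    stop("negative concentrations beyond tolerance; tighten solver tolerances")
  conc[conc < 0] <- 0

  prof <- data.frame(time_h = res[, 1],
                     c_venous = conc[, nt + 1],
                     c_arterial = conc[, nt + 2],
                     conc[, seq_len(nt), drop = FALSE],
                     amount_metabolized_mg = pmax(res[, nt + 4], 0))
  names(prof) <- c("time_h", "c_venous_mg_per_L", "c_arterial_mg_per_L",
                   paste0("c_", tis$name, "_mg_per_L"),
                   "amount_metabolized_mg")

  dose_total <- attr(regimen, "dose_total_mg")
  in_body <- sum(conc[nrow(conc), seq_len(nt)] * tis$volume_L) +
    conc[nrow(conc), nt + 1] * physiology$venous_blood_volume_L +
    conc[nrow(conc), nt + 2] * physiology$arterial_blood_volume_L
  mb_err <- if (dose_total > 0)
    abs(dose_total - in_body - prof$amount_metabolized_mg[nrow(prof)]) /
      dose_total else 0
  if (mb_err > mass_balance_tol)
    stop(sprintf("mass balance violated (relative error %.2e) for regimen with total dose %.1f mg",
                 mb_err, dose_total))

  structure(prof, regimen = regimen, physiology = physiology,
            substance = substance, dose_total_mg = dose_total,
            last_event_end_h = last_end, mass_balance_rel_error = mb_err,
            class = c("fu_profile", "data.frame"))
}

#' @export
print.fu_profile <- function(x, ...) {
  cat(sprintf("PBPK profile: %d time points over [%.2f, %.2f] h, dose %.1f mg\n",
              nrow(x), x$time_h[1], x$time_h[nrow(x)], attr(x, "dose_total_mg")))
  cat(sprintf("Cmax (venous) %.3f mg/L; mass-balance rel. error %.1e\n",
              max(x$c_venous_mg_per_L), attr(x, "mass_balance_rel_error")))
  invisible(x)
}

#' Export a profile to CSV
#'
#' Writes the profile's time grid and concentration columns to a CSV file,
#' preceded by `#`-comment header lines recording the dose and mass-balance
#' check (and any extra stamp lines supplied).
#'
#' @param profile an `fu_profile`.
#' @param path output file path.
#' @param stamp optional named character vector written as extra header lines.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, stamp = NULL) {
  header <- c(sprintf("# fupbpk profile; total dose %.6g mg; mass balance rel. error %.3e",
                      attr(profile, "dose_total_mg"),
                      attr(profile, "mass_balance_rel_error")),
              if (length(stamp)) sprintf("# %s: %s", names(stamp), stamp))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}
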