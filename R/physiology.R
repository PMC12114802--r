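#' Tissue parameter set for the perfusion-limited model
#'
#' Builds the per-tissue parameter table of the PBPK model: one row per
#' organ with its volume \eqn{V_T} (L), blood flow \eqn{Q_T} (L/h),
#' tissue:blood partition coefficient \eqn{P_T} (dimensionless) and a flag
#' marking the metabolizing tissue (the liver in the default model).
#'
#' @param name character vector of tissue labels.
#' @param volume_L tissue volumes (L), all positive.
#' @param flow_L_per_h blood flows through the tissues (L/h), all positive.
#' @param partition tissue:blood partition coefficients, all positive.
#' @param metabolizing logical; which tissues eliminate drug. The default
#'   model has exactly one (liver).
#'
#' @return A `data.frame` of class `fu_tissues`.
#' @export
tissue_parameters <- function(name, volume_L, flow_L_per_h, partition,
                              metabolizing) {
  n <- length(name)
  stopifnot(length(volume_L) == n, length(flow_L_per_h) == n,
            length(partition) == n, length(metabolizing) == n)
  if (any(volume_L <= 0)) stop("tissue volumes must be positive")
  if (any(flow_L_per_h <= 0)) stop("tissue blood flows must be positive")
  if (any(partition <= 0)) stop("partition coefficients must be positive")
  out <- data.frame(name = as.character(name), volume_L = as.numeric(volume_L),
                    flow_L_per_h = as.numeric(flow_L_per_h),
                    partition = as.numeric(partition),
                    metabolizing = as.logical(metabolizing),
                    stringsAsFactors = FALSE)
  class(out) <- c("fu_tissues", "data.frame")
  out
}

#' Whole-body physiology for the PBPK model
#'
#' Assembles tissues, blood volumes and cardiac output into the physiology
#' object the solver consumes. The nine tissue flows need not add up to the
#' cardiac output exactly (reference tables rarely balance); the venous-to-
#' arterial transfer uses the sum of the tissue flows so compartment-level
#' mass balance holds. A tissue-flow sum exceeding cardiac output by more
#' than 5% is rejected as inconsistent.
#'
#' @param body_weight_kg body weight (kg).
#' @param cardiac_output_L_per_h cardiac output Qc (L/h).
#' @param tissues an `fu_tissues` table, see [tissue_parameters()].
#' @param arterial_blood_volume_L,venous_blood_volume_L blood volumes (L).
#'
#' @return An object of class `fu_physiology`: a list with the fields above
#'   plus `total_flow_L_per_h`, the sum of tissue flows.
#' @seealso [default_physiology()]
#' @export
physiology <- function(body_weight_kg, cardiac_output_L_per_h, tissues,
                       arterial_blood_volume_L, venous_blood_volume_L) {
  if (!inherits(tissues, "fu_tissues")) stop("`tissues` must be an fu_tissues table")
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (cardiac_output_L_per_h <= 0) stop("cardiac output must be positive")
  if (arterial_blood_volume_L <= 0 || venous_blood_volume_L <= 0)
    stop("blood volumes must be positive")
  qsum <- sum(tissues$flow_L_per_h)
  if (qsum > cardiac_output_L_per_h * 1.05)
    stop("sum of tissue flows exceeds cardiac output by more than 5%")
  if (sum(tissues$metabolizing) < 1)
    stop("at least one metabolizing tissue is required")
  structure(list(body_weight_kg = body_weight_kg,
                 cardiac_output_L_per_h = cardiac_output_L_per_h,
                 tissues = tissues,
                 arterial_blood_volume_L = arterial_blood_volume_L,
                 venous_blood_volume_L = venous_blood_volume_L,
                 total_flow_L_per_h = qsum),
            class = "fu_physiology")
}

# Reference parameter table: ICRP-style volumes (L) and flows (L/h) for a
# 73-kg adult; muscle and skin volumes are written as coefficients on body
# weight and are the only body-weight-dependent entries.
.fu_reference_tissues <- function(body_weight_kg) {
  tissue_parameters(
    name = c("fat", "liver", "brain", "kidney", "muscle", "skin",
             "vessel_rich", "skeleton", "red_marrow"),
    volume_L = c(18.2, 1.8, 1.45, 0.31, 0.40 * body_weight_kg,
                 0.0371 * body_weight_kg, 2.6, 6.9, 1.2),
    flow_L_per_h = c(19.5, 99.5, 46.8, 74.1, 65.8, 20, 44.8, 7.8, 11.7),
    partition = c(0.20, 0.92, 1.35, 0.98, 2.19, 10.04, 0.98, 0.63, 0.92),
    metabolizing = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE))
}

# Reference total blood volume (L) at 73 kg, split 1/3 arterial 2/3 venous,
# scaled linearly with body weight.
.fu_reference_blood_L <- 5.3
.fu_reference_bw_kg <- 73

#' Default human physiology for 5-FU
#'
#' Reference physiology of the model: cardiac output 401.7 L/h and the
#' nine-organ table of volumes, flows and 5-FU partition coefficients (fat,
#' liver, brain, kidney, muscle, skin, vessel-rich tissue, skeleton, red
#' marrow). Only muscle (0.40 x bw) and skin (0.0371 x bw) volumes scale
#' with body weight; all other volumes and all flows stay at their reference
#' values. Total blood volume is 5.3 L at 73 kg, split 1/3 arterial and 2/3
#' venous, scaled linearly with body weight.
#'
#' @param body_weight_kg body weight in kg (default 73, the reference adult).
#' @return An `fu_physiology` object.
#' @examples
#' phys <- default_physiology(49)
#' subset(phys$tissues, name == "muscle")$volume_L  # 19.6 L
#' @export
default_physiology <- function(body_weight_kg = 73) {
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1 ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be a single positive number")
  blood <- .fu_reference_blood_L * body_weight_kg / .fu_reference_bw_kg
  physiology(body_weight_kg = body_weight_kg,
             cardiac_output_L_per_h = 401.7,
             tissues = .fu_reference_tissues(body_weight_kg),
             arterial_blood_volume_L = blood / 3,
             venous_blood_volume_L = 2 * blood / 3)
}

#' Substance (drug) parameters
#'
#' Michaelis-Menten elimination constants plus physicochemical metadata for
#' the modeled compound.
#'
#' @param vmax_mg_per_h maximum metabolic rate \eqn{V_{max}} (mg/h).
#' @param km_mg_per_L half-saturation concentration \eqn{K_m} (mg/L).
#' @param log_kow octanol/water partition coefficient (metadata).
#' @param pka acid dissociation constant (metadata).
#' @param fraction_bound plasma protein binding fraction (metadata).
#' @return An object of class `fu_substance`.
#' @export
substance_parameters <- function(vmax_mg_per_h, km_mg_per_L, log_kow = NA_real_,
                                 pka = NA_real_, fraction_bound = NA_real_) {
  if (!is.numeric(vmax_mg_per_h) || vmax_mg_per_h <= 0)
    stop("vmax_mg_per_h must be positive")
  if (!is.numeric(km_mg_per_L) || km_mg_per_L <= 0)
    stop("km_mg_per_L must be positive")
  structure(list(vmax_mg_per_h = vmax_mg_per_h, km_mg_per_L = km_mg_per_L,
                 log_kow = log_kow, pka = pka, fraction_bound = fraction_bound),
            class = "fu_substance")
}

#' Default 5-fluorouracil parameters
#'
#' Hepatic Michaelis-Menten constants for 5-FU elimination by
#' dihydropyrimidine dehydrogenase: Vmax 1221.7 mg/h, Km 11.7 mg/L;
#' log Kow -0.89, pKa 8.02, protein binding 8-12% (midpoint 0.10).
#'
#' @return An `fu_substance` object.
#' @export
default_substance <- function() {
  substance_parameters(vmax_mg_per_h = 1221.7, km_mg_per_L = 11.7,
                       log_kow = -0.89, pka = 8.02, fraction_bound = 0.10)
}

#' @export
print.fu_physiology <- function(x, ...) {
  cat(sprintf("PBPK physiology: bw %.1f kg, Qc %.1f L/h, %d tissues (flow sum %.1f L/h)\n",
              x$body_weight_kg, x$cardiac_output_L_per_h, nrow(x$tissues),
              x$total_flow_L_per_h))
  cat(sprintf("blood volumes: arterial %.2f L, venous %.2f L\n",
              x$arterial_blood_volume_L, x$venous_blood_volume_L))
  print(as.data.frame(x$tissues))
  invisible(x)
}

#' @export
print.fu_substance <- function(x, ...) {
  cat(sprintf("substance: Vmax %.1f mg/h, Km %.2f mg/L\n",
              x$vmax_mg_per_h, x$km_mg_per_L))
  invisible(x)
}
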