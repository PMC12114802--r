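# Naive brute-force decision-stump oracle: evaluates the Gini gain of every
# candidate midpoint split of every feature directly from the impurity
# definition, with the same tie-break convention (css before auc, smaller
# threshold). Deliberately O(n^2) and loop-based so it shares no code path
# with fit_stump().
oracle_stump <- function(css, auc, y) {
  gini <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- mean(lab)
    1 - p^2 - (1 - p)^2
  }
  n <- length(y)
  parent <- gini(y)
  best <- list(gain = -Inf, feature = NA_character_, threshold = NA_real_)
  for (feature in c("css", "auc")) {
    x <- if (feature == "css") css else auc
    v <- sort(unique(x))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      lo <- x < thr
      gain <- parent - sum(lo) / n * gini(y[lo]) -
        sum(!lo) / n * gini(y[!lo])
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, feature = feature, threshold = thr)
    }
  }
  if (!is.finite(best$gain) || best$gain <= 0)
    return(list(gain = 0, feature = NA_character_, threshold = NA_real_))
  lo <- (if (best$feature == "css") css else auc) < best$threshold
  best$leaf_counts <- rbind(below = c(sum(!y & lo), sum(y & lo)),
                            above = c(sum(!y & !lo), sum(y & !lo)))
  best
}

# random exposure-like dataset for stump property tests
random_stump_data <- function(n) {
  css <- round(runif(n, 0, 10), 2)          # rounding induces ties
  auc <- round(css * runif(n, 5, 30), 1)    # correlated, noisy feature
  y <- runif(n) < plogis(css - 5)
  list(rows = data.frame(css_mg_per_L = css, auc_mg_h_per_L = auc,
                         toxicity = ifelse(y, "life_threatening", "none")),
       css = css, auc = auc, y = y)
}

# hand-built profile object for metric tests that need exact curves
fake_profile <- function(time_h, c_venous, regimen = NULL,
                         substance = default_substance()) {
  structure(data.frame(time_h = time_h, c_venous_mg_per_L = c_venous),
            regimen = regimen, substance = substance,
            class = c("fu_profile", "data.frame"))
}

# patient-case regimens used across tests
patient_erroneous <- function() dosing_regimen(dose_mg = 3052, duration_h = 2)
patient_planned <- function() dosing_regimen(dose_mg = 4612, duration_h = 24)
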