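## Agent life course: fertility, pregnancy state chart, births with
## intergenerational risk endowment, weight categories, and the legacy
## risk-factor-count comparator.

#' Default age-specific conception hazard table
#'
#' Annual conception hazards by 5-year band over the reproductive window
#' (15-49), stylised on contemporary Australian age-specific fertility.
#' @return data.frame (`age_lo`, `age_hi`, `rate`).
#' @export
default_fertility <- function() {
  data.frame(
    age_lo = seq(15, 45, by = 5),
    age_hi = seq(20, 50, by = 5),
    rate = c(0.015, 0.055, 0.100, 0.120, 0.070, 0.015, 0.002)
  )
}

#' Age-specific conception hazard
#'
#' Piecewise-constant hazard (per year) looked up from a fertility table;
#' zero outside the reproductive window \[15, 50).
#'
#' @param age age in years (vectorised).
#' @param fertility fertility table as from [default_fertility()].
#' @return hazard rate per year, >= 0.
#' @export
conception_hazard <- function(age, fertility = default_fertility()) {
  idx <- findInterval(age, c(fertility$age_lo, fertility$age_hi[nrow(fertility)]))
  out <- ifelse(idx >= 1 & idx <= nrow(fertility), fertility$rate[pmax(idx, 1)], 0)
  ifelse(age < fertility$age_lo[1] | age >= fertility$age_hi[nrow(fertility)],
         0, out)
}

#' Advance a pregnancy by a number of weeks
#'
#' The pregnancy state chart: gestation advances week by week; crossing week
#' 40 emits a delivery and moves the woman to POSTPARTUM; POSTPARTUM reverts
#' to NOT_PREGNANT after the configured interval. Gestation is fixed at 40
#' weeks (no preterm birth).
#'
#' @param state pregnancy state, one of `"NOT_PREGNANT"`, `"PREGNANT"`,
#'   `"POSTPARTUM"`.
#' @param gestational_week current week in [0, 40].
#' @param dt_weeks weeks to advance, > 0.
#' @return list with `state`, `gestational_week` (reset to 0 on delivery)
#'   and `delivered` (logical).
#' @export
advance_pregnancy <- function(state, gestational_week, dt_weeks) {
  if (!identical(state, "PREGNANT"))
    stop("cannot advance pregnancy of a ", state, " agent", call. = FALSE)
  w <- gestational_week + dt_weeks
  if (w >= 40)
    list(state = "POSTPARTUM", gestational_week = 0, delivered = TRUE)
  else
    list(state = "PREGNANT", gestational_week = w, delivered = FALSE)
}

#' Intergenerational risk endowment at birth
#'
#' Babies are born with a risk profile reflecting both the mother's history
#' and her glycemic control during the pregnancy: the in-utero dysglycemia
#' flag is set when the mother's mean pregnancy glycemic index reached the
#' dysglycemia threshold, and flagged babies start with reduced baseline
#' beta-cell function and an upward childhood BMI drift.
#'
#' @param mean_G mother's mean glycemic index over the pregnancy
#'   (vectorised).
#' @param mother_state mother's glycemic state (`classify_glycemic()$state`).
#' @param mother_prior_gdm logical.
#' @param params a [physiology_params()] object.
#' @param b_base_mult multiplier applied to an exposed baby's baseline
#'   beta-cell function (default 0.9).
#' @param drift_mult childhood BMI drift multiplier for exposed babies
#'   (default 1.3).
#' @return data.frame with `in_utero_dysglycemia`, `family_history`,
#'   `b_base_mult`, `drift_mult` per baby.
#' @export
birth_endowment <- function(mean_G, mother_state, mother_prior_gdm,
                            params = physiology_params(),
                            b_base_mult = 0.9, drift_mult = 1.3) {
  exposed <- !is.na(mean_G) & mean_G >= params$g_thr
  data.frame(
    in_utero_dysglycemia = exposed,
    family_history = mother_state %in% c("IMPAIRED", "DIABETES") |
      as.logical(mother_prior_gdm),
    b_base_mult = ifelse(exposed, b_base_mult, 1),
    drift_mult = ifelse(exposed, drift_mult, 1)
  )
}

#' Probability of a composite adverse perinatal outcome
#'
#' Logistic in the mother's mean pregnancy glycemic index:
#' p = p_min + (p_max - p_min) / (1 + exp(-k (mean_G - g_mid))). Strictly
#' increasing and bounded by (p_min, p_max).
#'
#' @param mean_G mean glycemic index over the pregnancy, >= 0.
#' @param p_min,p_max floor and ceiling probabilities.
#' @param k logistic steepness.
#' @param g_mid glycemic index at the logistic midpoint.
#' @return probability vector.
#' @export
adverse_outcome_prob <- function(mean_G, p_min = 0.05, p_max = 0.45,
                                 k = 4, g_mid = 1.8) {
  if (any(mean_G < 0, na.rm = TRUE)) stop("mean_G must be >= 0", call. = FALSE)
  p_min + (p_max - p_min) / (1 + exp(-k * (mean_G - g_mid)))
}

#' Legacy risk-factor-count probability of diabetes in pregnancy
#'
#' The first-generation comparator model: the per-pregnancy probability of a
#' DIP diagnosis rises linearly with the count of true risk flags
#' (high-risk ethnicity, age >= 40, prior GDM, family history, BMI >= 30)
#' and is clamped to [0, 1]. Under this aetiology mode the latent physiology
#' is bypassed entirely.
#'
#' @param ethnicity_flag,prior_gdm,family_history logical risk flags.
#' @param age_years age in years.
#' @param bmi body-mass index.
#' @param p0 baseline probability with zero flags.
#' @param beta probability increment per flag.
#' @return probability in [0, 1].
#' @examples
#' risk_count_probability(TRUE, 41, FALSE, TRUE, 31, p0 = 0.03, beta = 0.04)
#' @export
risk_count_probability <- function(ethnicity_flag, age_years, prior_gdm,
                                   family_history, bmi,
                                   p0 = 0.03, beta = 0.04) {
  count <- as.numeric(as.logical(ethnicity_flag)) +
    as.numeric(age_years >= 40) +
    as.numeric(as.logical(prior_gdm)) +
    as.numeric(as.logical(family_history)) +
    as.numeric(bmi >= 30)
  clamp(p0 + beta * count, 0, 1)
}

#' Weight category from continuous BMI
#'
#' WHO cut-points with inclusive lower bounds: healthy below 25, overweight
#' from 25 up to (exclusive) 30, obese from 30.
#'
#' @param bmi body-mass index, > 0 (vectorised).
#' @return character vector in `{"healthy", "overweight", "obese"}`.
#' @export
weight_category <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0", call. = FALSE)
  ifelse(bmi >= 30, "obese", ifelse(bmi >= 25, "overweight", "healthy"))
}

## Initial BMI assignment: category probabilities by age group and risk
## group, then a continuous draw within the category's range (obese
## truncated at 45).
default_weight_init <- function() {
  ## late-1980s prevalence: the secular drift builds modern levels on top
  list(
    age_breaks = c(0, 25, 35, Inf),
    standard = rbind(c(0.78, 0.16, 0.06),
                     c(0.68, 0.22, 0.10),
                     c(0.62, 0.26, 0.12)),
    high_risk_ethnicity = rbind(c(0.70, 0.20, 0.10),
                                c(0.58, 0.27, 0.15),
                                c(0.52, 0.30, 0.18))
  )
}

draw_initial_bmi <- function(age, risk_group, weight_init, u_cat, u_val) {
  grp_idx <- findInterval(age, weight_init$age_breaks)
  grp_idx <- pmin(pmax(grp_idx, 1L), nrow(weight_init$standard))
  probs <- weight_init$standard[grp_idx, , drop = FALSE]
  hr <- risk_group == "high_risk_ethnicity"
  if (any(hr))
    probs[hr, ] <- weight_init$high_risk_ethnicity[grp_idx[hr], , drop = FALSE]
  cum1 <- probs[, 1]
  cum2 <- probs[, 1] + probs[, 2]
  cat <- ifelse(u_cat < cum1, 1L, ifelse(u_cat < cum2, 2L, 3L))
  lo <- c(18.5, 25, 30)[cat]
  hi <- c(25, 30, 45)[cat]
  lo + u_val * (hi - lo)
}
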