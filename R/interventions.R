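## Policy/program intervention scenarios: targeting, mechanism channels,
## and baseline-vs-scenario comparison.

#' Intervention specification
#'
#' Interventions act through two mechanistic channels: a weight channel
#' (`bmi_effect_kg`, converted to BMI units by height and applied over a
#' 6-month ramp) and an activity channel (`s_multiplier`, a direct multiplier
#' on baseline insulin sensitivity, letting physical activity improve
#' metabolic function without any weight change). Effects persist for
#' `duration_years` and then decay at `adherence_decay` per year.
#'
#' @param name label used in event logs and comparisons.
#' @param target `"population"` (all women 15-49), `"high_risk"`
#'   ([adips_high_risk()] true) or `"post_gdm"` (prior GDM).
#' @param timing `"pre_pregnancy"` (parity 0, not pregnant),
#'   `"inter_pregnancy"` (parity >= 1, not pregnant) or `"during_pregnancy"`.
#' @param uptake probability that an eligible woman ever enrols, in [0, 1].
#' @param bmi_effect_kg weight change in kg (<= 0 for loss).
#' @param s_multiplier insulin-sensitivity multiplier, >= 1 for benefit.
#' @param duration_years years the full effect persists, > 0.
#' @param adherence_decay fraction of the effect lost per year after the
#'   duration ends, in [0, 1].
#' @param start_year,end_year calendar window in which enrolment is open.
#' @return list of class `intervention_spec`.
#' @export
intervention_spec <- function(name, target = c("population", "high_risk", "post_gdm"),
                              timing = c("pre_pregnancy", "inter_pregnancy",
                                         "during_pregnancy"),
                              uptake = 0.5, bmi_effect_kg = 0,
                              s_multiplier = 1, duration_years = 5,
                              adherence_decay = 0.5,
                              start_year = -Inf, end_year = Inf) {
  target <- match.arg(target)
  timing <- match.arg(timing)
  stopifnot(uptake >= 0, uptake <= 1, duration_years > 0,
            adherence_decay >= 0, adherence_decay <= 1, s_multiplier > 0)
  structure(list(name = name, target = target, timing = timing,
                 uptake = uptake, bmi_effect_kg = bmi_effect_kg,
                 s_multiplier = s_multiplier, duration_years = duration_years,
                 adherence_decay = adherence_decay,
                 start_year = start_year, end_year = end_year),
            class = c("intervention_spec", "list"))
}

as_intervention_spec <- function(x) {
  if (inherits(x, "intervention_spec")) x else do.call(intervention_spec, x)
}

#' Intervention eligibility
#'
#' Target gates: `population` covers all women aged 15-49; `high_risk`
#' requires the high-risk screening definition; `post_gdm` requires a prior
#' GDM pregnancy. Timing gates: `pre_pregnancy` requires parity 0 and not
#' pregnant; `inter_pregnancy` parity >= 1 and not pregnant;
#' `during_pregnancy` requires a current pregnancy.
#'
#' @param spec an [intervention_spec()].
#' @param age,bmi numeric (vectorised).
#' @param ethnicity_flag,prior_gdm,family_history logical flags.
#' @param parity pregnancy count.
#' @param pregnant logical, currently pregnant.
#' @return logical vector.
#' @export
intervention_eligible <- function(spec, age, bmi, ethnicity_flag, prior_gdm,
                                  family_history, parity, pregnant) {
  in_window <- age >= 15 & age < 50
  tgt <- switch(spec$target,
    population = in_window,
    high_risk = in_window & adips_high_risk(ethnicity_flag, age, prior_gdm,
                                            family_history, bmi),
    post_gdm = in_window & as.logical(prior_gdm))
  tim <- switch(spec$timing,
    pre_pregnancy = parity == 0 & !pregnant,
    inter_pregnancy = parity >= 1 & !pregnant,
    during_pregnancy = as.logical(pregnant))
  tgt & tim
}

#' Time profile of an intervention's effect channels
#'
#' Given enrolment time(s), returns the current fractional intensity of the
#' weight channel (ramps up over 6 months, then decays at `adherence_decay`
#' per year once `duration_years` have elapsed) and of the activity channel
#' (immediate, same decay). Intensity 1 means full effect.
#'
#' @param spec an [intervention_spec()].
#' @param t current time (years).
#' @param t_enrol enrolment time(s); `NA` means never enrolled (intensity 0).
#' @return list with numeric vectors `bmi` and `s`.
#' @keywords internal
intervention_intensity <- function(spec, t, t_enrol) {
  el <- t - t_enrol
  active <- !is.na(el) & el >= 0
  ramp <- clamp(el / 0.5, 0, 1)
  after <- pmax(0, el - spec$duration_years)
  retain <- pmax(0, 1 - spec$adherence_decay * after)
  bmi <- ifelse(active, ramp * retain, 0)
  s <- ifelse(active, retain, 0)
  list(bmi = bmi, s = s)
}

#' Apply an intervention to agent attributes (functional form)
#'
#' Returns the modified BMI and effective baseline sensitivity implied by an
#' enrolment at `t_enrol` evaluated at time `t`. Raises an error when the
#' agent is not eligible. This is the single-shot functional counterpart of
#' the rolling enrolment the simulation engine performs.
#'
#' @inheritParams intervention_eligible
#' @param spec an [intervention_spec()].
#' @param height_m height in metres.
#' @param s_base baseline insulin sensitivity.
#' @param t evaluation time, years.
#' @param t_enrol enrolment time, years (<= t).
#' @param enrolled logical; if `FALSE` (uptake draw failed) the agent is
#'   returned unchanged.
#' @return list with `bmi` and `s_base`.
#' @export
apply_intervention <- function(spec, age, bmi, ethnicity_flag, prior_gdm,
                               family_history, parity, pregnant, height_m,
                               s_base, t = 0, t_enrol = 0, enrolled = TRUE) {
  ok <- intervention_eligible(spec, age, bmi, ethnicity_flag, prior_gdm,
                              family_history, parity, pregnant)
  if (!all(ok))
    stop("agent not eligible for intervention '", spec$name, "'",
         call. = FALSE)
  if (!enrolled) return(list(bmi = bmi, s_base = s_base))
  inten <- intervention_intensity(spec, t, t_enrol)
  list(
    bmi = bmi + inten$bmi * delta_bmi(spec$bmi_effect_kg, height_m),
    s_base = s_base * (1 + inten$s * (spec$s_multiplier - 1))
  )
}

#' Compare a scenario run against a baseline
#'
#' Computes per-year differences (scenario minus baseline) and relative
#' reductions for DIP incidence, adverse outcomes and service costs. When
#' lists of replicate runs are supplied (>= 2 seeds shared pairwise between
#' the arms), the table carries the replicate mean and a percentile interval.
#' Combined effects of stacked interventions are reported, never assumed
#' additive.
#'
#' @param baseline,scenario a `dip_run` or a list of `dip_run` replicates
#'   with matching horizons and reporting years.
#' @param probs percentile interval bounds (default 5% and 95%).
#' @return data.frame with one row per year and metric: `delta` (absolute),
#'   `rel_reduction`, and `lo`/`hi` interval columns when replicated.
#' @export
scenario_compare <- function(baseline, scenario, probs = c(0.05, 0.95)) {
  as_list <- function(x) if (inherits(x, "dip_run")) list(x) else x
  b <- as_list(baseline); s <- as_list(scenario)
  if (length(b) != length(s))
    stop("baseline and scenario must have the same number of replicates",
         call. = FALSE)
  metrics <- c("dip_frac", "adverse", "total_cost")
  pair_delta <- function(br, sr) {
    if (!identical(br$annual$year, sr$annual$year))
      stop("mismatched horizons or reporting years", call. = FALSE)
    do.call(rbind, lapply(metrics, function(m) {
      bv <- br$annual[[m]]; sv <- sr$annual[[m]]
      data.frame(year = br$annual$year, metric = m, delta = sv - bv,
                 rel_reduction = ifelse(is.finite(bv) & bv != 0,
                                        (bv - sv) / bv, NA_real_))
    }))
  }
  per_rep <- Map(pair_delta, b, s)
  stacked <- do.call(rbind, per_rep)
  agg <- aggregate(cbind(delta, rel_reduction) ~ year + metric, stacked,
                   mean, na.action = stats::na.pass, na.rm = TRUE)
  if (length(per_rep) > 1) {
    qs <- aggregate(delta ~ year + metric, stacked, function(v)
      quantile(v, probs = probs, na.rm = TRUE, names = FALSE),
      na.action = stats::na.pass)
    agg$delta_lo <- qs$delta[, 1]
    agg$delta_hi <- qs$delta[, 2]
  }
  agg[order(agg$metric, agg$year), ]
}
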