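## Latent metabolic model: insulin sensitivity, beta-cell function, glycemic
## index, exposure accumulation, and continuous BMI dynamics.

#' Physiology parameter set
#'
#' Collects the parameters of the latent metabolic model. All rates are per
#' year unless stated otherwise.
#'
#' @param bmi_ref reference BMI at which the BMI penalty on insulin
#'   sensitivity is zero (units of BMI).
#' @param k_bmi exponential decay of insulin sensitivity per BMI unit above
#'   `bmi_ref`.
#' @param s_min floor on insulin sensitivity, in (0,1).
#' @param rho_preg maximal fractional reduction of insulin sensitivity
#'   reached at term (week 40) of pregnancy, in [0,1).
#' @param g_thr glycemic-index threshold above which dysglycemia exposure
#'   accumulates.
#' @param g_igr threshold for impaired glucose regulation.
#' @param g_dm threshold for diabetes (inclusive).
#' @param g_gdm default pregnancy diagnostic threshold; runs normally take
#'   the threshold from the calendar-year diagnostic schedule instead.
#' @param g_max cap on the glycemic index returned when beta-cell function
#'   collapses towards zero.
#' @param k_decay beta-cell loss rate per unit of supra-threshold glycemic
#'   index per year.
#' @param r_regen beta-cell regeneration rate per year, active only while
#'   cumulative exposure is below `e_rev`.
#' @param e_rev reversibility ceiling on cumulative dysglycemia exposure
#'   (index-years): beyond it, regeneration stops and beta-cell loss is
#'   effectively irreversible.
#' @param bmi_secular secular BMI trend, units/year (a headline calibration
#'   parameter).
#' @param bmi_drift_age data.frame (`age`, `rate`) giving the age-specific
#'   BMI drift spline, units/year; interpolated linearly, constant beyond
#'   the ends.
#' @param childhood_rate BMI drift for agents under 15, units/year (scaled
#'   by the in-utero endowment multiplier).
#' @param bmi_noise_sd standard deviation of annual BMI noise
#'   (units/sqrt(year)).
#' @param gwg_mean,gwg_sd gestational weight gain, kg.
#' @param retention_frac fraction of gestational weight gain retained
#'   postpartum, in [0,1].
#' @param phenotype_mix probabilities of the RESISTANCE / SECRETION / MIXED
#'   aetiological phenotypes (must sum to 1).
#' @param base_high,base_high_sd mean and sd of the unaffected baseline
#'   (s_base or b_base) for a phenotype that does not load on that axis.
#' @param base_low,base_low_sd mean and sd of the lowered baseline on the
#'   phenotype's driving axis.
#' @param base_mixed,base_mixed_sd mean and sd of both baselines for the
#'   MIXED phenotype.
#' @return a list of class `physiology_params`.
#' @export
physiology_params <- function(bmi_ref = 25, k_bmi = 0.05, s_min = 0.1,
                              rho_preg = 0.5, g_thr = 1.5, g_igr = 1.5,
                              g_dm = 2.0, g_gdm = 1.3, g_max = 10,
                              k_decay = 0.2, r_regen = 0.05, e_rev = 1.0,
                              bmi_secular = 0.05,
                              bmi_drift_age = NULL, childhood_rate = 0.5,
                              bmi_noise_sd = 0.25,
                              gwg_mean = 12, gwg_sd = 3,
                              retention_frac = 0.3,
                              phenotype_mix = c(1, 1, 1) / 3,
                              base_high = 0.97, base_high_sd = 0.02,
                              base_low = 0.85, base_low_sd = 0.05,
                              base_mixed = 0.90, base_mixed_sd = 0.04) {
  p <- as.list(environment())
  p$bmi_drift_age <- bmi_drift_age %||% data.frame(
    age = c(15, 25, 35, 45, 55, 65, 80),
    rate = c(0.15, 0.10, 0.06, 0.03, 0.00, -0.05, -0.10)
  )
  validate_physiology(p)
  structure(p, class = c("physiology_params", "list"))
}

validate_physiology <- function(p) {
  rates <- c("k_bmi", "k_decay", "r_regen", "e_rev", "childhood_rate",
             "bmi_noise_sd", "gwg_mean", "gwg_sd")
  for (nm in rates)
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  if (!(p$g_igr > 1 && p$g_igr <= p$g_dm))
    stop("thresholds must satisfy 1 < g_igr <= g_dm", call. = FALSE)
  if (!(p$s_min > 0 && p$s_min < 1)) stop("s_min must lie in (0,1)", call. = FALSE)
  if (!(p$rho_preg >= 0 && p$rho_preg < 1))
    stop("rho_preg must lie in [0,1)", call. = FALSE)
  if (!(p$retention_frac >= 0 && p$retention_frac <= 1))
    stop("retention_frac must lie in [0,1]", call. = FALSE)
  if (abs(sum(p$phenotype_mix) - 1) > 1e-9)
    stop("phenotype_mix must sum to 1", call. = FALSE)
  invisible(p)
}

PHENOTYPES <- c("RESISTANCE", "SECRETION", "MIXED")

#' Assign aetiological phenotypes and metabolic baselines
#'
#' Three routes into gestational dysglycemia are represented: a
#' resistance-driven phenotype (lowered baseline insulin sensitivity), a
#' secretion-driven phenotype (lowered baseline beta-cell function), and a
#' mixed phenotype with both moderately lowered.
#'
#' @param n number of agents.
#' @param params a [physiology_params()] object (supplies the mixture and
#'   baseline distributions).
#' @param mix optional override of the phenotype mixture proportions
#'   (RESISTANCE, SECRETION, MIXED); must sum to 1.
#' @param seed integer seed; identical seeds give identical assignments.
#' @return data.frame with columns `phenotype` (character), `s_base`,
#'   `b_base`, all baselines clamped to (0.3, 1].
#' @export
assign_phenotype <- function(n, params = physiology_params(), mix = NULL,
                             seed = 1L) {
  mix <- mix %||% params$phenotype_mix
  if (abs(sum(mix) - 1) > 1e-9)
    stop("phenotype mixture proportions must sum to 1", call. = FALSE)
  d <- phenotype_draw(n, params, mix, seed)
  data.frame(phenotype = d$phenotype, s_base = d$s_base, b_base = d$b_base)
}

## list-returning kernel used by the engine (no data.frame overhead)
phenotype_draw <- function(n, params, mix = NULL, seed = 1L) {
  mix <- mix %||% params$phenotype_mix
  if (n == 0L)
    return(list(phenotype = character(0), s_base = numeric(0),
                b_base = numeric(0)))
  set.seed(seed)
  u <- runif(n)
  ph <- PHENOTYPES[findInterval(u, cumsum(mix), left.open = TRUE) + 1L]
  zs <- rnorm(n)
  zb <- rnorm(n)
  mean_s <- rep(params$base_high, n); sd_s <- rep(params$base_high_sd, n)
  mean_b <- mean_s; sd_b <- sd_s
  i <- ph == "RESISTANCE"
  mean_s[i] <- params$base_low; sd_s[i] <- params$base_low_sd
  i <- ph == "SECRETION"
  mean_b[i] <- params$base_low; sd_b[i] <- params$base_low_sd
  i <- ph == "MIXED"
  mean_s[i] <- params$base_mixed; sd_s[i] <- params$base_mixed_sd
  mean_b[i] <- params$base_mixed; sd_b[i] <- params$base_mixed_sd
  list(phenotype = ph,
       s_base = clamp(mean_s + sd_s * zs, 0.3, 1),
       b_base = clamp(mean_b + sd_b * zb, 0.3, 1))
}

#' Insulin sensitivity from BMI, pregnancy stage and individual baseline
#'
#' S = clamp(s_base * exp(-k_bmi * max(0, bmi - bmi_ref)) * preg_mult,
#' s_min, 1), where the pregnancy multiplier ramps linearly from 1 at
#' conception to `1 - rho_preg` at week 40, capturing the physiological
#' insulin resistance of late pregnancy. Non-increasing in BMI above the
#' reference point.
#'
#' @param bmi body-mass index, > 0 (vectorised).
#' @param gestational_week week of pregnancy in [0, 40], or `NA` when not
#'   pregnant.
#' @param s_base individual baseline sensitivity (from the phenotype draw,
#'   possibly scaled by an intervention's activity channel).
#' @param params a [physiology_params()] object.
#' @return insulin sensitivity in `[s_min, 1]`.
#' @examples
#' insulin_sensitivity(35, NA, 1)        # exp(-0.5)
#' insulin_sensitivity(25, 28, 1)        # 1 - 0.5 * 28/40
#' @export
insulin_sensitivity <- function(bmi, gestational_week = NA, s_base = 1,
                                params = physiology_params()) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0", call. = FALSE)
  n <- max(length(bmi), length(gestational_week), length(s_base))
  gw <- rep_len(gestational_week, n)
  preg_mult <- rep(1, n)
  i <- which(!is.na(gw))
  preg_mult[i] <- 1 - params$rho_preg * pmin(40, gw[i]) / 40
  clamp(rep_len(s_base, n) *
          exp(-params$k_bmi * pmax(0, rep_len(bmi, n) - params$bmi_ref)) *
          preg_mult,
        params$s_min, 1)
}

#' Glycemic index from sensitivity and beta-cell function
#'
#' G = 1 / (S * B), normalised so that full sensitivity and full beta-cell
#' function give G = 1. When beta-cell function collapses to zero the index
#' is capped at `g_max` rather than diverging.
#'
#' @param S insulin sensitivity in (0, 1].
#' @param B beta-cell function in [0, 1].
#' @param g_max cap applied as B approaches 0.
#' @return glycemic index, >= 1 whenever S, B <= 1, capped at `g_max`.
#' @export
glycemic_index <- function(S, B, g_max = 10) {
  if (any(S <= 0, na.rm = TRUE)) stop("S must be > 0", call. = FALSE)
  ## B at (or below) zero runs into the cap rather than dividing by zero
  pmin(1 / (S * pmax(B, 1e-12)), g_max)
}

#' One Euler step of the exposure / beta-cell dynamics
#'
#' Supra-threshold glycemia `y = max(0, G - g_thr)` accumulates into the
#' exposure integral E (which never decreases) and erodes beta-cell function
#' at rate `k_decay * y * B`. Regeneration at rate `r_regen * (1 - B)`
#' operates only while `E < e_rev`: once cumulative exposure passes the
#' reversibility ceiling, lost beta-cell function can no longer be rebuilt,
#' which is what makes late intervention less effective than early
#' intervention.
#'
#' @param B beta-cell function in [0, 1] (vectorised).
#' @param E cumulative dysglycemia exposure, index-years.
#' @param G current glycemic index.
#' @param dt step in years, > 0.
#' @param params a [physiology_params()] object.
#' @return list with updated `B` (clamped to [0,1]) and `E`.
#' @export
step_metabolism <- function(B, E, G, dt, params = physiology_params()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  y <- pmax(0, G - params$g_thr)
  E2 <- E + y * dt
  dB <- (params$r_regen * (1 - B) * (E < params$e_rev) -
           params$k_decay * y * B) * dt
  list(B = clamp(B + dB, 0, 1), E = E2)
}

#' Convert a weight change in kilograms to BMI units
#'
#' dBMI = kg / height^2; a 5 kg loss at typical adult heights is one to two
#' BMI units.
#'
#' @param weight_change_kg weight change in kg (signed).
#' @param height_m height in metres, > 0.
#' @return change in BMI units.
#' @examples
#' delta_bmi(-5, 1.65)
#' @export
delta_bmi <- function(weight_change_kg, height_m) {
  if (any(height_m <= 0, na.rm = TRUE))
    stop("height must be > 0", call. = FALSE)
  weight_change_kg / height_m^2
}

make_drift_fun <- function(params) {
  tab <- params$bmi_drift_age
  approxfun(tab$age, tab$rate, rule = 2)
}

#' One step of continuous BMI dynamics
#'
#' bmi' = bmi + (age drift + secular trend) * dt + noise, with an optional
#' postpartum weight-retention increment `retention_frac * gwg_kg / height^2`
#' applied on a delivery event. Children (under 15) follow a constant
#' childhood drift scaled by the in-utero endowment multiplier instead of
#' the adult spline; the calendar-anchored secular trend applies at every
#' age, so later cohorts are heavier at the same age.
#'
#' @param bmi current BMI, > 0 (vectorised).
#' @param age age in years.
#' @param dt step in years, > 0.
#' @param params a [physiology_params()] object.
#' @param noise additive BMI noise for this step (already scaled; default 0).
#' @param delivery_kg gestational weight gain (kg) retained at a delivery
#'   happening this step, 0 otherwise.
#' @param height_m height in metres (needed when `delivery_kg` != 0).
#' @param drift_mult multiplier on the age drift (in-utero endowment channel).
#' @return updated BMI, floored at 12.
#' @export
bmi_step <- function(bmi, age, dt, params = physiology_params(), noise = 0,
                     delivery_kg = 0, height_m = NULL, drift_mult = 1) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  drift_fun <- make_drift_fun(params)
  adult <- age >= 15
  drift <- ifelse(adult, drift_fun(age), params$childhood_rate) * drift_mult
  out <- bmi + (drift + params$bmi_secular) * dt + noise
  if (any(delivery_kg != 0)) {
    if (is.null(height_m)) stop("height_m needed for a delivery step",
                                call. = FALSE)
    out <- out + params$retention_frac * delta_bmi(delivery_kg, height_m)
  }
  pmax(out, 12)
}

#' Classify glycemic state, with a pregnancy diagnostic flag
#'
#' NORMAL below `g_igr`, IMPAIRED from `g_igr` up to (exclusive) `g_dm`,
#' DIABETES at or above `g_dm` (upper states inclusive at their lower
#' boundary). When pregnant, a separate DIP-positive flag compares G against
#' the diagnostic threshold in force, which may change with calendar year —
#' the mechanism behind artefactual steps in recorded incidence.
#'
#' @param G glycemic index, >= 0 (vectorised).
#' @param pregnant logical.
#' @param diagnostic_threshold pregnancy diagnostic threshold on G.
#' @param params a [physiology_params()] object.
#' @return data.frame with `state` (character) and `dip_positive` (logical,
#'   `NA` when not pregnant).
#' @export
classify_glycemic <- function(G, pregnant = FALSE,
                              diagnostic_threshold = NULL,
                              params = physiology_params()) {
  if (any(G < 0, na.rm = TRUE)) stop("G must be >= 0", call. = FALSE)
  thr <- diagnostic_threshold %||% params$g_gdm
  state <- ifelse(G >= params$g_dm, "DIABETES",
                  ifelse(G >= params$g_igr, "IMPAIRED", "NORMAL"))
  dip <- ifelse(rep_len(pregnant, length(G)), G >= thr, NA)
  data.frame(state = state, dip_positive = dip)
}
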