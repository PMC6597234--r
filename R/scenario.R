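## Scenario configuration: defaults, YAML round-trip, validation.

#' Default scenario configuration
#'
#' Returns the full experiment definition as a nested list. The defaults
#' describe a desk-scale jurisdictional experiment: 10,000 women with 20%
#' in the high-risk-ethnicity group, a 29-year horizon starting in 1988
#' with a 20-year burn-in (so reporting covers 2008-2016), universal
#' screening at week 26 with 95% participation, and a diagnostic-standard
#' change in 2014.
#'
#' @param ... named overrides merged into the defaults (top level only;
#'   supply whole sub-lists to replace them).
#' @return nested list of class `dip_scenario`.
#' @export
default_scenario <- function(...) {
  cfg <- list(
    population = list(
      n = 10000,
      frac_high_risk = 0.2,
      table = NULL,                 # optional explicit PopulationTable
      family_history_prev = 0.15,
      height_mean = 1.65,
      height_sd = 0.07,
      weight_init = default_weight_init()
    ),
    simulation = list(
      calendar_start_year = 1988,
      horizon_years = 29,
      burn_in_years = 20,
      dt_months = 1,
      seed = 1,
      bud_scope = "all_reproductive",   # or "high_risk_only"
      female_fraction = 0.493,
      postpartum_weeks = 26
    ),
    etiology = "mechanistic",           # or "risk_count"
    physiology = unclass(physiology_params()),
    fertility = default_fertility(),
    mortality = list(exit_rate = default_exit_rates()),
    screening = unclass(screening_policy()),
    diagnostics = list(years = c(1988, 2014), thresholds = c(4.2, 2.8)),
    treatment = list(m_full = 0.8, ramp_weeks = 4, pharmaco_g = 2.6),
    outcomes = list(p_min = 0.05, p_max = 0.45, k = 4, g_mid = 1.8),
    endowment = list(b_base_mult = 0.9, drift_mult = 1.3),
    risk_count = list(p0 = 0.03, beta = 0.04),
    costs = as.list(default_unit_costs()),
    interventions = list()
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- c("dip_scenario", "list")
  cfg
}

#' Validate a scenario configuration
#'
#' Checks structural and numeric constraints and returns the (normalised)
#' configuration; all violations found are reported together.
#'
#' @param config scenario list as from [default_scenario()] or
#'   [load_scenario()].
#' @return the validated configuration, invisibly classed `dip_scenario`.
#' @export
validate_scenario <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  sim <- config$simulation
  if (is.null(sim)) push("missing `simulation` section")
  else {
    if (!isTRUE(sim$horizon_years > 0)) push("horizon_years must be > 0")
    if (!isTRUE(sim$burn_in_years >= 0)) push("burn_in_years must be >= 0")
    if (!isTRUE(sim$burn_in_years < sim$horizon_years))
      push("burn_in_years must be smaller than horizon_years")
    if (!isTRUE(sim$dt_months %in% c(1, 2, 3, 4, 6, 12)))
      push("dt_months must divide a year (1, 2, 3, 4, 6 or 12)")
    if (!isTRUE(sim$bud_scope %in% c("all_reproductive", "high_risk_only")))
      push("bud_scope must be 'all_reproductive' or 'high_risk_only'")
  }
  if (!isTRUE(config$etiology %in% c("mechanistic", "risk_count")))
    push("etiology must be 'mechanistic' or 'risk_count'")
  phys <- try(do.call(physiology_params,
                      config$physiology[names(config$physiology) %in%
                                          names(formals(physiology_params))]),
              silent = TRUE)
  if (inherits(phys, "try-error"))
    push(paste0("physiology: ", conditionMessage(attr(phys, "condition"))))
  else config$physiology <- unclass(phys)
  pol <- try(do.call(screening_policy,
                     config$screening[c("mode", "universal_week",
                                        "early_week", "participation")]),
             silent = TRUE)
  if (inherits(pol, "try-error"))
    push(paste0("screening: ", conditionMessage(attr(pol, "condition"))))
  sch <- try(diagnostic_schedule(config$diagnostics$years,
                                 config$diagnostics$thresholds),
             silent = TRUE)
  if (inherits(sch, "try-error"))
    push(paste0("diagnostics: ", conditionMessage(attr(sch, "condition"))))
  if (!is.null(config$population$table)) {
    ok <- try(validate_population(config$population$table), silent = TRUE)
    if (inherits(ok, "try-error"))
      push(paste0("population: ", conditionMessage(attr(ok, "condition"))))
  } else if (!isTRUE(config$population$n > 0)) {
    push("population n must be > 0")
  }
  ivs <- try(lapply(config$interventions, as_intervention_spec), silent = TRUE)
  if (inherits(ivs, "try-error"))
    push(paste0("interventions: ", conditionMessage(attr(ivs, "condition"))))
  if (length(errs))
    stop("invalid scenario configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  class(config) <- c("dip_scenario", "list")
  invisible(config)
}

#' Load / save a scenario configuration as YAML
#'
#' @param path YAML file path (JSON is valid YAML and is accepted).
#' @return `load_scenario` returns a validated scenario list; values absent
#'   from the file take their defaults.
#' @export
load_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_scenario()
  cfg <- merge_config(cfg, raw)
  ## data.frame-ish sections come back from YAML as lists of columns
  for (nm in c("fertility")) {
    if (!is.data.frame(cfg[[nm]])) cfg[[nm]] <- as.data.frame(cfg[[nm]])
  }
  if (!is.data.frame(cfg$physiology$bmi_drift_age))
    cfg$physiology$bmi_drift_age <- as.data.frame(cfg$physiology$bmi_drift_age)
  wi <- cfg$population$weight_init
  for (nm in c("standard", "high_risk_ethnicity"))
    if (!is.matrix(wi[[nm]])) wi[[nm]] <- do.call(rbind, wi[[nm]])
  wi$age_breaks <- as.numeric(unlist(wi$age_breaks))
  cfg$population$weight_init <- wi
  if (!is.null(cfg$population$table) && !is.data.frame(cfg$population$table))
    cfg$population$table <- as.data.frame(cfg$population$table)
  validate_scenario(cfg)
}

merge_config <- function(base, override) {
  if (!is.list(override)) return(override)
  if (!is.list(base) || is.data.frame(base) || is.null(names(override)))
    return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (nm %in% names(base) && !is.null(base[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' @rdname load_scenario
#' @param config scenario list.
#' @export
write_scenario <- function(config, path) {
  ser <- rapply(unclass(config), f = function(x) x, how = "replace")
  yaml::write_yaml(serialize_config(config), path, precision = 15)
  invisible(path)
}

serialize_config <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) unname(x[i, ])))
  if (is.list(x)) return(lapply(unclass(x), serialize_config))
  if (is.null(x)) return(NULL)
  unname(x)
}
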