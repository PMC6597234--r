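## Discrete-event screening, diagnosis and treatment pathways.

#' Screening policy definition
#'
#' @param mode `"universal"` (routine test for every pregnancy) or
#'   `"selective"` (routine test plus an early test for women meeting the
#'   high-risk definition).
#' @param universal_week gestational week of the routine test (default 26).
#' @param early_week gestational week of the early high-risk test
#'   (default 12).
#' @param participation probability of attending any scheduled test,
#'   in [0, 1].
#' @return list of class `screening_policy`.
#' @export
screening_policy <- function(mode = c("universal", "selective"),
                             universal_week = 26, early_week = 12,
                             participation = 0.95) {
  if (!is.character(mode) || !mode[1] %in% c("universal", "selective"))
    stop("unknown screening mode: ", mode[1], call. = FALSE)
  mode <- mode[1]
  stopifnot(universal_week >= 0, universal_week <= 40,
            early_week >= 0, early_week <= 40,
            participation >= 0, participation <= 1)
  structure(list(mode = mode, universal_week = universal_week,
                 early_week = early_week, participation = participation),
            class = c("screening_policy", "list"))
}

#' Schedule screening tests for a newly pregnant woman
#'
#' Universal mode schedules one oral glucose tolerance test (OGTT) at the
#' routine week; selective mode adds an early screen at `early_week` when the
#' woman meets the high-risk definition. Each scheduled event is retained
#' with probability `participation`, using the supplied uniform draws so the
#' caller controls the random stream.
#'
#' @param high_risk logical: does the woman meet [adips_high_risk()]?
#' @param policy a [screening_policy()].
#' @param u_early,u_universal uniform(0,1) draws deciding attendance (default
#'   0 = always attend).
#' @return data.frame of scheduled events with columns `kind`
#'   (`"early_screen"` / `"ogtt"`) and `week`, possibly empty.
#' @export
schedule_screening <- function(high_risk, policy, u_early = 0,
                               u_universal = 0) {
  if (!inherits(policy, "screening_policy")) policy <- do.call(screening_policy, policy)
  kinds <- character(0); weeks <- numeric(0)
  if (policy$mode == "selective" && isTRUE(high_risk) &&
      u_early < policy$participation) {
    kinds <- c(kinds, "early_screen"); weeks <- c(weeks, policy$early_week)
  }
  if (u_universal < policy$participation) {
    kinds <- c(kinds, "ogtt"); weeks <- c(weeks, policy$universal_week)
  }
  data.frame(kind = kinds, week = weeks)
}

#' Diagnostic-threshold schedule
#'
#' A piecewise-constant schedule of pregnancy diagnostic thresholds on the
#' glycemic index, keyed by the first calendar year each threshold is in
#' force. Changes to the diagnostic standard enter the model here and
#' produce artefactual steps in recorded incidence with no change in the
#' underlying physiology.
#'
#' @param years integer vector, strictly increasing.
#' @param thresholds thresholds on G, all > 1, same length as `years`.
#' @return list of class `diagnostic_schedule`.
#' @export
diagnostic_schedule <- function(years, thresholds) {
  stopifnot(length(years) == length(thresholds), length(years) >= 1)
  if (is.unsorted(years, strictly = TRUE))
    stop("schedule years must be strictly increasing", call. = FALSE)
  if (any(thresholds <= 1))
    stop("diagnostic thresholds must be > 1", call. = FALSE)
  structure(list(years = as.numeric(years), thresholds = as.numeric(thresholds)),
            class = c("diagnostic_schedule", "list"))
}

#' Diagnostic threshold in force in a calendar year
#' @param schedule a [diagnostic_schedule()].
#' @param year calendar year (vectorised).
#' @export
threshold_in_force <- function(schedule, year) {
  idx <- findInterval(year, schedule$years)
  if (any(idx < 1))
    stop("year ", min(year), " precedes the first schedule entry (",
         schedule$years[1], ")", call. = FALSE)
  schedule$thresholds[idx]
}

#' Oral glucose tolerance test result
#'
#' Deterministic threshold test on the latent glycemic index: positive if and
#' only if G is at or above the threshold in force in `year` (boundary
#' inclusive). No assay noise by default.
#'
#' @param G glycemic index at the test (vectorised).
#' @param year calendar year of the test.
#' @param schedule a [diagnostic_schedule()].
#' @return logical vector, `TRUE` = positive.
#' @export
ogtt_result <- function(G, year, schedule) {
  G >= threshold_in_force(schedule, year)
}

#' Treatment effect on the glycemic index
#'
#' After diagnosis, treatment (lifestyle advice, escalating to
#' pharmacotherapy) multiplies the glycemic index during pregnancy. The
#' multiplier ramps linearly from 1 at diagnosis to the floor `m_full` by
#' `ramp_weeks`, then stays constant until delivery.
#'
#' @param weeks_since_diagnosis weeks, >= 0 (vectorised).
#' @param m_full full-effect multiplier in (0, 1].
#' @param ramp_weeks weeks to reach full effect (default 4).
#' @return multiplier in `[m_full, 1]`.
#' @export
treatment_effect <- function(weeks_since_diagnosis, m_full = 0.8,
                             ramp_weeks = 4) {
  if (any(weeks_since_diagnosis < 0, na.rm = TRUE))
    stop("weeks_since_diagnosis must be >= 0", call. = FALSE)
  frac <- pmin(1, weeks_since_diagnosis / ramp_weeks)
  1 - (1 - m_full) * frac
}

#' Default unit costs per service event kind
#' @export
default_unit_costs <- function() {
  c(booking = 40, early_screen = 60, ogtt = 60, diagnosis = 0,
    lifestyle_rx = 250, pharmaco_rx = 400, delivery_care = 3000,
    postpartum_test = 60)
}

#' Tally service events against a unit-cost table
#'
#' Counts events by kind and multiplies by unit costs. An event kind missing
#' from the cost table is still counted but its cost is flagged unknown
#' (`NA`). Tallies are additive over concatenated logs.
#'
#' @param events event-log data.frame with a `kind` column (may be empty).
#' @param unit_costs named numeric vector of costs per event kind.
#' @return data.frame with `kind`, `count`, `unit_cost`, `cost`, plus a
#'   `"total"` row summing the known costs.
#' @export
tally_services <- function(events, unit_costs = default_unit_costs()) {
  service_kinds <- union(names(unit_costs),
                         if (nrow(events)) unique(events$kind) else character(0))
  counts <- vapply(service_kinds,
                   function(k) if (nrow(events)) sum(events$kind == k) else 0L,
                   numeric(1))
  uc <- unit_costs[service_kinds]
  names(uc) <- service_kinds
  out <- data.frame(kind = service_kinds, count = as.numeric(counts),
                    unit_cost = as.numeric(uc),
                    cost = as.numeric(uc) * as.numeric(counts),
                    row.names = NULL)
  total <- sum(out$cost, na.rm = TRUE)
  rbind(out, data.frame(kind = "total", count = sum(out$count),
                        unit_cost = NA_real_, cost = total))
}
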