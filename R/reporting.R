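## Reporting: annual summaries recomputed from the event log, agent
## "life story" narratives, and file outputs.

#' Recompute the annual output series from an event log
#'
#' The event log is the single source of truth for event-derived statistics:
#' this function rebuilds, per calendar year, births (deliveries), DIP
#' diagnoses, the DIP fraction with subgroup splits (high-risk ethnicity vs
#' standard; mothers under vs over 35), and adverse-outcome counts. Weight
#' category proportions come from the population snapshots when supplied
#' (they are state, not events).
#'
#' @param events event-log data.frame/data.table as in `dip_run$events`.
#' @param snapshots optional `dip_run$snapshots` for weight proportions.
#' @param years calendar years to report; defaults to every year with a
#'   delivery in the log.
#' @return data.frame, one row per year.
#' @export
annual_summary <- function(events, snapshots = NULL, years = NULL) {
  events <- as.data.frame(events)
  yr_ev <- floor(events$time)
  years <- years %||% sort(unique(yr_ev[events$kind == "delivery_care"]))
  count <- function(keep) vapply(years, function(y)
    sum(keep & yr_ev == y), numeric(1))
  del <- events$kind == "delivery_care"
  dig <- events$kind == "diagnosis"
  hr <- events$high_risk %in% TRUE
  a35 <- !is.na(events$age) & events$age >= 35
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  b <- count(del); d <- count(dig)
  b_hr <- count(del & hr); d_hr <- count(dig & hr)
  b_35 <- count(del & a35); d_35 <- count(dig & a35)
  out <- data.frame(
    year = years,
    births = b,
    dip_diagnoses = d,
    dip_frac = frac(d, b),
    dip_frac_high_risk = frac(d_hr, b_hr),
    dip_frac_standard = frac(d - d_hr, b - b_hr),
    dip_frac_under35 = frac(d - d_35, b - b_35),
    dip_frac_35plus = frac(d_35, b_35),
    adverse = count(events$kind == "adverse_outcome")
  )
  if (!is.null(snapshots)) {
    idx <- match(years, snapshots$year)
    out$prop_healthy <- snapshots$weight[idx, "healthy"]
    out$prop_overweight <- snapshots$weight[idx, "overweight"]
    out$prop_obese <- snapshots$weight[idx, "obese"]
  }
  out
}

load_story_templates <- function(path = NULL) {
  path <- path %||% system.file("templates", "life_story_templates.yaml",
                                package = "dipsim")
  yaml::read_yaml(path)
}

fill_template <- function(tpl, row) {
  fields <- c(age = "age", year = "year", week = "week", value = "value",
              threshold = "threshold", detail = "detail")
  out <- tpl
  for (nm in names(fields)) {
    v <- row[[fields[[nm]]]]
    v <- if (is.null(v) || is.na(v)) "?" else if (is.numeric(v))
      format(round(v, 2)) else as.character(v)
    out <- gsub(paste0("{", nm, "}"), v, out, fixed = TRUE)
  }
  out
}

#' Render an agent's life story
#'
#' Turns every logged event of one agent into a chronological narrative
#' line carrying the agent's age and the calendar year — the "case history"
#' format used to communicate individual trajectories to non-technical
#' audiences. Rendering is lossless: one line per logged event, in time
#' order.
#'
#' @param agent_id agent identifier.
#' @param events event log (`dip_run$events`).
#' @param templates named list of narrative templates by event kind; default
#'   loaded from the package's editable template file.
#' @return object of class `dip_life_story`: data.frame with `time`, `age`,
#'   `year`, `kind`, `text`.
#' @export
render_life_story <- function(agent_id, events,
                              templates = load_story_templates()) {
  events <- as.data.frame(events)
  mine <- events[events$agent_id == agent_id, , drop = FALSE]
  if (nrow(mine) == 0L)
    stop("agent ", agent_id, " does not appear in the event log",
         call. = FALSE)
  mine <- mine[order(mine$time, mine$kind), , drop = FALSE]
  mine$year <- floor(mine$time)
  mine$age <- ifelse(is.na(mine$age), NA, floor(mine$age))
  text <- vapply(seq_len(nrow(mine)), function(i) {
    row <- as.list(mine[i, ])
    tpl <- templates[[row$kind]] %||% paste0("At age {age} ({year}): ",
                                             row$kind, ".")
    fill_template(tpl, row)
  }, character(1))
  structure(data.frame(time = mine$time, age = mine$age, year = mine$year,
                       kind = mine$kind, text = text),
            class = c("dip_life_story", "data.frame"),
            agent_id = agent_id)
}

#' @export
print.dip_life_story <- function(x, ...) {
  cat("Life story of agent", attr(x, "agent_id"), "\n")
  for (line in x$text) cat(" -", line, "\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes `annual.csv` (tidy long format: year, metric, value),
#' `events.jsonl` (one JSON event per line), `config_echo.yaml` and
#' `report.json` (seed, runtime, headline series). Refuses to overwrite an
#' existing result directory unless `force`.
#'
#' @param result a `dip_run`.
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing outputs.
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir, force = FALSE) {
  marker <- file.path(out_dir, "report.json")
  if (file.exists(marker) && !force)
    stop("output directory ", out_dir,
         " already holds results; use force = TRUE to overwrite",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(
    setdiff(names(result$annual), "year"),
    function(m) data.frame(year = result$annual$year, metric = m,
                           value = result$annual[[m]])))
  write.csv(long, file.path(out_dir, "annual.csv"), row.names = FALSE)
  if (!is.null(result$events)) {
    con <- file(file.path(out_dir, "events.jsonl"), "w")
    jsonlite::stream_out(as.data.frame(result$events), con, verbose = FALSE)
    close(con)
  }
  write_scenario(result$config, file.path(out_dir, "config_echo.yaml"))
  jsonlite::write_json(
    list(seed = result$seed, runtime_s = result$runtime_s,
         agents_final = result$agents_final,
         years = result$annual$year,
         dip_percent = round(100 * result$annual$dip_frac, 3)),
    marker, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Read back the annual series written by [write_outputs()]
#'
#' @param out_dir directory written by [write_outputs()].
#' @return wide data.frame equal to the `annual` component of the run.
#' @export
read_annual <- function(out_dir) {
  long <- read.csv(file.path(out_dir, "annual.csv"))
  wide <- stats::reshape(long, idvar = "year", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
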