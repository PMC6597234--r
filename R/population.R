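## Aggregate population: stock-and-flow ageing chain and agent budding.

#' Five-year age bands used by the ageing chain
#' @export
AGE_BANDS <- c(
  "0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34", "35-39",
  "40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74", "75-79",
  "80-84", "85+"
)

#' Risk-group labels for the population stratification
#' @export
RISK_GROUPS <- c("standard", "high_risk_ethnicity")

band_lower <- function() seq(0, 85, by = 5)

band_of_age <- function(age) {
  pmin(length(AGE_BANDS), floor(age / 5) + 1L)
}

default_age_weights <- function() {
  ## stylised female age structure of a developed jurisdiction: broadly flat
  ## through working ages, tapering above 65
  w <- c(6.1, 5.9, 5.8, 5.9, 6.6, 7.2, 7.3, 7.0, 6.6, 6.5, 6.4, 6.1, 5.7,
         5.0, 4.4, 3.4, 2.4, 2.7)
  w / sum(w)
}

default_exit_rates <- function() {
  ## per-capita annual exit (mortality + net out-migration) by band
  c(0.004, 0.002, 0.002, 0.003, 0.004, 0.004, 0.004, 0.004, 0.004, 0.005,
    0.006, 0.009, 0.014, 0.022, 0.036, 0.060, 0.100, 0.180)
}

#' Generate a synthetic stratified female population table
#'
#' Builds a fixture population emulating an age-structured female population
#' stratified by a high-risk-ethnicity flag. Counts are apportioned
#' deterministically (largest-remainder within each risk group) so that the
#' overall total and the high-risk total are met exactly.
#'
#' @param n total number of women.
#' @param frac_high_risk proportion in the high-risk-ethnicity group.
#' @param age_weights optional vector of 18 band weights (normalised
#'   internally); defaults to a stylised jurisdictional age structure.
#' @return a data.frame with columns `age_band`, `risk_group`, `count`.
#' @examples
#' pop <- synthetic_population(10000, 0.2)
#' sum(pop$count)
#' @export
synthetic_population <- function(n = 10000, frac_high_risk = 0.2,
                                 age_weights = NULL) {
  stopifnot(n > 0, frac_high_risk >= 0, frac_high_risk <= 1)
  w <- age_weights %||% default_age_weights()
  stopifnot(length(w) == length(AGE_BANDS), all(w >= 0))
  w <- w / sum(w)
  totals <- c(standard = round(n * (1 - frac_high_risk)),
              high_risk_ethnicity = round(n * frac_high_risk))
  totals[1] <- n - totals[2]
  apportion <- function(total) {
    raw <- total * w
    base <- floor(raw)
    short <- total - sum(base)
    if (short > 0) {
      ord <- order(raw - base, decreasing = TRUE)
      base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
    }
    base
  }
  data.frame(
    age_band = rep(AGE_BANDS, times = 2),
    risk_group = rep(RISK_GROUPS, each = length(AGE_BANDS)),
    count = c(apportion(totals[1]), apportion(totals[2])),
    stringsAsFactors = FALSE
  )
}

#' Read / write a population table as CSV
#'
#' The on-disk format is a plain CSV with header `age_band,risk_group,count`.
#'
#' @param path file path.
#' @return `read_population` returns the validated population data.frame.
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  validate_population(pop)
  pop
}

#' @rdname read_population
#' @param pop population table as from [synthetic_population()].
#' @export
write_population <- function(pop, path) {
  validate_population(pop)
  write.csv(pop, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_population <- function(pop) {
  need <- c("age_band", "risk_group", "count")
  if (!is.data.frame(pop) || nrow(pop) == 0L)
    stop("population table must be a non-empty data.frame", call. = FALSE)
  if (!all(need %in% names(pop)))
    stop("population table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(pop$count) | pop$count < 0)
  if (length(bad))
    stop("negative or non-finite count in population row(s) ",
         paste(bad, collapse = ", "), " (",
         paste(pop$age_band[bad], pop$risk_group[bad], sep = "/",
               collapse = "; "), ")", call. = FALSE)
  unknown <- setdiff(unique(pop$age_band), AGE_BANDS)
  if (length(unknown))
    stop("unknown age band(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(pop$risk_group), RISK_GROUPS)
  if (length(unknown))
    stop("unknown risk group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(pop)
}

#' Initialise the ageing chain from a population table
#'
#' Creates the stock-and-flow ageing chain: one stock of persons per
#' (5-year age band, risk group) cell, linked by ageing flows with a
#' residence time of 5 years per band, plus per-capita exit flows and an
#' entry flow into the first band.
#'
#' @param pop population table (`age_band`, `risk_group`, `count`).
#' @param entry_rate persons/year entering band 0-4, one value per risk
#'   group. Default: the initial band 0-4 stock divided by the residence
#'   time, which holds the youngest stock stationary in the absence of exits.
#' @param exit_rate per-capita annual exit rate, one value per band (recycled
#'   across risk groups). Default: a stylised mortality + out-migration
#'   schedule.
#' @param residence years spent in each band (5).
#' @return an object of class `ageing_chain`.
#' @export
init_stocks <- function(pop, entry_rate = NULL, exit_rate = NULL,
                        residence = 5) {
  validate_population(pop)
  stocks <- matrix(0, nrow = length(AGE_BANDS), ncol = length(RISK_GROUPS),
                   dimnames = list(AGE_BANDS, RISK_GROUPS))
  for (i in seq_len(nrow(pop))) {
    stocks[pop$age_band[i], pop$risk_group[i]] <-
      stocks[pop$age_band[i], pop$risk_group[i]] + pop$count[i]
  }
  exit_rate <- exit_rate %||% default_exit_rates()
  stopifnot(length(exit_rate) == length(AGE_BANDS), all(exit_rate >= 0))
  entry_rate <- entry_rate %||% (stocks[1, ] / residence)
  stopifnot(length(entry_rate) == length(RISK_GROUPS), all(entry_rate >= 0))
  structure(
    list(stocks = stocks, entry_rate = entry_rate, exit_rate = exit_rate,
         residence = residence,
         cumulative_entries = 0, cumulative_exits = 0, agents_created = 0),
    class = "ageing_chain"
  )
}

#' @export
print.ageing_chain <- function(x, ...) {
  cat("<ageing_chain> ", format(round(chain_total(x))), " persons (",
      format(round(sum(x$stocks[, 2]))), " high-risk ethnicity)\n", sep = "")
  invisible(x)
}

#' Total persons currently held in the chain stocks
#' @param chain an `ageing_chain`.
#' @export
chain_total <- function(chain) sum(chain$stocks)

#' Advance the ageing chain by one time step
#'
#' Each cell loses `stock / residence * dt` persons to the next band and
#' `stock * exit_rate * dt` to exits; entries are added to band 0-4. When the
#' requested outflow would exceed the available stock, both flows are rescaled
#' proportionally so no stock goes negative. The terminal band (85+) has no
#' ageing outflow.
#'
#' The realised flows are attached as `attr(, "flows")` (matrices `aging`,
#' `exits` and the `entries` vector) so callers can redirect an ageing flow
#' into agent budding.
#'
#' @param chain an `ageing_chain`.
#' @param dt step length in years, > 0.
#' @return the advanced `ageing_chain`.
#' @export
step_chain <- function(chain, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  s <- chain$stocks
  nb <- nrow(s)
  aging_rate <- 1 / chain$residence
  aging <- s * aging_rate * dt
  aging[nb, ] <- 0                      # terminal band
  exits <- s * chain$exit_rate * dt
  out <- aging + exits
  over <- out > s & out > 0
  if (any(over)) {
    scale <- s[over] / out[over]
    aging[over] <- aging[over] * scale
    exits[over] <- exits[over] * scale
  }
  entries <- chain$entry_rate * dt
  s2 <- s - aging - exits
  s2[-1, ] <- s2[-1, ] + aging[-nb, ]
  s2[1, ] <- s2[1, ] + entries
  s2[s2 < 0] <- 0        # guard against -1e-16 from the rescaling arithmetic
  chain$stocks <- s2
  chain$cumulative_entries <- chain$cumulative_entries + sum(entries)
  chain$cumulative_exits <- chain$cumulative_exits + sum(exits)
  attr(chain, "flows") <- list(aging = aging, exits = exits, entries = entries)
  chain
}

#' ADIPS-style high-risk screening predicate
#'
#' Returns whether a woman meets the high-risk definition used for selective
#' early screening: high-risk ethnicity, age at or above `age_cut`, a prior
#' GDM-affected pregnancy, a family history of diabetes, or BMI at or above
#' `bmi_cut`. The criteria set is an editable approximation of the clinical
#' risk-factor list; the predicate is monotone in every argument.
#'
#' @param ethnicity_flag logical, member of a high-risk ethnic group.
#' @param age_years age in years, >= 0.
#' @param prior_gdm logical, GDM in a previous pregnancy.
#' @param family_history logical, family history of diabetes.
#' @param bmi body-mass index, > 0.
#' @param age_cut,bmi_cut thresholds (defaults 40 years, 35 units).
#' @return logical vector.
#' @examples
#' adips_high_risk(FALSE, 41, FALSE, FALSE, 22)
#' @export
adips_high_risk <- function(ethnicity_flag, age_years, prior_gdm,
                            family_history, bmi, age_cut = 40, bmi_cut = 35) {
  if (any(age_years < 0, na.rm = TRUE)) stop("age must be >= 0", call. = FALSE)
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be > 0", call. = FALSE)
  as.logical(ethnicity_flag) | age_years >= age_cut | as.logical(prior_gdm) |
    as.logical(family_history) | bmi >= bmi_cut
}

#' Bud agents out of the ageing chain
#'
#' Converts part of the aggregate stock into individually tracked agents:
#' `n` persons are drawn from the eligible (band, risk group) cells in
#' proportion to their stocks, ages are sampled uniformly within the source
#' band, and the source stocks are decremented by exactly the number of
#' agents created.
#'
#' @param chain an `ageing_chain`.
#' @param n number of agents to bud; `"all"` buds the (floored) entire
#'   eligible stock.
#' @param age_range two-element numeric, eligible band range (default the
#'   reproductive window 15-49).
#' @param risk_groups character subset of [RISK_GROUPS] to bud from.
#' @param seed integer seed for the age/cell sampling.
#' @return list with elements `chain` (decremented), `age` (numeric vector),
#'   `risk_group` (character vector).
#' @export
bud_agents <- function(chain, n, age_range = c(15, 50),
                       risk_groups = RISK_GROUPS, seed = 1L) {
  lo <- band_lower()
  elig_band <- which(lo >= age_range[1] & lo < age_range[2])
  elig_grp <- match(risk_groups, RISK_GROUPS)
  cells <- expand.grid(band = elig_band, grp = elig_grp)
  avail <- chain$stocks[as.matrix(cells)]
  total <- sum(avail)
  if (identical(n, "all")) n <- floor(total)
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (n == 0L)
    return(list(chain = chain, age = numeric(0), risk_group = character(0)))
  if (n > floor(total) + 1e-9)
    stop("requested ", n, " agents but only ", floor(total),
         " persons available in eligible stocks", call. = FALSE)
  set.seed(seed)
  ## integer allocation proportional to stock, largest remainder
  raw <- n * avail / total
  take <- floor(raw)
  short <- n - sum(take)
  if (short > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
  }
  ## never take more than a cell holds
  over <- take > floor(avail)
  while (any(over)) {
    excess <- sum(take[over] - floor(avail[over]))
    take[over] <- floor(avail[over])
    room <- which(take < floor(avail))
    for (j in room) {
      if (excess <= 0) break
      add <- min(excess, floor(avail[j]) - take[j])
      take[j] <- take[j] + add
      excess <- excess - add
    }
    over <- take > floor(avail)
    if (excess > 0 && !length(which(take < floor(avail)))) break
  }
  idx <- rep(seq_len(nrow(cells)), times = take)
  band <- cells$band[idx]
  age <- lo[band] + runif(length(idx)) * 5
  grp <- RISK_GROUPS[cells$grp[idx]]
  chain$stocks[as.matrix(cells)] <- avail - take
  chain$agents_created <- chain$agents_created + sum(take)
  ord <- order(age)
  list(chain = chain, age = age[ord], risk_group = grp[ord])
}
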