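## Hybrid simulation engine: fixed-step monthly updates for the ageing
## chain, metabolism and BMI, interleaved with discrete pregnancy/service
## events processed in (time, agent id, kind) order.
##
## All per-agent state is held in parallel vectors inside an environment so
## the monthly update is a handful of vectorised operations; randomness is
## drawn from substreams keyed by (seed, purpose, step) and indexed by agent
## position, making results independent of collection iteration order and
## giving the common-random-numbers contract across scenario pairs.

SERVICE_KINDS <- c("booking", "early_screen", "ogtt", "diagnosis",
                   "lifestyle_rx", "pharmaco_rx", "delivery_care",
                   "postpartum_test")

## Agent state lives in parallel vectors preallocated to a capacity that
## doubles on demand; slots beyond `n` are inert (alive = FALSE, numeric NA)
## so whole-vector operations remain valid as long as `alive` leads every
## logical conjunction.
AG_NUM <- c("birth_t", "height", "bmi", "s_base", "b_base", "B", "E",
            "preg_t0", "gsum", "gn", "diag_w", "sw_early", "sw_univ",
            "pp_end", "dmult", "ivbmi_prev")
AG_DEFAULT <- list(
  id = NA_integer_, alive = FALSE, phen = NA_character_, preg = 0L,
  rc_pos = FALSE, parity = 0L, prior_gdm = FALSE, fam_hist = FALSE,
  mother = NA_integer_, iud = FALSE, eth = FALSE
)

agents_new <- function(n_iv = 0L, cap = 256L) {
  ag <- new.env(parent = emptyenv())
  for (f in AG_NUM) ag[[f]] <- rep(NA_real_, cap)
  for (f in names(AG_DEFAULT)) ag[[f]] <- rep(AG_DEFAULT[[f]], cap)
  ag$gsum[] <- 0; ag$gn[] <- 0; ag$ivbmi_prev[] <- 0
  ag$iv_offered <- replicate(n_iv, rep(FALSE, cap), simplify = FALSE)
  ag$iv_enrol <- replicate(n_iv, rep(NA_real_, cap), simplify = FALSE)
  ag$n <- 0L
  ag$cap <- cap
  ag
}

agents_grow <- function(ag, need) {
  new_cap <- ag$cap
  while (new_cap < need) new_cap <- new_cap * 2L
  extra <- new_cap - ag$cap
  if (extra == 0L) return(invisible())
  for (f in AG_NUM) ag[[f]] <- c(ag[[f]], rep(NA_real_, extra))
  for (f in names(AG_DEFAULT)) ag[[f]] <- c(ag[[f]], rep(AG_DEFAULT[[f]], extra))
  ag$gsum[(ag$cap + 1L):new_cap] <- 0
  ag$gn[(ag$cap + 1L):new_cap] <- 0
  ag$ivbmi_prev[(ag$cap + 1L):new_cap] <- 0
  for (i in seq_along(ag$iv_offered)) {
    ag$iv_offered[[i]] <- c(ag$iv_offered[[i]], rep(FALSE, extra))
    ag$iv_enrol[[i]] <- c(ag$iv_enrol[[i]], rep(NA_real_, extra))
  }
  ag$cap <- new_cap
  invisible()
}

agents_append <- function(ag, new) {
  n_new <- length(new$birth_t)
  if (n_new == 0L) return(invisible(integer(0)))
  agents_grow(ag, ag$n + n_new)
  at <- ag$n + seq_len(n_new)
  ag$id[at] <- at
  ag$alive[at] <- TRUE
  ag$birth_t[at] <- new$birth_t
  ag$height[at] <- new$height
  ag$bmi[at] <- new$bmi
  ag$eth[at] <- new$eth
  ag$phen[at] <- new$phen
  ag$s_base[at] <- new$s_base
  ag$b_base[at] <- new$b_base
  ag$B[at] <- new$b_base
  ag$E[at] <- 0
  ag$fam_hist[at] <- new$fam_hist
  ag$mother[at] <- new$mother
  ag$iud[at] <- new$iud
  ag$dmult[at] <- new$dmult
  ag$ivbmi_prev[at] <- 0
  ag$n <- ag$n + n_new
  invisible(at)
}

## event accumulator: one list of column vectors appended per batch
ev_new <- function() {
  e <- new.env(parent = emptyenv()); e$chunks <- list(); e$k <- 0L; e
}

ev_add <- function(ev, kind, time, agent_id, week = NA_real_,
                   value = NA_real_, threshold = NA_real_,
                   age = NA_real_, high_risk = NA,
                   detail = NA_character_) {
  n <- length(time)
  if (n == 0L) return(invisible())
  ev$k <- ev$k + 1L
  ev$chunks[[ev$k]] <- list(
    time = as.numeric(time), agent_id = as.integer(agent_id),
    kind = rep_len(kind, n), week = rep_len(as.numeric(week), n),
    value = rep_len(as.numeric(value), n),
    threshold = rep_len(as.numeric(threshold), n),
    age = rep_len(as.numeric(age), n),
    high_risk = rep_len(as.logical(high_risk), n),
    detail = rep_len(as.character(detail), n))
  invisible()
}

ev_collect <- function(ev) {
  if (ev$k == 0L)
    return(data.table::data.table(time = numeric(0), agent_id = integer(0),
                                  kind = character(0), week = numeric(0),
                                  value = numeric(0), threshold = numeric(0),
                                  age = numeric(0), high_risk = logical(0),
                                  detail = character(0)))
  out <- data.table::rbindlist(lapply(ev$chunks[seq_len(ev$k)],
                                      data.table::as.data.table))
  data.table::setorderv(out, c("time", "agent_id", "kind"))
  out[]
}

#' Run a scenario
#'
#' Executes the hybrid simulation: the aggregate ageing chain advances in
#' fixed monthly steps, women entering the reproductive window are budded
#' into agents, agents' latent metabolism and BMI update every step, and
#' pregnancy/screening/treatment milestones fire as discrete events ordered
#' by (time, agent id, kind). Burn-in years are simulated but excluded from
#' the reported annual series. Output is fully determined by
#' (configuration, seed).
#'
#' @param config scenario configuration ([default_scenario()] /
#'   [load_scenario()]).
#' @param seed master seed; defaults to `config$simulation$seed`.
#' @param record_events keep the full event log (disable for speed inside
#'   calibration loops; the annual series is unaffected).
#' @return an object of class `dip_run`: list with `annual` (data.frame of
#'   per-year outputs over the post-burn-in window), `events` (data.table or
#'   `NULL`), `snapshots` (weight-category and age-structure series),
#'   `chain` (final ageing chain), `config`, `seed`, `runtime_s`.
#' @export
run_scenario <- function(config = default_scenario(), seed = NULL,
                         record_events = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  config <- validate_scenario(config)
  sim <- config$simulation
  seed <- as.integer(seed %||% sim$seed %||% 1L)
  phys <- do.call(physiology_params,
                  config$physiology[names(config$physiology) %in%
                                      names(formals(physiology_params))])
  drift_fun <- make_drift_fun(phys)
  fert <- config$fertility
  pol <- do.call(screening_policy,
                 config$screening[c("mode", "universal_week", "early_week",
                                    "participation")])
  sched <- diagnostic_schedule(config$diagnostics$years,
                               config$diagnostics$thresholds)
  ivs <- lapply(config$interventions, as_intervention_spec)
  n_iv <- length(ivs)
  mech <- identical(config$etiology, "mechanistic")
  out_par <- config$outcomes
  endow <- config$endowment
  tx <- config$treatment

  kern_par <- list(
    k_bmi = phys$k_bmi, bmi_ref = phys$bmi_ref, s_min = phys$s_min,
    rho_preg = phys$rho_preg, g_max = phys$g_max, g_thr = phys$g_thr,
    k_decay = phys$k_decay, r_regen = phys$r_regen, e_rev = phys$e_rev,
    bmi_secular = phys$bmi_secular, bmi_noise_sd = phys$bmi_noise_sd,
    m_full = tx$m_full, ramp_weeks = tx$ramp_weeks,
    drift_age = as.numeric(phys$bmi_drift_age$age),
    drift_rate = as.numeric(phys$bmi_drift_age$rate))

  dt <- sim$dt_months / 12
  spy <- as.integer(round(1 / dt))          # steps per year
  fert_min <- min(fert$age_lo)
  fert_max <- max(fert$age_hi)
  p_conc <- 1 - exp(-conception_hazard(seq(fert_min, fert_max - 1) + 0.5,
                                       fert) * dt)
  t0 <- sim$calendar_start_year
  n_years <- as.integer(sim$horizon_years)
  n_steps <- n_years * spy
  dt_weeks <- dt * 52

  ## ---- population and initial budding ----
  pop <- config$population$table %||%
    synthetic_population(config$population$n, config$population$frac_high_risk)
  chain <- init_stocks(pop, exit_rate = config$mortality$exit_rate)
  scope <- if (sim$bud_scope == "high_risk_only") "high_risk_ethnicity" else RISK_GROUPS
  scope_idx <- match(scope, RISK_GROUPS)
  bud0 <- bud_agents(chain, "all", age_range = c(15, 50), risk_groups = scope,
                     seed = stream_seed(seed, PURPOSE[["bud"]], 0L))
  chain <- bud0$chain
  n0 <- length(bud0$age)
  cap0 <- max(1024L, 2L^as.integer(ceiling(log2((n0 + 1) * 3))))
  ag <- agents_new(n_iv, cap = cap0)
  if (n0 > 0) {
    ph <- phenotype_draw(n0, phys, seed = stream_seed(seed, PURPOSE[["phenotype"]], 0L))
    u_h <- draw_norm(seed, "height", 0L, n0)
    u_f <- draw_unif(seed, "fam_hist", 0L, n0)
    u_b <- draw_unif(seed, "bmi_init", 0L, 2L * n0)
    agents_append(ag, list(
      birth_t = t0 - bud0$age,
      height = clamp(config$population$height_mean +
                       config$population$height_sd * u_h, 1.45, 1.90),
      bmi = draw_initial_bmi(bud0$age, bud0$risk_group,
                             config$population$weight_init,
                             u_b[seq_len(n0)], u_b[n0 + seq_len(n0)]),
      eth = bud0$risk_group == "high_risk_ethnicity",
      phen = ph$phenotype, s_base = ph$s_base, b_base = ph$b_base,
      fam_hist = u_f < config$population$family_history_prev,
      mother = rep(NA_integer_, n0), iud = rep(FALSE, n0),
      dmult = rep(1, n0)))
  }

  ## ---- accumulators ----
  births <- diag_n <- adverse_n <- numeric(n_years)
  births_hr <- diag_hr <- births_35 <- diag_35 <- numeric(n_years)
  svc <- matrix(0, nrow = length(SERVICE_KINDS), ncol = n_years,
                dimnames = list(SERVICE_KINDS, NULL))
  wt_snap <- matrix(NA_real_, nrow = n_years, ncol = 3,
                    dimnames = list(NULL, c("healthy", "overweight", "obese")))
  age_snap <- matrix(0, nrow = n_years, ncol = length(AGE_BANDS),
                     dimnames = list(NULL, AGE_BANDS))
  ev <- if (record_events) ev_new() else NULL
  yr_of <- function(tt) pmin(n_years, pmax(1L, as.integer(floor(tt - t0)) + 1L))

  band15 <- 4L  # "15-19"; inflow arrives from band 3 ("10-14")

  ## agents created during a year (budded entrants, newborn girls) are
  ## collected here and appended in one batch at the next year boundary;
  ## they take no part in conception or screening before age 15, so the
  ## deferral does not change any observable pathway
  pend <- new.env(parent = emptyenv())
  pend$chunks <- list()
  flush_pending <- function() {
    if (!length(pend$chunks)) return(invisible())
    fields <- lapply(names(pend$chunks[[1]]$fields), function(f)
      unlist(lapply(pend$chunks, function(ch) ch$fields[[f]]),
             use.names = FALSE))
    names(fields) <- names(pend$chunks[[1]]$fields)
    ids <- agents_append(ag, fields)
    if (record_events) {
      off <- 0L
      for (chunk in pend$chunks) {
        nn <- length(chunk$fields$birth_t)
        if (!is.null(chunk$birth_time))
          ev_add(ev, "birth", chunk$birth_time, ids[off + seq_len(nn)],
                 value = chunk$meanG, age = 0,
                 high_risk = chunk$fields$eth, detail = "female")
        off <- off + nn
      }
    }
    pend$chunks <- list()
  }

  for (k in seq_len(n_steps)) {
    t <- t0 + (k - 1L) * dt
    yi <- as.integer(floor(t - t0)) + 1L

    ## year boundary: integrate pending agents, take the annual snapshot,
    ## and advance children's (linear, noise-free) BMI by one year
    if ((k - 1L) %% spy == 0L) {
      flush_pending()
      bad <- which(ag$alive & !(is.finite(ag$bmi) & is.finite(ag$B) &
                                  is.finite(ag$E)))
      if (length(bad))
        stop("non-finite agent state detected: agent ", ag$id[bad[1]],
             " at t = ", round(t, 3), call. = FALSE)
      age_now <- t - ag$birth_t
      sub <- ag$alive & age_now >= 15 & age_now < 65
      if (any(sub)) {
        wc <- weight_category(ag$bmi[sub])
        wt_snap[yi, ] <- c(mean(wc == "healthy"), mean(wc == "overweight"),
                           mean(wc == "obese"))
      }
      counts <- tabulate(band_of_age(pmax(0, age_now[ag$alive])),
                         nbins = length(AGE_BANDS))
      age_snap[yi, ] <- counts + rowSums(chain$stocks)
      ci <- which(ag$alive & age_now < 15)
      if (length(ci)) {
        frac_yr <- pmin(1, 15 - age_now[ci])
        ag$bmi[ci] <- ag$bmi[ci] +
          (phys$childhood_rate * ag$dmult[ci] + phys$bmi_secular) * frac_yr
      }
    }

    ## 1. aggregate chain step; bud the ageing inflow into the
    ##    reproductive window for the scoped risk groups
    chain <- step_chain(chain, dt)
    fl <- attr(chain, "flows")
    inflow <- fl$aging[band15 - 1L, scope_idx]
    u_bud <- draw_unif(seed, "bud", k, length(scope_idx) * 3L)
    nbud <- stochastic_round(inflow, u_bud[seq_along(scope_idx)])
    nbud <- pmin(nbud, floor(chain$stocks[band15, scope_idx] + 1e-9))
    tot_bud <- sum(nbud)
    if (tot_bud > 0) {
      chain$stocks[band15, scope_idx] <- chain$stocks[band15, scope_idx] - nbud
      chain$agents_created <- chain$agents_created + tot_bud
      grp <- rep(scope, times = nbud)
      ph <- phenotype_draw(tot_bud, phys,
                            seed = stream_seed(seed, PURPOSE[["phenotype"]], k))
      u_h <- draw_norm(seed, "height", k, tot_bud)
      u_f <- draw_unif(seed, "fam_hist", k, tot_bud)
      u_b <- draw_unif(seed, "bmi_init", k, 3L * tot_bud)
      age_in <- 15 + u_b[2L * tot_bud + seq_len(tot_bud)] * dt
      pend$chunks[[length(pend$chunks) + 1L]] <- list(fields = list(
        birth_t = t - age_in,
        height = clamp(config$population$height_mean +
                         config$population$height_sd * u_h, 1.45, 1.90),
        ## later entry cohorts carry the secular trend accumulated since
        ## the simulation start (calendar-anchored childhood weight trend)
        bmi = draw_initial_bmi(age_in, grp, config$population$weight_init,
                               u_b[seq_len(tot_bud)],
                               u_b[tot_bud + seq_len(tot_bud)]) +
          phys$bmi_secular * (t - t0),
        eth = grp == "high_risk_ethnicity",
        phen = ph$phenotype, s_base = ph$s_base, b_base = ph$b_base,
        fam_hist = u_f < config$population$family_history_prev,
        mother = rep(NA_integer_, tot_bud), iud = rep(FALSE, tot_bud),
        dmult = rep(1, tot_bud)))
    }

    if (ag$n == 0L && !length(pend$chunks)) next
    ntot <- ag$cap
    age <- t - ag$birth_t
    alive <- ag$alive

    ## 2. agent mortality (same per-band exit schedule as the chain),
    ##    applied once per simulated year
    if ((k - 1L) %% spy == 0L) {
      u_m <- draw_unif(seed, "mortality", k, ntot)
      p_die <- (1 - exp(-config$mortality$exit_rate))[band_of_age(pmax(0, age))]
      dies <- alive & (u_m < p_die | age > 100)
      if (any(dies)) {
        ag$alive[dies] <- FALSE
        alive <- ag$alive
        if (record_events)
          ev_add(ev, "death", rep(t, sum(dies)), ag$id[dies],
                 age = age[dies], high_risk = ag$eth[dies])
      }
    }

    ## 3. intervention enrolment and current channel intensities
    if (n_iv) {
      s_mult <- rep(1, ntot)
      ivbmi <- rep(0, ntot)
      for (i in seq_len(n_iv)) {
        spec <- ivs[[i]]
        yr_now <- floor(t)
        if (yr_now >= spec$start_year && yr_now <= spec$end_year) {
          cand <- alive & !ag$iv_offered[[i]] &
            intervention_eligible(spec, age, ag$bmi, ag$eth, ag$prior_gdm,
                                  ag$fam_hist, ag$parity, ag$preg == 1L)
          if (any(cand)) {
            ag$iv_offered[[i]][cand] <- TRUE
            u_up <- draw_unif(seed, "uptake", k * 8L + i, ntot)
            enrol <- cand & u_up < spec$uptake
            if (any(enrol)) {
              ag$iv_enrol[[i]][enrol] <- t
              if (record_events)
                ev_add(ev, "intervention_enrol", rep(t, sum(enrol)),
                       ag$id[enrol], age = age[enrol],
                       high_risk = ag$eth[enrol], detail = spec$name)
            }
          }
        }
        en <- which(!is.na(ag$iv_enrol[[i]]))
        if (length(en)) {
          inten <- intervention_intensity(spec, t, ag$iv_enrol[[i]][en])
          s_mult[en] <- s_mult[en] * (1 + inten$s * (spec$s_multiplier - 1))
          ivbmi[en] <- ivbmi[en] +
            inten$bmi * delta_bmi(spec$bmi_effect_kg, ag$height[en])
        }
      }
      dbmi_iv <- ivbmi - ag$ivbmi_prev
      ag$ivbmi_prev <- ivbmi
    } else {
      s_mult <- NULL
      dbmi_iv <- NULL
    }

    ## 4. one compiled pass over the living agents in the
    ##    screening-relevant life span (15-65): metabolism and BMI update
    ##    plus collection of the step's discrete events (tests falling due,
    ##    deliveries, postpartum completions, conceptions). Children keep
    ##    their annual drift; agents past 65 keep their last state. The
    ##    kernel mirrors insulin_sensitivity / glycemic_index /
    ##    step_metabolism / bmi_step exactly (checked by the test suite).
    ge15 <- alive & age >= 15
    li <- which(ge15 & age < 65)
    z <- draw_norm(seed, "bmi_noise", k, length(li))
    u_c <- draw_unif(seed, "conception", k, length(li))
    scan <- .step_scan_cpp(li, age, ag$bmi, ag$B, ag$E, ag$s_base, ag$preg,
                           ag$preg_t0, ag$diag_w, ag$gsum, ag$gn, ag$dmult,
                           z,
                           s_mult %||% numeric(0),
                           dbmi_iv %||% numeric(0),
                           ag$sw_early, ag$sw_univ, ag$pp_end, u_c, p_conc,
                           fert_min, fert_max, dt_weeks, t, dt, kern_par,
                           mech)

    ## 5. pregnancy milestones: screenings, deliveries, postpartum ends,
    ##    processed in (time, agent id, kind) order within the step
    {
      do_test <- function(di, kind) {
        if (!length(di)) return()
        swd <- if (kind == "early_screen") ag$sw_early[di] else ag$sw_univ[di]
        t_ev <- ag$preg_t0[di] + swd / 52
        ord <- order(t_ev, ag$id[di])
        di <- di[ord]; swd <- swd[ord]; t_ev <- t_ev[ord]
        thr <- threshold_in_force(sched, floor(t_ev))
        if (mech) {
          S_t <- insulin_sensitivity(ag$bmi[di], swd, ag$s_base[di] *
                                       (if (n_iv) s_mult[di] else 1), phys)
          G_t <- glycemic_index(S_t, ag$B[di], phys$g_max)
          was_tr <- !is.na(ag$diag_w[di]) & ag$diag_w[di] < swd
          if (any(was_tr))
            G_t[was_tr] <- G_t[was_tr] *
              treatment_effect(swd[was_tr] - ag$diag_w[di][was_tr],
                               tx$m_full, tx$ramp_weeks)
          pos <- G_t >= thr
        } else {
          G_t <- rep(NA_real_, length(di))
          pos <- ag$rc_pos[di]
        }
        if (record_events)
          ev_add(ev, kind, t_ev, ag$id[di], week = swd, value = G_t,
                 threshold = thr, age = t_ev - ag$birth_t[di],
                 high_risk = ag$eth[di])
        yr_ev <- yr_of(t_ev)
        for (y in unique(yr_ev)) svc[kind, y] <<- svc[kind, y] + sum(yr_ev == y)
        newdiag <- pos & is.na(ag$diag_w[di])
        if (any(newdiag)) {
          nd <- di[newdiag]
          ag$diag_w[nd] <- swd[newdiag]
          y_nd <- yr_ev[newdiag]
          add_tab <- tabulate(y_nd, nbins = n_years)
          diag_n <<- diag_n + add_tab
          diag_hr <<- diag_hr + tabulate(y_nd[ag$eth[nd]], nbins = n_years)
          diag_35 <<- diag_35 +
            tabulate(y_nd[(t_ev[newdiag] - ag$birth_t[nd]) >= 35],
                     nbins = n_years)
          svc["diagnosis", ] <<- svc["diagnosis", ] + add_tab
          svc["lifestyle_rx", ] <<- svc["lifestyle_rx", ] + add_tab
          if (record_events) {
            ev_add(ev, "diagnosis", t_ev[newdiag], ag$id[nd],
                   week = swd[newdiag], value = G_t[newdiag],
                   threshold = thr[newdiag],
                   age = t_ev[newdiag] - ag$birth_t[nd],
                   high_risk = ag$eth[nd])
            ev_add(ev, "lifestyle_rx", t_ev[newdiag], ag$id[nd],
                   week = swd[newdiag])
          }
          if (mech) {
            pharm <- G_t[newdiag] >= tx$pharmaco_g
            if (any(pharm)) {
              y_ph <- y_nd[pharm]
              svc["pharmaco_rx", ] <<- svc["pharmaco_rx", ] +
                tabulate(y_ph, nbins = n_years)
              if (record_events)
                ev_add(ev, "pharmaco_rx", t_ev[newdiag][pharm],
                       ag$id[nd[pharm]], week = swd[newdiag][pharm])
            }
          }
        }
      }
      do_test(scan$due_early, "early_screen")
      do_test(scan$due_univ, "ogtt")

      ## deliveries at week 40
      if (length(scan$due_deliver)) {
        mi <- scan$due_deliver
        t_d <- ag$preg_t0[mi] + 40 / 52
        ord <- order(t_d, ag$id[mi])
        mi <- mi[ord]; t_d <- t_d[ord]
        nd <- length(mi)
        meanG <- ag$gsum[mi] / pmax(ag$gn[mi], 1)
        u_a <- draw_unif(seed, "adverse", k, nd)
        adv <- u_a < adverse_outcome_prob(meanG, out_par$p_min, out_par$p_max,
                                          out_par$k, out_par$g_mid)
        z_g <- draw_norm(seed, "gwg", k, nd)
        gwg <- clamp(phys$gwg_mean + phys$gwg_sd * z_g, 0, 25)
        ag$bmi[mi] <- ag$bmi[mi] +
          phys$retention_frac * delta_bmi(gwg, ag$height[mi])
        dip_this <- !is.na(ag$diag_w[mi])
        y_d <- yr_of(t_d)
        m_age <- t_d - ag$birth_t[mi]
        births <- births + tabulate(y_d, nbins = n_years)
        births_hr <- births_hr + tabulate(y_d[ag$eth[mi]], nbins = n_years)
        births_35 <- births_35 + tabulate(y_d[m_age >= 35], nbins = n_years)
        adverse_n <- adverse_n + tabulate(y_d[adv], nbins = n_years)
        svc["delivery_care", ] <- svc["delivery_care", ] +
          tabulate(y_d, nbins = n_years)
        ## intergenerational endowment; only female babies become agents
        ## (inline form of birth_endowment / classify_glycemic)
        impaired <- if (mech) {
          S_m <- insulin_sensitivity(ag$bmi[mi], NA, ag$s_base[mi] *
                                       (if (n_iv) s_mult[mi] else 1), phys)
          glycemic_index(S_m, ag$B[mi], phys$g_max) >= phys$g_igr
        } else rep(FALSE, nd)
        exposed <- meanG >= phys$g_thr
        ed <- list(
          in_utero_dysglycemia = exposed,
          family_history = impaired | ag$prior_gdm[mi],
          b_base_mult = 1 - (1 - endow$b_base_mult) * exposed,
          drift_mult = 1 + (endow$drift_mult - 1) * exposed)
        u_s <- draw_unif(seed, "sex", k, nd)
        female <- u_s < sim$female_fraction
        if (record_events) {
          ev_add(ev, "delivery_care", t_d, ag$id[mi], week = 40,
                 value = meanG, age = m_age, high_risk = ag$eth[mi])
          if (any(adv))
            ev_add(ev, "adverse_outcome", t_d[adv], ag$id[mi[adv]],
                   value = meanG[adv], age = m_age[adv],
                   high_risk = ag$eth[mi[adv]])
        }
        if (any(female)) {
          fb <- which(female)
          nb <- length(fb)
          ph_b <- phenotype_draw(nb, phys,
                                 seed = stream_seed(seed, PURPOSE[["phenotype"]],
                                                    n_steps + k))
          u_h <- draw_norm(seed, "height", n_steps + k, nb)
          pend$chunks[[length(pend$chunks) + 1L]] <- list(
            fields = list(
              birth_t = t_d[fb],
              height = clamp(config$population$height_mean +
                               config$population$height_sd * u_h, 1.45, 1.90),
              ## childhood drift owed between birth and the batch append
              ## is credited at the next year boundary via birth_t
              bmi = rep(14, nb),
              eth = ag$eth[mi[fb]],
              phen = ph_b$phenotype, s_base = ph_b$s_base,
              b_base = ph_b$b_base * ed$b_base_mult[fb],
              fam_hist = ed$family_history[fb] | dip_this[fb],
              mother = ag$id[mi[fb]], iud = ed$in_utero_dysglycemia[fb],
              dmult = ed$drift_mult[fb]),
            birth_time = t_d[fb], meanG = meanG[fb])
        }
        if (record_events && any(!female))
          ev_add(ev, "birth_male", t_d[!female], ag$id[mi[!female]],
                 age = 0, high_risk = ag$eth[mi[!female]], detail = "male")
        ## mother transitions: POSTPARTUM, latch prior GDM, parity
        ag$parity[mi] <- ag$parity[mi] + 1L
        ag$prior_gdm[mi] <- ag$prior_gdm[mi] | dip_this
        ag$preg[mi] <- 2L
        ag$pp_end[mi] <- t_d + sim$postpartum_weeks / 52
        ag$preg_t0[mi] <- NA_real_
        ag$gsum[mi] <- 0; ag$gn[mi] <- 0
        ag$diag_w[mi] <- NA_real_
        ag$sw_early[mi] <- NA_real_; ag$sw_univ[mi] <- NA_real_
        ag$rc_pos[mi] <- FALSE
        dip_latch <- dip_this   # postpartum test offered to these mothers
        if (any(dip_latch)) {
          u_pp <- draw_unif(seed, "participation", n_steps + k, nd)
          att <- dip_latch & u_pp < pol$participation
          if (any(att)) {
            t_pp <- ag$pp_end[mi[att]]
            y_pp <- yr_of(t_pp)
            svc["postpartum_test", ] <- svc["postpartum_test", ] +
              tabulate(y_pp, nbins = n_years)
            if (record_events)
              ev_add(ev, "postpartum_test", t_pp, ag$id[mi[att]],
                     age = t_pp - ag$birth_t[mi[att]],
                     high_risk = ag$eth[mi[att]])
          }
        }
      }
    }

    ## postpartum -> not pregnant
    ppi <- scan$pp_done
    if (length(ppi)) {
      ag$preg[ppi] <- 0L
      ag$pp_end[ppi] <- NA_real_
    }

    ## 6. conceptions (eligibility assessed in the kernel pass)
    {
      conc <- scan$conc
      if (length(conc)) {
        nc <- length(conc)
        u_j <- draw_unif(seed, "preg_jitter", k, nc)
        ag$preg[conc] <- 1L
        ag$preg_t0[conc] <- t + u_j * dt
        ag$gsum[conc] <- 0; ag$gn[conc] <- 0
        ag$diag_w[conc] <- NA_real_
        u_p <- draw_unif(seed, "participation", k, 2L * nc)
        hr <- adips_high_risk(ag$eth[conc], age[conc], ag$prior_gdm[conc],
                              ag$fam_hist[conc], ag$bmi[conc])
        sw_u <- rep(NA_real_, nc)
        sw_u[u_p[seq_len(nc)] < pol$participation] <- pol$universal_week
        ag$sw_univ[conc] <- sw_u
        sw_e <- rep(NA_real_, nc)
        sw_e[pol$mode == "selective" & hr &
               u_p[nc + seq_len(nc)] < pol$participation] <- pol$early_week
        ag$sw_early[conc] <- sw_e
        if (!mech) {
          u_rc <- draw_unif(seed, "risk_count", k, nc)
          ag$rc_pos[conc] <- u_rc <
            risk_count_probability(ag$eth[conc], age[conc], ag$prior_gdm[conc],
                                   ag$fam_hist[conc], ag$bmi[conc],
                                   config$risk_count$p0, config$risk_count$beta)
        }
        t_bk <- ag$preg_t0[conc] + 8 / 52
        y_bk <- yr_of(t_bk)
        svc["booking", ] <- svc["booking", ] + tabulate(y_bk, nbins = n_years)
        if (record_events) {
          ev_add(ev, "conception", ag$preg_t0[conc], ag$id[conc], week = 0,
                 age = ag$preg_t0[conc] - ag$birth_t[conc],
                 high_risk = ag$eth[conc])
          ev_add(ev, "booking", t_bk, ag$id[conc], week = 8,
                 age = t_bk - ag$birth_t[conc], high_risk = ag$eth[conc])
        }
      }
    }
  }

  flush_pending()

  ## ---- assemble annual series over the reporting window ----
  rep_years <- (sim$burn_in_years + 1L):n_years
  yr <- t0 + rep_years - 1L
  frac <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  unit_costs <- unlist(config$costs)
  cost_year <- as.numeric(unit_costs[SERVICE_KINDS] %*% svc)
  annual <- data.frame(
    year = yr,
    births = births[rep_years],
    dip_diagnoses = diag_n[rep_years],
    dip_frac = frac(diag_n, births)[rep_years],
    dip_frac_high_risk = frac(diag_hr, births_hr)[rep_years],
    dip_frac_standard = frac(diag_n - diag_hr, births - births_hr)[rep_years],
    dip_frac_under35 = frac(diag_n - diag_35, births - births_35)[rep_years],
    dip_frac_35plus = frac(diag_35, births_35)[rep_years],
    adverse = adverse_n[rep_years],
    prop_healthy = wt_snap[rep_years, 1],
    prop_overweight = wt_snap[rep_years, 2],
    prop_obese = wt_snap[rep_years, 3],
    ogtt_tests = svc["ogtt", rep_years] + svc["early_screen", rep_years],
    total_cost = cost_year[rep_years]
  )
  if (!all(is.finite(unlist(annual[c("births", "dip_diagnoses")])))) {
    stop("non-finite annual series detected", call. = FALSE)
  }
  structure(list(
    annual = annual,
    events = if (record_events) ev_collect(ev) else NULL,
    agents = if (record_events) data.frame(
      id = ag$id, birth_t = ag$birth_t, high_risk = ag$eth,
      phenotype = ag$phen, mother_id = ag$mother, parity = ag$parity,
      prior_gdm = ag$prior_gdm, alive = ag$alive, bmi = ag$bmi
    ) else NULL,
    snapshots = list(year = t0 + seq_len(n_years) - 1L,
                     weight = wt_snap, ages = age_snap,
                     reporting = yr),
    service_counts = svc,
    chain = chain,
    agents_final = ag$n,
    config = config, seed = seed,
    runtime_s = proc.time()[["elapsed"]] - t_start
  ), class = "dip_run")
}

#' @export
print.dip_run <- function(x, ...) {
  a <- x$annual
  cat("<dip_run> seed ", x$seed, ", years ", min(a$year), "-", max(a$year),
      ", ", x$agents_final, " agents, ", round(x$runtime_s, 2), "s\n", sep = "")
  cat("  births/yr ", round(mean(a$births), 1), ", DIP % ",
      paste(round(100 * range(a$dip_frac, na.rm = TRUE), 1), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' Run replicate seeds of one scenario
#'
#' @param config scenario configuration.
#' @param seeds integer vector of seeds, or a count (expanded with
#'   [replicate_seeds()] from the scenario seed).
#' @param record_events forwarded to [run_scenario()].
#' @return list of `dip_run` objects.
#' @export
run_replicates <- function(config, seeds = 5, record_events = FALSE) {
  if (length(seeds) == 1L && seeds == floor(seeds) && seeds > 0 &&
      is.null(names(seeds)) && seeds < 1000)
    seeds <- replicate_seeds(config$simulation$seed %||% 1L, seeds)
  lapply(seeds, function(s) run_scenario(config, seed = s,
                                         record_events = record_events))
}

#' Burn-in stationarity statistic
#'
#' Splits off the last two `window`-length segments of a series and returns
#' the absolute difference of their means normalised by the overall level
#' (mean of the two window means). Near zero for a series that has reached
#' a plateau; large for a trending series. The caller compares against a
#' tolerance when choosing a burn-in length.
#'
#' @param series numeric vector (e.g. annual DIP fraction including
#'   burn-in years).
#' @param window segment length; `series` must contain at least two windows.
#' @return non-negative scalar.
#' @export
burn_in_check <- function(series, window) {
  if (length(series) < 2 * window)
    stop("series too short: need at least 2 * window = ", 2 * window,
         " values", call. = FALSE)
  tail2 <- series[(length(series) - 2 * window + 1):length(series)]
  m1 <- mean(tail2[seq_len(window)])
  m2 <- mean(tail2[window + seq_len(window)])
  lev <- (m1 + m2) / 2
  if (lev == 0) return(abs(m2 - m1))
  abs(m2 - m1) / lev
}
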