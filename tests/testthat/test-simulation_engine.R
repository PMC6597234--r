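test_that("scenario validation reports all violations together", {
  cfg <- default_scenario()
  cfg$simulation$horizon_years <- -1
  cfg$simulation$dt_months <- 5
  cfg$etiology <- "astrology"
  err <- tryCatch(validate_scenario(cfg), error = conditionMessage)
  expect_match(err, "horizon_years")
  expect_match(err, "dt_months")
  expect_match(err, "etiology")
})

test_that("identical configuration and seed give identical results", {
  cfg <- small_scenario()
  r1 <- run_scenario(cfg, seed = 42, record_events = FALSE)
  r2 <- run_scenario(cfg, seed = 42, record_events = FALSE)
  expect_identical(r1$annual, r2$annual)
  ## recording events does not perturb the simulation
  r3 <- run_scenario(cfg, seed = 42, record_events = TRUE)
  expect_identical(r1$annual, r3$annual)
})

test_that("a degenerate run with no fertile agents reports NA incidence,
           not zero", {
  cfg <- default_scenario()
  cfg$population$n <- 500
  cfg$simulation$horizon_years <- 1
  cfg$simulation$burn_in_years <- 0
  cfg$fertility$rate[] <- 0
  r <- run_scenario(cfg, seed = 1, record_events = FALSE)
  expect_equal(r$annual$births, 0)
  expect_true(is.na(r$annual$dip_frac))
})

test_that("annual births scale with the initial population", {
  mk <- function(n) {
    cfg <- default_scenario()
    cfg$population$n <- n
    cfg$simulation$horizon_years <- 8
    cfg$simulation$burn_in_years <- 2
    cfg
  }
  ratios <- vapply(1:3, function(s) {
    b1 <- mean(run_scenario(mk(4000), seed = s,
                            record_events = FALSE)$annual$births)
    b2 <- mean(run_scenario(mk(8000), seed = s,
                            record_events = FALSE)$annual$births)
    b2 / b1
  }, numeric(1))
  expect_true(all(abs(ratios - 2) < 0.2))
})

test_that("the event log is time-ordered and agent pregnancies are
           internally consistent", {
  cfg <- small_scenario()
  r <- run_scenario(cfg, seed = 9)
  ev <- as.data.frame(r$events)
  expect_true(!is.unsorted(ev$time))
  ## within one agent, service events never run backwards in time
  one <- ev[ev$agent_id == ev$agent_id[which(ev$kind == "diagnosis")[1]], ]
  expect_true(!is.unsorted(one$time))
  ## deliveries happen 40 weeks after their conception
  conc <- ev[ev$kind == "conception", c("agent_id", "time")]
  del <- ev[ev$kind == "delivery_care", c("agent_id", "time")]
  first_conc <- conc[!duplicated(conc$agent_id), ]
  first_del <- del[!duplicated(del$agent_id), ]
  both <- merge(first_conc, first_del, by = "agent_id")
  gest <- (both$time.y - both$time.x) * 52
  expect_true(all(abs(gest[gest < 45] - 40) < 1e-6))
})

test_that("metabolism updates run monthly: a constant-G pregnancy tracks
           its mean exactly", {
  cfg <- small_scenario()
  r <- run_scenario(cfg, seed = 9)
  ev <- as.data.frame(r$events)
  del <- ev[ev$kind == "delivery_care", ]
  ## mean G recorded at delivery is bounded by the physiological range
  expect_true(all(del$value >= 1 & del$value <= r$config$physiology$g_max))
})

test_that("switching universal to selective screening preserves
           routine-week test results under shared seeds", {
  uni <- small_scenario()
  uni$screening$mode <- "universal"
  uni$screening$participation <- 1
  sel <- uni
  sel$screening$mode <- "selective"
  ru <- run_scenario(uni, seed = 17)
  rs <- run_scenario(sel, seed = 17)
  gu <- as.data.frame(ru$events)
  gs <- as.data.frame(rs$events)
  ogtt_u <- gu[gu$kind == "ogtt", c("agent_id", "time", "value", "threshold")]
  ogtt_s <- gs[gs$kind == "ogtt", c("agent_id", "time", "value", "threshold")]
  rownames(ogtt_u) <- rownames(ogtt_s) <- NULL
  ## the same women attend the same routine tests at the same times
  expect_equal(ogtt_u[c("agent_id", "time")], ogtt_s[c("agent_id", "time")])
  ## among women not already diagnosed (and treated) at an early screen,
  ## the routine-week results are identical across the two policies
  early_dx <- unique(gs$agent_id[gs$kind == "diagnosis" & gs$week < 26])
  untouched <- !(ogtt_s$agent_id %in% early_dx)
  expect_equal(ogtt_u$value[untouched], ogtt_s$value[untouched])
  expect_equal(ogtt_u$value[untouched] >= ogtt_u$threshold[untouched],
               ogtt_s$value[untouched] >= ogtt_s$threshold[untouched])
  ## and the selective arm adds early screens for high-risk women only
  expect_gt(sum(gs$kind == "early_screen"), 0)
  expect_equal(sum(gu$kind == "early_screen"), 0)
})

test_that("burn-in statistic is zero for a plateau and large for a trend", {
  expect_equal(burn_in_check(rep(5, 10), 3), 0)
  expect_equal(burn_in_check(c(1, 1, 1, 2, 2, 2), 3), 1 / 1.5)
  expect_gt(burn_in_check(1:40, 10), 0.3)
  expect_error(burn_in_check(1:5, 3), "too short")
})

test_that("the legacy risk-count aetiology produces diagnoses without
           touching the latent physiology", {
  cfg <- small_scenario()
  cfg$etiology <- "risk_count"
  cfg$risk_count <- list(p0 = 0.05, beta = 0.05)
  r <- run_scenario(cfg, seed = 4)
  expect_gt(sum(r$annual$dip_diagnoses), 0)
  ev <- as.data.frame(r$events)
  ## risk-count tests carry no latent G measurement
  expect_true(all(is.na(ev$value[ev$kind == "ogtt"])))
})
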