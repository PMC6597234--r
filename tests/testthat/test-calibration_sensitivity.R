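test_that("target tables validate years and fractions", {
  tab <- calibration_targets(c(2008, 2016), c(0.06, 0.16))
  expect_equal(nrow(tab), 2)
  expect_error(calibration_targets(c(2008, 2008), c(0.1, 0.2)), "distinct")
  expect_error(calibration_targets(2008, 1.5), "\\[0,1\\]")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  expect_equal(read_targets(path), tab)
})

test_that("free parameters address the configuration by path", {
  cfg <- default_scenario()
  fp <- default_free_parameters()
  cfg2 <- dipsim:::apply_free_params(cfg, fp, c(0.11, 0.07, 2.5))
  expect_equal(cfg2$physiology$bmi_secular, 0.11)
  expect_equal(cfg2$physiology$k_decay, 0.07)
  expect_equal(cfg2$diagnostics$thresholds[2], 2.5)
  ## untouched values stay put
  expect_equal(cfg2$diagnostics$thresholds[1], cfg$diagnostics$thresholds[1])
})

test_that("the loss is a replicate-mean sum of squares, invariant to target
           order, and guards the reporting window", {
  cfg <- small_scenario()
  fp <- default_free_parameters()
  yrs <- cfg$simulation$calendar_start_year +
    c(cfg$simulation$burn_in_years, cfg$simulation$horizon_years - 1)
  vals <- c(0.10, 0.05, 2.8)

  ## self-targets: simulate once, use the simulated values as targets with
  ## the same single replicate seed -> loss is exactly zero
  r <- run_scenario(dipsim:::apply_free_params(cfg, fp, vals),
                    seed = replicate_seeds(1, 1), record_events = FALSE)
  sim <- r$annual$dip_frac[match(yrs, r$annual$year)]
  tg <- calibration_targets(yrs, sim)
  expect_equal(calibration_loss(vals, tg, cfg, fp, n_replicates = 1,
                                seed = 1), 0)

  ## permuting target rows leaves the loss unchanged
  tg2 <- calibration_targets(yrs, c(0.06, 0.16))
  l_a <- calibration_loss(vals, tg2, cfg, fp, n_replicates = 1, seed = 1)
  l_b <- calibration_loss(vals, tg2[2:1, ], cfg, fp, n_replicates = 1,
                          seed = 1)
  expect_equal(l_a, l_b)
  expect_gte(l_a, 0)

  bad <- calibration_targets(1900, 0.1)
  expect_error(calibration_loss(vals, bad, cfg, fp), "outside")
})

test_that("a budget of one returns the single evaluated point", {
  cfg <- small_scenario()
  yrs <- cfg$simulation$calendar_start_year +
    c(cfg$simulation$burn_in_years, cfg$simulation$horizon_years - 1)
  tg <- calibration_targets(yrs, c(0.06, 0.16))
  cal <- calibrate_model(cfg, tg, budget = 1, n_replicates = 1, seed = 2)
  expect_equal(cal$n_eval, 1L)
  expect_equal(nrow(cal$trace), 1L)
  expect_true(all(names(cal$par) ==
                    c("bmi_secular", "k_decay", "threshold_post")))
})

test_that("sensitivity ranks a causally connected parameter above a cost
           parameter", {
  cfg <- small_scenario()
  fp <- list(
    list(name = "k_decay", path = c("physiology", "k_decay"),
         lower = 0.01, upper = 0.5, transform = "log"),
    list(name = "ogtt_cost", path = c("costs", "ogtt"),
         lower = 1, upper = 1000, transform = "linear")
  )
  out <- sensitivity_oat(cfg, fp, perturbation_frac = 0.5, n_replicates = 2,
                         seed = 3)
  expect_equal(out$elasticity[out$name == "ogtt_cost"], 0)
  expect_gt(abs(out$elasticity[out$name == "k_decay"]), 0)
  ## tornado order puts the influential parameter first
  expect_equal(out$name[1], "k_decay")
  ## ordering of the input list does not change the ranking
  out2 <- sensitivity_oat(cfg, fp[2:1], perturbation_frac = 0.5,
                          n_replicates = 2, seed = 3)
  expect_equal(out$name, out2$name)
})

test_that("readiness report scores anchors and marks missing references as
           not assessed", {
  cfg <- small_scenario()
  r <- run_scenario(cfg, seed = 6, record_events = FALSE)
  yrs <- range(r$annual$year)
  sim <- r$annual$dip_frac[match(yrs, r$annual$year)]

  ## perfect anchors: zero error, pass
  rep1 <- readiness_report(r, calibration_targets(yrs, sim))
  expect_true(all(rep1$rows$error[1:2] == 0))
  expect_true(rep1$pass)
  expect_equal(rep1$rows$status[rep1$rows$indicator == "weight_categories"],
               "not assessed")

  ## anchors off by more than the tolerance: fail
  rep2 <- readiness_report(r, calibration_targets(yrs, pmin(1, sim + 0.1)))
  expect_false(rep2$pass)

  ## weight reference supplied: assessed via L1 distance
  wt <- as.numeric(r$annual[nrow(r$annual),
                            c("prop_healthy", "prop_overweight", "prop_obese")])
  rep3 <- readiness_report(r, calibration_targets(yrs, sim),
                           reference_weight = wt)
  expect_equal(rep3$rows$error[rep3$rows$indicator == "weight_categories"], 0)

  expect_error(readiness_report(r, calibration_targets(1900, 0.1)),
               "target year")
})
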