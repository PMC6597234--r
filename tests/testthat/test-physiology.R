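test_that("parameter validation enforces the documented constraints", {
  expect_s3_class(physiology_params(), "physiology_params")
  expect_error(physiology_params(s_min = 0), "s_min")
  expect_error(physiology_params(rho_preg = 1), "rho_preg")
  expect_error(physiology_params(g_igr = 0.9), "g_igr")
  expect_error(physiology_params(retention_frac = 1.2), "retention_frac")
  expect_error(physiology_params(k_decay = -0.1), "k_decay")
  expect_error(physiology_params(phenotype_mix = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("phenotype assignment respects the mixture", {
  p <- physiology_params()
  only_r <- assign_phenotype(50, p, mix = c(1, 0, 0), seed = 1)
  expect_true(all(only_r$phenotype == "RESISTANCE"))
  ## the driving axis is lowered relative to the spared axis
  expect_true(mean(only_r$s_base) < mean(only_r$b_base))
  only_s <- assign_phenotype(50, p, mix = c(0, 1, 0), seed = 1)
  expect_true(mean(only_s$b_base) < mean(only_s$s_base))

  big <- assign_phenotype(30000, p, mix = rep(1 / 3, 3), seed = 99)
  props <- table(big$phenotype) / 30000
  expect_true(all(abs(props - 1 / 3) < 0.01))
  expect_true(all(big$s_base > 0.3 & big$s_base <= 1))
  expect_true(all(big$b_base > 0.3 & big$b_base <= 1))

  expect_identical(assign_phenotype(100, p, seed = 5),
                   assign_phenotype(100, p, seed = 5))
  expect_error(assign_phenotype(10, p, mix = c(0.6, 0.6, 0)), "sum to 1")
})

test_that("insulin sensitivity follows the exponential BMI penalty and the
           pregnancy ramp", {
  p <- physiology_params()
  expect_equal(insulin_sensitivity(25, NA, 1, p), 1)
  expect_equal(insulin_sensitivity(35, NA, 1, p), exp(-0.5))
  expect_equal(insulin_sensitivity(25, 28, 1, p), 1 - 0.5 * 28 / 40)
  ## floor and cap
  expect_equal(insulin_sensitivity(200, NA, 1, p), p$s_min)
  expect_equal(insulin_sensitivity(18, NA, 1, p), 1)
  expect_error(insulin_sensitivity(0, NA, 1, p), "bmi")

  ## non-increasing in BMI above the reference point
  bmis <- seq(20, 50, by = 0.5)
  s <- insulin_sensitivity(bmis, NA, 0.9, p)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("glycemic index is 1/(S*B) with a cap at secretory failure", {
  expect_equal(glycemic_index(1, 1), 1)
  expect_equal(glycemic_index(0.5, 1), 2)
  expect_equal(glycemic_index(0.5, 0.8), 2.5)
  expect_equal(glycemic_index(0.5, 0), 10)
  expect_equal(glycemic_index(0.5, 0, g_max = 7), 7)
  expect_error(glycemic_index(0, 1), "S")
  ## decreasing in each argument
  expect_true(all(diff(glycemic_index(seq(0.2, 1, 0.1), 0.9)) < 0))
  expect_true(all(diff(glycemic_index(0.9, seq(0.2, 1, 0.1))) < 0))
})

test_that("exposure/beta-cell update matches the stated Euler step", {
  p <- physiology_params()
  ## below threshold: no exposure, regeneration only
  up <- step_metabolism(B = 0.8, E = 0, G = 1.0, dt = 0.1, p)
  expect_equal(up$E, 0)
  expect_equal(up$B, 0.8 + 0.05 * 0.2 * 0.1)

  ## exposure increment (2.5 - 1.5) * 0.1
  up <- step_metabolism(B = 1, E = 0, G = 2.5, dt = 0.1, p)
  expect_equal(up$E, 0.1)

  ## full update at the documented example point
  up <- step_metabolism(B = 0.8, E = 0, G = 2.5, dt = 0.1, p)
  expect_equal(up$B, 0.8 + (0.05 * 0.2 - 0.2 * 1.0 * 0.8) * 0.1)

  ## beyond the reversibility ceiling regeneration shuts off
  up <- step_metabolism(B = 0.8, E = 1.5, G = 1.0, dt = 0.1, p)
  expect_equal(up$B, 0.8)
})

test_that("exposure never decreases and B stays in [0,1] along trajectories", {
  p <- physiology_params()
  set.seed(11)
  for (rep in 1:20) {
    B <- runif(1, 0.2, 1); E <- 0
    for (i in 1:120) {
      G <- runif(1, 0.8, 4)
      up <- step_metabolism(B, E, G, 1 / 12, p)
      expect_gte(up$E, E)
      expect_gte(up$B, 0)
      expect_lte(up$B, 1)
      B <- up$B; E <- up$E
    }
  }
})

test_that("weight change converts to BMI units by height squared", {
  expect_equal(delta_bmi(-5, 1.65), -5 / 1.65^2)
  expect_gt(abs(delta_bmi(-5, 1.65)), 1)   # one to two units at 1.65 m
  expect_lt(abs(delta_bmi(-5, 1.65)), 2)
  expect_equal(delta_bmi(0, 1.7), 0)
  expect_equal(delta_bmi(-10, 1.6), -10 / 2.56)
  expect_error(delta_bmi(5, 0), "height")
})

test_that("bmi_step applies drift, secular trend and postpartum retention", {
  p0 <- physiology_params(bmi_secular = 0, bmi_noise_sd = 0,
                          bmi_drift_age = data.frame(age = c(15, 80),
                                                     rate = c(0, 0)))
  expect_equal(bmi_step(27, 30, 1, p0), 27)
  p1 <- physiology_params(bmi_secular = 0.05, bmi_noise_sd = 0,
                          bmi_drift_age = data.frame(age = c(15, 80),
                                                     rate = c(0, 0)))
  expect_equal(bmi_step(27, 30, 1, p1), 27.05)
  out <- bmi_step(27, 30, 1, p0, delivery_kg = 12, height_m = 1.65)
  expect_equal(out, 27 + 0.3 * 12 / 1.65^2)
  expect_error(bmi_step(0, 30, 1, p0), "bmi")
})

test_that("glycemic classification uses inclusive upper-state boundaries", {
  p <- physiology_params()
  expect_equal(classify_glycemic(1.0, params = p)$state, "NORMAL")
  expect_equal(classify_glycemic(1.5, params = p)$state, "IMPAIRED")
  expect_equal(classify_glycemic(2.0, params = p)$state, "DIABETES")

  ## the diagnostic-standard change flips the same woman's test result
  pre <- classify_glycemic(1.35, pregnant = TRUE, diagnostic_threshold = 1.40,
                           params = p)
  post <- classify_glycemic(1.35, pregnant = TRUE, diagnostic_threshold = 1.30,
                            params = p)
  expect_false(pre$dip_positive)
  expect_true(post$dip_positive)
  expect_true(is.na(classify_glycemic(1.35, pregnant = FALSE,
                                      diagnostic_threshold = 1.3,
                                      params = p)$dip_positive))
})

test_that("deterministic cohort mean matches the scalar update and Euler
           integration converges", {
  p <- physiology_params()
  ## 10,000 identical agents stepped together equal one scalar trajectory
  n <- 10000
  Bv <- rep(0.9, n); Ev <- rep(0, n)
  Bs <- 0.9; Es <- 0
  for (i in 1:24) {
    upv <- step_metabolism(Bv, Ev, 2.2, 1 / 12, p)
    ups <- step_metabolism(Bs, Es, 2.2, 1 / 12, p)
    Bv <- upv$B; Ev <- upv$E; Bs <- ups$B; Es <- ups$E
  }
  expect_equal(mean(Bv), Bs, tolerance = 1e-12)

  ## halving dt changes the 5-year beta-cell trajectory by < 1% for an
  ## agent held at a fixed (markedly dysglycemic) glycemic load
  run_traj <- function(dt) {
    B <- 0.9; E <- 0
    for (i in seq_len(5 / dt)) {
      up <- step_metabolism(B, E, 2.5, dt, p)
      B <- up$B; E <- up$E
    }
    B
  }
  b1 <- run_traj(1 / 12)
  b2 <- run_traj(1 / 24)
  expect_lt(abs(b1 - b2) / b2, 0.01)
})

test_that("compiled step kernel agrees with the R reference functions", {
  p <- physiology_params(bmi_noise_sd = 0.3)
  tx <- list(m_full = 0.8, ramp_weeks = 4)
  kern_par <- list(
    k_bmi = p$k_bmi, bmi_ref = p$bmi_ref, s_min = p$s_min,
    rho_preg = p$rho_preg, g_max = p$g_max, g_thr = p$g_thr,
    k_decay = p$k_decay, r_regen = p$r_regen, e_rev = p$e_rev,
    bmi_secular = p$bmi_secular, bmi_noise_sd = p$bmi_noise_sd,
    m_full = tx$m_full, ramp_weeks = tx$ramp_weeks,
    drift_age = as.numeric(p$bmi_drift_age$age),
    drift_rate = as.numeric(p$bmi_drift_age$rate))
  set.seed(202)
  n <- 400
  t <- 2000; dt <- 1 / 12
  age <- runif(n, 15, 64)
  bmi <- runif(n, 18, 44)
  B <- runif(n, 0.2, 1); E <- runif(n, 0, 2)
  s_base <- runif(n, 0.6, 1)
  preg <- sample(0:1, n, replace = TRUE)
  preg_t0 <- ifelse(preg == 1, t - runif(n, 0, 35) / 52, NA)
  diag_w <- ifelse(preg == 1 & runif(n) < 0.3, runif(n, 10, 26), NA)
  gsum <- rep(0, n); gn <- rep(0, n)
  z <- rnorm(n)

  ## R reference composition
  week <- ifelse(preg == 1, (t - preg_t0) * 52, NA)
  S <- insulin_sensitivity(bmi, week, s_base, p)
  G <- glycemic_index(S, B, p$g_max)
  tr <- preg == 1 & !is.na(diag_w)
  G[tr] <- G[tr] * treatment_effect(pmax(0, week[tr] - diag_w[tr]),
                                    tx$m_full, tx$ramp_weeks)
  ref <- step_metabolism(B, E, G, dt, p)
  drift_fun <- dipsim:::make_drift_fun(p)
  bmi_ref_out <- pmax(12, bmi + (drift_fun(age) + p$bmi_secular) * dt +
                        z * p$bmi_noise_sd * sqrt(dt))

  B2 <- B + 0; E2 <- E + 0; bmi2 <- bmi + 0
  gsum2 <- gsum + 0; gn2 <- gn + 0
  dipsim:::.step_scan_cpp(seq_len(n), age, bmi2, B2, E2, s_base,
                          as.integer(preg), preg_t0, diag_w, gsum2, gn2,
                          rep(1, n), z, numeric(0), numeric(0),
                          rep(NA_real_, n), rep(NA_real_, n),
                          rep(NA_real_, n), runif(n),
                          rep(0, 35), 15, 50, dt * 52, t, dt, kern_par,
                          TRUE)
  expect_equal(B2, ref$B, tolerance = 1e-12)
  expect_equal(E2, ref$E, tolerance = 1e-12)
  expect_equal(bmi2, bmi_ref_out, tolerance = 1e-12)
  expect_equal(gsum2[preg == 1], G[preg == 1], tolerance = 1e-12)
  expect_equal(gn2[preg == 1], rep(1, sum(preg == 1)))
})
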