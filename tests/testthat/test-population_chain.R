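test_that("init_stocks reproduces the input table and rejects bad rows", {
  pop <- data.frame(age_band = "15-19", risk_group = "standard", count = 100)
  chain <- init_stocks(pop)
  expect_equal(chain$stocks["15-19", "standard"], 100)
  expect_equal(chain_total(chain), 100)

  expect_error(init_stocks(data.frame()), "non-empty")
  bad <- data.frame(age_band = c("15-19", "20-24"),
                    risk_group = "standard", count = c(10, -1))
  expect_error(init_stocks(bad), "row\\(s\\) 2")
})

test_that("synthetic population hits group totals exactly", {
  pop <- synthetic_population(10000, 0.2)
  expect_equal(sum(pop$count), 10000)
  expect_equal(sum(pop$count[pop$risk_group == "high_risk_ethnicity"]), 2000)
  chain <- init_stocks(pop)
  expect_equal(chain_total(chain), 10000)
  expect_equal(sum(chain$stocks[, "high_risk_ethnicity"]), 2000)
})

test_that("population CSV round-trips", {
  pop <- synthetic_population(500, 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  expect_equal(read_population(path), pop)
})

test_that("step_chain moves stock/residence*dt to the next band", {
  pop <- data.frame(age_band = "15-19", risk_group = "standard", count = 50)
  chain <- init_stocks(pop, entry_rate = c(0, 0),
                       exit_rate = rep(0, length(AGE_BANDS)))
  out <- step_chain(chain, 1)
  expect_equal(out$stocks["15-19", "standard"], 40)
  expect_equal(out$stocks["20-24", "standard"], 10)
  expect_equal(chain_total(out), 50)

  expect_error(step_chain(chain, 0), "positive")
  expect_error(step_chain(chain, -1), "positive")
})

test_that("infinite residence with zero rates leaves the chain unchanged", {
  pop <- synthetic_population(1000, 0.2)
  chain <- init_stocks(pop, entry_rate = c(0, 0),
                       exit_rate = rep(0, length(AGE_BANDS)),
                       residence = Inf)
  out <- step_chain(chain, 1)
  expect_equal(out$stocks, chain$stocks)
})

test_that("outflows are rescaled so no stock goes negative", {
  pop <- data.frame(age_band = "15-19", risk_group = "standard", count = 10)
  chain <- init_stocks(pop, entry_rate = c(0, 0),
                       exit_rate = rep(5, length(AGE_BANDS)))  # 5/yr demand
  out <- step_chain(chain, 1)
  expect_true(all(out$stocks >= 0))
  ## everything leaves, split between ageing and exits in proportion
  expect_equal(out$stocks["15-19", "standard"], 0)
  fl <- attr(out, "flows")
  expect_equal(fl$aging["15-19", "standard"] + fl$exits["15-19", "standard"],
               10)
})

test_that("person conservation holds to 1e-9 over long horizons", {
  pop <- synthetic_population(5000, 0.2)
  chain <- init_stocks(pop)
  total0 <- chain_total(chain)
  for (i in 1:1200) chain <- step_chain(chain, 1 / 12)  # 100 years
  balance <- chain_total(chain) + chain$cumulative_exits -
    chain$cumulative_entries
  expect_equal(balance, total0, tolerance = 1e-9)
})

test_that("stationary chain converges to a stable age distribution", {
  pop <- synthetic_population(10000, 0.2)
  chain <- init_stocks(pop)
  for (i in 1:200) chain <- step_chain(chain, 1)
  d200 <- rowSums(chain$stocks) / chain_total(chain)
  for (i in 1:10) chain <- step_chain(chain, 1)
  d210 <- rowSums(chain$stocks) / chain_total(chain)
  expect_lt(sum(abs(d210 - d200)), 0.01)
})

test_that("adips_high_risk implements the five-criterion screen", {
  expect_true(adips_high_risk(TRUE, 25, FALSE, FALSE, 22))
  expect_false(adips_high_risk(FALSE, 25, FALSE, FALSE, 22))
  expect_true(adips_high_risk(FALSE, 41, FALSE, FALSE, 22))
  expect_true(adips_high_risk(FALSE, 25, TRUE, FALSE, 22))
  expect_true(adips_high_risk(FALSE, 25, FALSE, TRUE, 22))
  expect_true(adips_high_risk(FALSE, 25, FALSE, FALSE, 35))
  expect_error(adips_high_risk(FALSE, -1, FALSE, FALSE, 22), "age")
  expect_error(adips_high_risk(FALSE, 25, FALSE, FALSE, 0), "bmi")
})

test_that("adips_high_risk is monotone in every risk attribute", {
  set.seed(42)
  for (i in 1:200) {
    eth <- runif(1) < 0.5; age <- runif(1, 15, 50)
    pg <- runif(1) < 0.5; fh <- runif(1) < 0.5; bmi <- runif(1, 18, 45)
    base <- adips_high_risk(eth, age, pg, fh, bmi)
    ## raising any attribute never flips TRUE -> FALSE
    expect_true(!base || adips_high_risk(TRUE, age, pg, fh, bmi))
    expect_true(!base || adips_high_risk(eth, 45, pg, fh, bmi))
    expect_true(!base || adips_high_risk(eth, age, TRUE, fh, bmi))
    expect_true(!base || adips_high_risk(eth, age, pg, TRUE, bmi))
    expect_true(!base || adips_high_risk(eth, age, pg, fh, bmi + 10))
  }
})

test_that("budding conserves persons and is reproducible", {
  pop <- synthetic_population(2000, 0.25)
  chain <- init_stocks(pop)
  total0 <- chain_total(chain)

  out <- bud_agents(chain, 10, seed = 7)
  expect_length(out$age, 10)
  expect_equal(chain_total(out$chain), total0 - 10)
  expect_equal(out$chain$agents_created, 10)
  expect_true(all(out$age >= 15 & out$age < 50))

  none <- bud_agents(chain, 0, seed = 7)
  expect_equal(none$chain$stocks, chain$stocks)
  expect_length(none$age, 0)

  again <- bud_agents(chain, 10, seed = 7)
  expect_identical(out$age, again$age)
  expect_identical(out$risk_group, again$risk_group)

  avail <- floor(sum(chain$stocks[4:10, ]))
  expect_error(bud_agents(chain, avail + 1), "available")
})
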