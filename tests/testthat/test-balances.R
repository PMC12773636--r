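# Printed resting-cell endpoint concentrations (mM), used across blocks.
resting_consumed <- c(glucose = 12.15)
resting_formed <- c(acetate = 13.62, succinate = 10.12, formate = 5.23,
                    lactate = 0.36, h2 = 5.05)

test_that("molar yields divide product deltas by primary substrate delta", {
  y <- molar_yields(resting_consumed, resting_formed, "glucose")
  expect_equal(round(unname(y["acetate"]), 2), 1.12)
  expect_equal(round(unname(y["succinate"]), 2), 0.83)
  expect_equal(unname(molar_yields(c(glucose = 10), c(acetate = 0),
                                   "glucose")["acetate"]), 0)
  expect_error(molar_yields(c(glucose = 0), c(acetate = 1), "glucose"),
               "consumption")
})

test_that("carbon recovery handles reference stoichiometries", {
  # exact homoacetogenesis: 6 C in, 3 x 2 C out
  expect_equal(carbon_recovery(c(glucose = 1), c(acetate = 3)), 100)
  expect_equal(carbon_recovery(c(glucose = 1), numeric(0)), 0)
  expect_error(carbon_recovery(c(glucose = 1), c(mystery = 1)),
               "not in registry")
  # net CO2 fixation pushes the CO2-exclusive recovery above 100%
  expect_gt(carbon_recovery(resting_consumed, resting_formed[1:4]), 100)
})

test_that("electron recovery is the gamma-weighted product/substrate ratio", {
  expect_equal(electron_recovery(c(glucose = 1), c(acetate = 3)), 100)
  expect_equal(electron_recovery(c(glucose = 1), c(lactate = 2)), 100)
  # CO counts among the substrates when supplied
  expect_equal(electron_recovery(c(glucose = 1, co = 2),
                                 c(acetate = 3, lactate = (2 * 2) / 12)),
               100)
})

test_that("recoveries are invariant under uniform concentration scaling", {
  for (k in c(0.1, 3, 42)) {
    expect_equal(carbon_recovery(k * resting_consumed, k * resting_formed),
                 carbon_recovery(resting_consumed, resting_formed))
    expect_equal(electron_recovery(k * resting_consumed, k * resting_formed),
                 electron_recovery(resting_consumed, resting_formed))
  }
})

test_that("element-balanced synthetic fermentations close at exactly 100%", {
  # products generated from an exact stoichiometry with CO2 tracked on the
  # consumed side (net CO2 fixation): recovery must be exact
  y <- yields_preset("resting_cells_closed")
  co2_in <- sum(c(2, 4, 3, 1, 0) * y) - 6          # net CO2 fixed per glucose
  k <- 9.7                                          # arbitrary mM scale
  cons <- c(glucose = k, co2 = k * co2_in)
  formd <- k * y
  expect_equal(carbon_recovery(cons, formd), 100, tolerance = 1e-9)
  expect_equal(electron_recovery(cons, formd), 100, tolerance = 1e-9)
})

test_that("carbon fractions follow yield * Cp / Cprimary", {
  cf <- carbon_fractions(c(formate = 0.15), "glucose")
  expect_equal(unname(cf["formate"]), 2.5)
  expect_equal(unname(carbon_fractions(c(acetate = 0.97), "glucose")),
               100 * 0.97 * 2 / 6)
  expect_equal(unname(carbon_fractions(c(acetate = 0), "glucose")), 0)
  # fractions of all carbon products reproduce the recovery
  y <- molar_yields(resting_consumed, resting_formed, "glucose")
  expect_equal(sum(carbon_fractions(y, "glucose")),
               carbon_recovery(resting_consumed, resting_formed))
})

test_that("balance equations render in canonical order and precision", {
  y <- c(acetate = 1.121, succinate = 0.8329, lactate = 0.0296,
         formate = 0.4305, h2 = 0.4156)
  expect_equal(render_balance_equation(y, "glucose"),
               "1glucose→1.12acetate+0.83succinate+0.03lactate+0.43formate+0.42H2")
  expect_equal(render_balance_equation(c(acetate = 1), "glucose"),
               "1glucose→1.00acetate")
  # zero coefficients kept only on request (an absent product can be the point)
  y2 <- c(acetate = 1.66, succinate = 0.86, lactate = 0.13, formate = 0)
  expect_false(grepl("formate", render_balance_equation(y2, "glucose")))
  eq <- render_balance_equation(y2, "glucose", include_zero = TRUE,
                                co_substrates = c(co = 1.57))
  expect_equal(eq,
               "1glucose+1.57CO→1.66acetate+0.86succinate+0.13lactate+0.00formate")
})

test_that("endpoint balances of time courses clamp transient intermediates", {
  tc <- simulate_resting_cells(yields = yields_preset("resting_cells"),
                               noise_cv = 0, seed = 1)
  b <- fermentation_balance(tc, "glucose")
  expect_equal(round(unname(b$yields[c("acetate", "succinate", "lactate",
                                       "formate", "h2")]), 2),
               c(1.12, 0.83, 0.03, 0.43, 0.41))
  # transient formate: endpoint delta 0, peak mode recovers the maximum
  tc2 <- simulate_resting_cells(
    yields = c(acetate = 1.66, succinate = 0.86, lactate = 0.13, formate = 0),
    formate_transient = list(peak = 5, t_peak = 5), noise_cv = 0, seed = 1)
  b_end <- suppressWarnings(fermentation_balance(tc2, "glucose"))
  expect_equal(unname(b_end$yields["formate"]), 0)
  b_peak <- fermentation_balance(tc2, "glucose", mode = "peak")
  expect_equal(unname(b_peak$yields["formate"]), 0.5)   # 5 mM / 10 mM glucose
})
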