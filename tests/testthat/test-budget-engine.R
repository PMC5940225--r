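test_that("CCA calcification is 0.018 * cover * 10 with domain guard", {
  expect_equal(cca_calcification(15), 2.7)
  expect_equal(cca_calcification(0), 0)
  expect_equal(cca_calcification(100), 18)
  expect_error(cca_calcification(120), "\\[0, 100\\]")
})

test_that("gross calcification follows the rugosity-corrected cover sum", {
  tr <- toy_traits()
  # r * (m * x/100 * d * g * 10): 1.5 * (0.4 * 1.4 * 0.8 * 10) = 6.72
  expect_equal(coral_calcification(c(A = 40), tr, 1.5), 6.72)
  expect_equal(coral_calcification(c(A = 0), tr, 1.5), 0)
  # linear in rugosity and in cover
  one <- coral_calcification(c(A = 20), tr, 1.2)
  expect_equal(coral_calcification(c(A = 20), tr, 2.4), 2 * one)
  expect_equal(coral_calcification(c(A = 40), tr, 1.2), 2 * one)
  # additive across taxa
  expect_equal(coral_calcification(c(A = 10, B = 5), tr, 1),
               coral_calcification(c(A = 10), tr, 1) +
                 coral_calcification(c(B = 5), tr, 1))
  # CCA term is inside the rugosity bracket
  expect_equal(coral_calcification(c(A = 0), tr, 1.5, cca_cover_pct = 10),
               1.5 * 1.8)
  expect_error(coral_calcification(c(ZZ = 10), tr, 1), "ZZ")
  expect_warning(
    v <- coral_calcification(c(ZZ = 10), tr, 1, permissive = TRUE),
    "generic")
  expect_gt(v, 0)
})

test_that("bite volume is the exponential allometry in cm^3", {
  expect_equal(bite_volume(30), exp(1.32 + 0.06 * 30) / 1000)
  expect_equal(bite_volume(1e-9), exp(1.32) / 1000, tolerance = 1e-6)
  expect_gt(bite_volume(40), bite_volume(30))
  expect_error(bite_volume(0), "> 0")
})

test_that("scar proportion is the logistic regression in length", {
  expect_equal(scar_proportion(2.46 / 0.089), 0.5)
  expect_equal(scar_proportion(30), 1 / (1 + exp(-(-2.46 + 0.089 * 30))))
  expect_equal(scar_proportion(1e-9), 1 / (1 + exp(2.46)), tolerance = 1e-6)
  expect_true(all(diff(scar_proportion(seq(5, 100, 5))) > 0))
})

test_that("bite rate is linear, decreasing in length, clamped at zero", {
  expect_equal(bite_rate(10, brc = 2), 60 * (5.95 - 4.05)) # 114
  expect_equal(bite_rate(30, brc = 0), 0) # raw -492 clamps
  lens <- seq(2, 20, 2)
  expect_true(all(diff(bite_rate(lens, brc = 5)) <= 0))
  expect_error(bite_rate(10, brc = NA), "brc")
})

test_that("parrotfish erosion chains the allometries and scales per area", {
  # independent arithmetic for 1 fish: brc 2, length 10, D 1.3, 120 m^2
  vol <- exp(1.32 + 0.06 * 10) / 1000
  sp <- 1 / (1 + exp(-(-2.46 + 0.089 * 10)))
  br <- 60 * ((4.31 + 2 - 0.36) - 0.045 * 9 * 10)
  expected <- vol * sp * br * 1.3 * 365 * 0.001 / 120
  expect_rel_equal(parrotfish_erosion(10, 2, 1.3, 120), expected)
  expect_equal(parrotfish_erosion(numeric(0), 2, 1.3, 120), 0)
  expect_equal(parrotfish_erosion(c(10, 10), 2, 1.3, 120),
               2 * parrotfish_erosion(10, 2, 1.3, 120))
})

test_that("urchin erosion follows genus allometries, monotone in diameter", {
  expect_rel_equal(urchin_erosion_individual("Diadema", 5),
                   1e-6 * 5^3.42 * 0.365 * 0.57)
  expect_rel_equal(urchin_erosion_individual("Echinometra", 3),
                   4e-4 * 3^1.98 * 0.365 * 0.57)
  expect_rel_equal(urchin_erosion_individual("Other", 4),
                   1e-4 * 4^2.32 * 0.365 * 0.57)
  expect_lt(urchin_erosion_individual("Diadema", 1e-4), 1e-10)
  for (g in c("Diadema", "Echinometra", "Other")) {
    expect_true(all(diff(urchin_erosion_individual(g, seq(1, 15))) > 0))
  }
  expect_error(urchin_erosion_individual("Tripneustes", 5), "genus_class")
  # belt-area normalisation and additivity across genera
  expect_rel_equal(urchin_erosion("Diadema", 5, area_m2 = 6),
                   1e-6 * 5^3.42 * 0.365 * 0.57 / 6)
  expect_equal(urchin_erosion(c("Diadema", "Echinometra"), c(5, 3), 6),
               urchin_erosion("Diadema", 5, 6) +
                 urchin_erosion("Echinometra", 3, 6))
  expect_equal(urchin_erosion(character(0), numeric(0), 6), 0)
})

test_that("macroboring erosion is proportion cover times the constant", {
  expect_equal(macroboring_erosion(0.0058), 0.058)
  expect_equal(macroboring_erosion(0.0044), 0.044)
  expect_equal(macroboring_erosion(0), 0)
  expect_error(macroboring_erosion(0.58 * 10), "proportion")
})

test_that("net production identity holds to machine precision", {
  cfg <- scenario_config(seed = 11)
  sim <- generate_survey_dataset(cfg)
  tb <- transect_budgets(sim$dataset)
  eros <- tb$parrotfish_erosion + tb$urchin_erosion + tb$macroboring_erosion
  expect_rel_equal(tb$net_production,
                   tb$gross_calcification + tb$sediment - eros, tol = 1e-12)
  sb <- site_budgets(sim$dataset)
  eros_s <- sb$parrotfish_erosion + sb$urchin_erosion + sb$macroboring_erosion
  expect_rel_equal(sb$net_production,
                   sb$gross_calcification + sb$sediment - eros_s, tol = 1e-12)
  expect_true(all(eros >= 0))
})

test_that("sediment sign switch flips the sediment term", {
  ds <- make_toy_dataset()
  hi <- budget_constants(sediment_sign = -1)
  lo <- budget_constants()
  a <- site_budgets(ds, constants = lo)
  b <- site_budgets(ds, constants = hi)
  expect_equal(b$net_production, a$net_production - 0.8)
})

test_that("alpha calibration inverts the quadratic conversion", {
  expect_equal(calibrate_alpha(9.7, 7.9), (7.9 / 9.7 - 1) / 9.7)
  expect_equal(calibrate_alpha(5, 5), 0)
  # two pairs consistent with one alpha reproduce it exactly
  a <- calibrate_alpha(9.7, 7.9)
  v2 <- 15 + a * 225
  expect_equal(calibrate_alpha(c(9.7, 15), c(7.9, v2)), a)
  expect_error(calibrate_alpha(0, 0), "unidentifiable")
})

test_that("vertical growth evaluates the parabola and clamps past the apex", {
  a <- calibrate_alpha(9.7, 7.9)
  expect_equal(vertical_growth(0, a), 0)
  expect_equal(vertical_growth(9.7, a), 7.9)
  expect_warning(v <- vertical_growth(40, a), "apex")
  apex <- -1 / (2 * a)
  expect_equal(v, apex + a * apex^2)
  # monotone over the calibrated domain
  expect_true(all(diff(vertical_growth(seq(0, 25, 0.5), a)) > 0))
})

test_that("keep-up verdicts compare growth with RCP sea-level-rise rates", {
  r <- keep_up_assessment(7.9, "RCP2.6")
  expect_true(r$keeps_up)
  expect_equal(r$margin_mm, 2.9)
  expect_false(keep_up_assessment(7.9, "RCP8.5")$keeps_up)
  expect_true(keep_up_assessment(6.5, "RCP4.5")$keeps_up) # tie keeps up
  expect_error(keep_up_assessment(7.9, "RCP3"), "unknown scenario")
})

test_that("budget constants are audited and unit-consistent", {
  k <- budget_constants()
  expect_equal(k$g_day_to_kg_yr, 0.365)
  expect_error(budget_constants(nonsense = 1), "unknown budget constant")
  k2 <- budget_constants(reeftime_h = 8)
  expect_equal(attr(k2, "overridden"), "reeftime_h")
  expect_lt(bite_rate(20, 5, k2), bite_rate(20, 5, budget_constants(reeftime_h = 7)))
})
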