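test_that("estimated daily intake follows the intake equation", {
  # all factors cancel except the conversion factor
  expect_equal(compute_edi(1, 0.085, 365, 1, 1, 1, 365), 0.085)
  # children central values: concentration 3.51 mg/kg, IR 0.0155 kg/day,
  # EF mode 345, ED midpoint 4 years, BW 32.7 kg, AT = 4 x 365 days
  expect_equal(compute_edi(3.51, 0.085, 345, 4, 0.0155, 32.7, 1460),
               1.3367069875581247e-4, tolerance = 1e-12)
  expect_equal(compute_edi(0, 0.085, 345, 4, 0.0155, 32.7, 1460), 0)
  expect_error(compute_edi(1, 0.085, 345, 4, 0.0155, 0, 1460), "bw")
  expect_error(compute_edi(1, 0.085, 345, 4, 0.0155, 32.7, -1), "at")
  expect_error(compute_edi(-1, 0.085, 345, 4, 0.0155, 32.7, 1460), ">= 0")
})

test_that("hazard quotient is intake over reference dose", {
  expect_equal(compute_thq(1.3367069875581247e-4, 0.004),
               0.033417674688953116, tolerance = 1e-12)
  expect_equal(compute_thq(0, 0.004), 0)
  expect_equal(compute_thq(0.004, 0.004), 1)
  expect_error(compute_thq(1, 0), "rfd")
})

test_that("hazard index is the exact sum of quotients", {
  expect_equal(compute_hi(c(0.1, 0.2, 0.3)), 0.6)
  expect_equal(compute_hi(numeric()), 0)
  expect_equal(compute_hi(rep(1 / 24, 24)), 1)
  expect_error(compute_hi(c(0.1, -0.2)), ">= 0")
})

test_that("point assessment satisfies the aggregation invariants", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  res <- point_risk_assessment(tabs$veg_iww, cfg, "children")
  expect_s3_class(res, "exposure_result")
  expect_equal(nrow(res$thq), 24)
  by_veg <- tapply(res$thq$thq, res$thq$vegetable, sum)
  expect_equal(res$hi_by_vegetable[names(by_veg)], c(by_veg))
  expect_equal(res$hi_total, sum(res$hi_by_vegetable))
  expect_true(all(res$edi$edi >= 0))
  expect_lt(res$hi_total, 1)
})

test_that("hazard is linear in the concentration table", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  base <- point_risk_assessment(tabs$veg_iww, cfg, "children")
  doubled <- as.data.frame(tabs$veg_iww)
  doubled$mean <- doubled$mean * 2
  res2 <- point_risk_assessment(concentration_table(doubled), cfg,
                                "children")
  expect_equal(res2$hi_total, 2 * base$hi_total)
  zeroed <- as.data.frame(tabs$veg_iww)
  zeroed$mean <- 0
  expect_equal(point_risk_assessment(concentration_table(zeroed), cfg,
                                     "children")$hi_total, 0)
})

test_that("adult point hazard exceeds children's on the IWW diet", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  hi_c <- point_risk_assessment(tabs$veg_iww, cfg, "children")$hi_total
  hi_a <- point_risk_assessment(tabs$veg_iww, cfg, "adults")$hi_total
  expect_gte(hi_a, hi_c)
})

test_that("configuration gaps are reported by name", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  extra <- rbind(as.data.frame(tabs$veg_iww), data.frame(
    medium = "vegetable", source = "IWW", item = "Ladyfinger",
    metal = "Cd", mean = 1, sd = 0, unit = "mg/kg dw"))
  expect_error(point_risk_assessment(concentration_table(extra), cfg,
                                     "children"),
               "no RfD for metal\\(s\\) 'Cd'")
  expect_error(point_risk_assessment(tabs$veg_iww, cfg, "infants"),
               "no population group 'infants'")
  # fixed literal averaging time is honoured
  cfg_at <- default_risk_config("IWW",
                                at_rule = list(rule = "fixed_days",
                                               days = 1460))
  res <- point_risk_assessment(tabs$veg_iww, cfg_at, "children")
  expect_equal(res$hi_total,
               point_risk_assessment(tabs$veg_iww,
                                     default_risk_config("IWW"),
                                     "children")$hi_total)
})
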