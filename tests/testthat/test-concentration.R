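test_that("packaged study tables load with the expected shape and values", {
  tabs <- study_tables()
  expect_equal(nrow(tabs$water), 12)   # 6 metals x 2 sources
  expect_equal(nrow(tabs$soil), 12)
  expect_equal(nrow(tabs$veg_iww), 24) # 4 vegetables x 6 metals
  expect_equal(nrow(tabs$veg_tww), 24)
  row <- subset(tabs$veg_iww, item == "Ladyfinger" & metal == "Pb")
  expect_equal(row$mean, 3.51)
  expect_equal(row$sd, 0.27)
  expect_identical(row$source, "IWW")
  expect_identical(unique(tabs$soil$unit), "mg/kg dw")
  expect_identical(unique(tabs$water$unit), "mg/l")
  for (tab in tabs) expect_length(validate_table(tab), 0)
})

test_that("an empty file with a valid header yields an empty table", {
  path <- write_temp_csv("medium,source,item,metal,mean,sd,unit")
  expect_equal(nrow(load_concentration_table(path)), 0)
})

test_that("schema and invariant violations are reported by name", {
  expect_error(
    load_concentration_table(write_temp_csv(c(
      "medium,source,item,metal,mean,unit",
      "soil,IWW,-,Pb,2.92,mg/kg dw"))),
    "missing column.*'sd'")
  expect_error(
    load_concentration_table(write_temp_csv(c(
      "medium,source,item,metal,mean,sd,unit",
      "soil,IWW,-,Pb,2.92,0.1,mg/kg dw",
      "soil,IWW,-,Cr,-1.0,0.1,mg/kg dw"))),
    "row 2: mean -1 < 0")
  expect_error(
    load_concentration_table(write_temp_csv(c(
      "medium,source,item,metal,mean,sd,unit",
      "vegetable,IWW,Onion,Fe,3.6,0.04,mg/kg dw",
      "vegetable,IWW,Onion,Fe,3.7,0.04,mg/kg dw"))),
    "duplicate key \\(vegetable, IWW, Onion, Fe\\)")
  expect_error(load_concentration_table(tempfile()), "not found")
})

test_that("validate_table returns violations instead of raising", {
  tab <- as.data.frame(study_tables()$veg_iww)
  expect_length(validate_table(tab), 0)
  dup <- rbind(tab, tab[13, ])  # duplicate an Onion row
  v <- validate_table(dup)
  expect_length(v, 1)
  expect_match(v, "duplicate key \\(vegetable, IWW, Onion, Fe\\)")
  neg <- tab; neg$sd[5] <- -0.2
  v <- validate_table(neg)
  expect_length(v, 1)
  expect_match(v, "row 5: sd -0.2 < 0")
})

test_that("written tables round-trip to identical records", {
  tab <- study_tables()$veg_iww
  tab$mean[1] <- tab$mean[1] * pi  # exercise full double precision
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_report(tab, path, fmt)
    back <- read_report(path)
    if (fmt == "json") back <- back$records
    expect_identical(back$mean, tab$mean)
    expect_identical(back$sd, tab$sd)
    expect_identical(back$item, tab$item)
  }
})

test_that("the shipped configuration reproduces the documented defaults", {
  cfg <- load_risk_config(hmrisk_example("default_config.yaml"))
  expect_equal(cfg, default_risk_config("IWW"))
  ch <- cfg$groups$children
  expect_equal(ch$ir$Ladyfinger, dist_normal(0.0155, 0.01))
  expect_equal(ch$ef, dist_triangular(180, 345, 365))
  expect_equal(ch$ed, dist_uniform(1, 7))
  expect_equal(ch$bw, dist_lognormal(32.7, cv = 0.10))
  expect_equal(cfg$groups$adults$ed, dist_uniform(26, 70))
  expect_equal(cfg$groups$adults$bw$mean, 73.5)
  expect_equal(ch$cf, 0.085)
  expect_equal(vapply(cfg$metals, `[[`, 0, "rfd"),
               c(Fe = 0.7, Pb = 0.004, Cr = 1.5, Ni = 0.02,
                 Mn = 0.033, Co = 0.090))
})

test_that("configuration errors name the problem", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "source: IWW", "vegetables: [kale]",
    "metals:", "  - {name: Pb, rfd: 0.004}",
    "groups:", "  - name: children",
    "    bw: {family: gamma, shape: 2}",
    "    ed: {family: uniform, min: 1, max: 7}",
    "    ef: {family: triangular, min: 180, mode: 345, max: 365}",
    "    ir:", "      kale: {family: normal, mean: 0.02, sd: 0.01}"), path)
  expect_error(load_risk_config(path), "unknown distribution family 'gamma'")
  expect_error(
    risk_config(list(metal_spec("Pb", 0.004)),
                list(population_group("g", dist_fixed(30),
                                      dist_fixed(4), dist_fixed(345),
                                      ir = list(kale = dist_fixed(0.02)))),
                vegetables = c("kale", "beet")),
    "no IR spec for 'beet'")
  expect_error(metal_spec("Pb", 0), "rfd must be > 0")
})

test_that("unsupported report formats are refused by name", {
  tab <- study_tables()$soil
  expect_error(write_report(tab, tempfile(), "xml"),
               "supported formats: csv, json")
})
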