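# Shared builders for small models with known ground truth.

study_tables <- function() {
  list(
    water = load_concentration_table(hmrisk_example("water.csv")),
    soil = load_concentration_table(hmrisk_example("soil.csv")),
    veg_iww = load_concentration_table(hmrisk_example("vegetables_iww.csv")),
    veg_tww = load_concentration_table(hmrisk_example("vegetables_tww.csv")))
}

# two vegetables x two metals, exact transfer ratios
tiny_synthetic_spec <- function(replicate_cv = 0, seed = 1) {
  tm <- matrix(c(1.2, 0.4, 0.8, 0.1), nrow = 2, byrow = TRUE,
               dimnames = list(c("kale", "beet"), c("Pb", "Cd")))
  synthetic_spec(metals = c("Pb", "Cd"), vegetables = c("kale", "beet"),
                 true_soil = c(Pb = 3, Cd = 0.5), true_mtf = tm,
                 replicate_cv = replicate_cv, seed = seed)
}

tiny_config <- function(bw = dist_fixed(30),
                        ed = dist_uniform(1, 7),
                        ef = dist_triangular(180, 345, 365),
                        ir_kale = dist_normal(0.02, 0.005),
                        ir_beet = dist_normal(0.01, 0.005),
                        at_rule = list(rule = "ed_times_365")) {
  risk_config(
    metals = list(metal_spec("Pb", 0.004), metal_spec("Cd", 0.001)),
    groups = list(population_group(
      "children", bw = bw, ed = ed, ef = ef,
      ir = list(kale = ir_kale, beet = ir_beet), at_rule = at_rule)),
    vegetables = c("kale", "beet"), source = "IWW")
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
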