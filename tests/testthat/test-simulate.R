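test_that("simulation is bit-reproducible given seed and iterations", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  a <- run_simulation(tabs$veg_iww, cfg, "children", n_iter = 500,
                      seed = 11)
  b <- run_simulation(tabs$veg_iww, cfg, "children", n_iter = 500,
                      seed = 11)
  expect_identical(a, b)
  c2 <- run_simulation(tabs$veg_iww, cfg, "children", n_iter = 500,
                       seed = 12)
  expect_false(identical(a$hi_total, c2$hi_total))
})

test_that("simulation result invariants hold", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  sim <- run_simulation(tabs$veg_iww, cfg, "adults", n_iter = 400,
                        seed = 3)
  expect_equal(length(sim$hi_total), 400)
  expect_equal(nrow(sim$inputs), 400)
  expect_equal(ncol(sim$inputs), 3 + 4 + 24)  # BW/ED/EF, IR per veg, C
  expect_equal(sim$hi_total, rowSums(sim$hi_by_vegetable))
  expect_true(all(sim$hi_total >= 0))
  expect_true(all(sim$inputs$BW > 0))
  expect_true(all(sim$inputs[paste0("IR.", cfg$vegetables)] > 0))
  one <- run_simulation(tabs$veg_iww, cfg, "children", n_iter = 1,
                        seed = 5)
  expect_length(one$hi_total, 1)
})

test_that("a fully degenerate model reproduces the point estimate exactly", {
  tabs <- study_tables()
  veg0 <- as.data.frame(tabs$veg_iww)
  veg0$sd <- 0   # degenerate concentration specs
  veg0 <- concentration_table(veg0)
  cfg0 <- generate_degenerate_config(default_risk_config("IWW"))
  for (grp in c("children", "adults")) {
    point <- point_risk_assessment(veg0, cfg0, grp)
    sim <- run_simulation(veg0, cfg0, grp, n_iter = 25, seed = 1)
    expect_identical(unique(sim$hi_total), point$hi_total)
  }
})

test_that("simulated mean hazard stays below 1 on the study fixtures", {
  tabs <- study_tables()
  sim <- run_simulation(tabs$veg_iww, default_risk_config("IWW"),
                        "children", n_iter = 10000, seed = 42)
  expect_lt(mean(sim$hi_total), 1)
})

test_that("forecast summaries match hand-computable cases", {
  s <- summarize_forecast(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$p50, 3)
  expect_equal(s$minimum, 1)
  expect_equal(s$maximum, 5)
  expect_equal(s$variance, s$sd^2)

  k <- summarize_forecast(rep(7, 10))
  expect_equal(k$sd, 0)
  expect_true(all(unlist(k[c("p5", "p50", "p90", "p95")]) == 7))

  # interpolated percentile against an order-statistic oracle:
  # rank h = 1 + (n - 1) p, linear between floor and ceiling
  x <- c(rep(0, 99), 1)
  oracle <- function(v, p) {
    v <- sort(v); h <- 1 + (length(v) - 1) * p
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  s2 <- summarize_forecast(x)
  expect_equal(s2$p90, oracle(x, 0.90))
  expect_equal(s2$p95, oracle(x, 0.95))
  y <- rlnorm(101, 0, 1)
  expect_equal(summarize_forecast(y)$p90, oracle(y, 0.90))
  expect_error(summarize_forecast(numeric()), "empty")

  # ordering invariant
  s3 <- summarize_forecast(rlnorm(500, 0, 0.5))
  with(s3, expect_true(minimum <= p5 && p5 <= p50 && p50 <= p90 &&
                         p90 <= p95 && p95 <= maximum))
})

test_that("convergence check is the max relative difference", {
  a <- summarize_forecast(c(1, 2, 3, 4, 5))
  expect_equal(as.numeric(convergence_check(a, a)), 0)
  b <- a; b$mean <- a$mean * 1.01
  d <- convergence_check(a, b)
  expect_equal(as.numeric(d), abs(a$mean - b$mean) / b$mean)
  expect_equal(unname(attr(d, "by_stat")["sd"]), 0)
  z <- summarize_forecast(rep(0, 5))
  expect_equal(as.numeric(convergence_check(z, z)), 0)
})

test_that("run-to-run disagreement shrinks with iteration count", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  disagreement <- function(n, seeds) {
    mean(vapply(seq_len(nrow(seeds)), function(i) {
      a <- summarize_forecast(run_simulation(
        tabs$veg_iww, cfg, "children", n, seed = seeds[i, 1])$hi_total)
      b <- summarize_forecast(run_simulation(
        tabs$veg_iww, cfg, "children", n, seed = seeds[i, 2])$hi_total)
      as.numeric(convergence_check(a, b))
    }, 0))
  }
  seeds <- matrix(derive_seeds(2024, 6), ncol = 2)
  expect_gt(disagreement(400, seeds), disagreement(8000, seeds))
})

test_that("doubling every concentration doubles the hazard distribution", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  base <- run_simulation(tabs$veg_iww, cfg, "children", n_iter = 300,
                         seed = 9)
  doubled <- as.data.frame(tabs$veg_iww)
  doubled$mean <- 2 * doubled$mean
  doubled$sd <- 2 * doubled$sd
  sim2 <- run_simulation(concentration_table(doubled), cfg, "children",
                         n_iter = 300, seed = 9)
  expect_equal(sim2$hi_total, 2 * base$hi_total)  # same seed, scaled draws
  q <- seq(0.01, 0.99, by = 0.01)  # stochastic dominance
  expect_true(all(quantile(sim2$hi_total, q) >= quantile(base$hi_total, q)))
})

test_that("sampler failures carry the parameter name", {
  tabs <- study_tables()
  cfg <- default_risk_config("IWW")
  cfg$groups$children$ir$Onion <- structure(
    list(family = "gamma", shape = 1), class = "dist_spec")
  expect_error(run_simulation(tabs$veg_iww, cfg, "children", 10, 1),
               "IR.Onion")
})
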