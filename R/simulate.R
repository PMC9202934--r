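#' Monte Carlo simulation of the hazard index
#'
#' Propagates input uncertainty through the EDI/THQ/HI chain. Each
#' iteration simulates one individual: a single body weight, exposure
#' duration and exposure frequency draw shared across all vegetables and
#' metals, one ingestion-rate draw per vegetable, and one concentration
#' draw per (vegetable, metal) cell (lognormal, moment-matched to the
#' table's mean and sd). Averaging time follows the group's `at_rule`.
#'
#' Draw order is fixed (BW, ED, EF, then IR per vegetable in config order,
#' then concentrations vegetable-major in metal config order) under a
#' single `set.seed(seed)`, so a result is bit-reproducible given
#' `(seed, n_iter)` and identical inputs. The caller's RNG state is
#' preserved.
#'
#' @param veg A [concentration_table] of vegetable concentrations.
#' @param config A [risk_config()] covering the table.
#' @param group Population group name.
#' @param n_iter Number of iterations (>= 1); 10,000 is the default, which
#'   is where independent runs of the default models typically stabilize.
#' @param seed Integer seed.
#' @return A `simulation_result`: list with `n_iter`, `seed`, `group`,
#'   `source`, `inputs` (data frame of every sampled parameter per
#'   iteration, columns `BW`, `ED`, `EF`, `IR.<vegetable>`,
#'   `C.<vegetable>.<metal>`), `hi_by_vegetable` (matrix `n_iter` x
#'   vegetables) and `hi_total` (length `n_iter`).
#' @examples
#' veg <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' sim <- run_simulation(veg, default_risk_config("IWW"), "children",
#'                       n_iter = 1000, seed = 42)
#' summarize_forecast(sim$hi_total)
#' @export
run_simulation <- function(veg, config, group, n_iter = 10000, seed = 1) {
  stopifnot(inherits(config, "risk_config"), n_iter >= 1)
  veg <- as_concentration_table(veg)
  g <- group_or_stop(config, group)
  cm <- conc_matrix(veg, config)
  rfd <- vapply(config$metals, `[[`, 0, "rfd")
  n <- as.integer(n_iter)

  old <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (!is.null(get0(".Random.seed", globalenv())))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)

  draw_named <- function(spec, what) {
    tryCatch(draw_spec(spec, n), error = function(e) {
      stop(sprintf("sampling '%s': %s", what, conditionMessage(e)),
           call. = FALSE)
    })
  }
  bw <- draw_named(g$bw, "BW")
  ed <- draw_named(g$ed, "ED")
  ef <- draw_named(g$ef, "EF")
  at <- if (g$at_rule$rule == "ed_times_365") ed * 365 else
    rep.int(g$at_rule$days, n)
  nv <- length(config$vegetables)
  nm <- length(cm$metals)
  ir <- matrix(0, n, nv, dimnames = list(NULL, config$vegetables))
  for (j in seq_len(nv)) {
    v <- config$vegetables[j]
    ir[, j] <- draw_named(g$ir[[v]], paste0("IR.", v))
  }
  conc <- matrix(0, n, nv * nm)
  for (k in seq_len(nv * nm)) {
    spec <- dist_lognormal(max(cm$mean[1, k], .Machine$double.xmin),
                           sd = cm$sd[k])
    if (cm$mean[1, k] == 0) spec <- dist_fixed(0)  # zero concentration
    conc[, k] <- draw_named(
      spec, paste0("C.", cm$cells$vegetable[k], ".", cm$cells$metal[k]))
  }

  kr <- hi_kernel(conc, g$cf, ef, ed, ir, bw, at, rfd,
                  config$vegetables, cm$metals)
  inputs <- data.frame(BW = bw, ED = ed, EF = ef, check.names = FALSE)
  inputs[paste0("IR.", config$vegetables)] <- as.data.frame(ir)
  inputs[paste0("C.", cm$cells$vegetable, ".", cm$cells$metal)] <-
    as.data.frame(conc)
  structure(list(n_iter = n, seed = as.integer(seed), group = group,
                 source = config$source, inputs = inputs,
                 hi_by_vegetable = kr$hi_by_vegetable,
                 hi_total = kr$hi_total),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s/%s, %d iterations (seed %d)\n",
    x$group, x$source, x$n_iter, x$seed))
  print(summarize_forecast(x$hi_total))
  invisible(x)
}

#' Summary statistics of a simulated forecast
#'
#' Moments and order statistics of a forecast vector. Percentiles use
#' linear interpolation between order statistics (`stats::quantile`
#' type 7: the p-th percentile sits at rank `1 + (n - 1) p`, interpolated
#' linearly between the neighbouring sorted values).
#'
#' @param values Non-empty numeric vector (e.g. `hi_total` of a
#'   [run_simulation()] result).
#' @return A `summary_stats` object: named list with `mean`, `sd`,
#'   `variance`, `minimum`, `maximum`, `p5`, `p50`, `p90`, `p95`.
#' @export
summarize_forecast <- function(values) {
  if (!length(values)) stop("cannot summarize an empty vector",
                            call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.5, 0.9, 0.95), names = FALSE,
                       type = 7)
  s <- if (length(values) > 1) stats::sd(values) else 0
  structure(list(mean = mean(values), sd = s, variance = s^2,
                 minimum = min(values), maximum = max(values),
                 p5 = q[1], p50 = q[2], p90 = q[3], p95 = q[4]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  v <- unlist(x)
  cat("<summary_stats>\n")
  print(signif(v, 4))
  invisible(x)
}

#' Convergence check between two forecast summaries
#'
#' The stability diagnostic for independent Monte Carlo runs: the maximum
#' over `{mean, sd, variance, p90, p95}` of the relative difference
#' `|a - b| / max(|a|, |b|)` (0 when both are 0). Two runs are declared
#' converged at the 1% level when this maximum is <= 0.01.
#'
#' @param a,b `summary_stats` objects from [summarize_forecast()] in the
#'   same units.
#' @return The maximum relative difference (a fraction), with the
#'   per-statistic breakdown in the `by_stat` attribute.
#' @export
convergence_check <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  stats_used <- c("mean", "sd", "variance", "p90", "p95")
  d <- vapply(stats_used, function(s) {
    x <- a[[s]]; y <- b[[s]]
    m <- max(abs(x), abs(y))
    if (m == 0) 0 else abs(x - y) / m
  }, 0)
  structure(max(d), by_stat = d)
}
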