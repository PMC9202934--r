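#' Specification for synthetic concentration data
#'
#' Describes a ground-truth contamination scenario: true soil
#' concentrations per metal and true soil-to-plant transfer ratios per
#' (vegetable, metal). [generate_concentration_table()] emulates the field
#' workflow — each reported concentration is the sample mean and sd of
#' `n_replicates` instrument measurements with lognormal between-replicate
#' noise of coefficient of variation `replicate_cv`.
#'
#' @param metals Character vector of metal names.
#' @param vegetables Character vector of vegetable names.
#' @param true_soil Named numeric: true soil concentration per metal
#'   (mg/kg dw, > 0).
#' @param true_mtf Numeric matrix `vegetables x metals` of true transfer
#'   ratios (> 0), with dimnames.
#' @param replicate_cv Between-replicate coefficient of variation (>= 0).
#' @param n_replicates Replicates per measurement (default 3).
#' @param seed Integer seed.
#' @param source Source label stamped on the generated tables.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(metals, vegetables, true_soil, true_mtf,
                           replicate_cv = 0.05, n_replicates = 3,
                           seed = 1, source = "IWW") {
  stopifnot(length(metals) >= 1, length(vegetables) >= 1)
  if (!all(metals %in% names(true_soil))) {
    stop("true_soil must name every metal", call. = FALSE)
  }
  if (any(true_soil[metals] <= 0)) {
    stop("true soil concentrations must be > 0", call. = FALSE)
  }
  if (!is.matrix(true_mtf) ||
      !all(vegetables %in% rownames(true_mtf)) ||
      !all(metals %in% colnames(true_mtf))) {
    stop("true_mtf must be a vegetables x metals matrix with dimnames",
         call. = FALSE)
  }
  if (any(true_mtf[vegetables, metals] <= 0)) {
    stop("true transfer ratios must be > 0", call. = FALSE)
  }
  if (replicate_cv < 0) stop("replicate_cv must be >= 0", call. = FALSE)
  if (n_replicates < 2 && replicate_cv > 0) {
    stop("need n_replicates >= 2 to estimate an sd", call. = FALSE)
  }
  structure(list(metals = metals, vegetables = vegetables,
                 true_soil = true_soil[metals],
                 true_mtf = true_mtf[vegetables, metals, drop = FALSE],
                 replicate_cv = replicate_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), source = source),
            class = "synthetic_spec")
}

#' Generate soil and vegetable concentration tables with known truth
#'
#' The true vegetable concentration is `true_soil[m] * true_mtf[v, m]`;
#' the reported mean/sd per cell are the sample mean and sd of
#' `n_replicates` lognormal draws around the true value with coefficient
#' of variation `replicate_cv` (`replicate_cv = 0` reports the true means
#' exactly with sd 0). Deterministic given the spec's seed; the caller's
#' RNG state is preserved.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `soil` and `veg`, both
#'   [concentration_table]s in the standard schema.
#' @examples
#' tmf <- matrix(c(1.2, 0.4, 0.8, 0.1), 2, 2,
#'               dimnames = list(c("kale", "beet"), c("Pb", "Cd")))
#' sp <- synthetic_spec(c("Pb", "Cd"), c("kale", "beet"),
#'                      c(Pb = 3, Cd = 0.5), tmf, replicate_cv = 0)
#' tabs <- generate_concentration_table(sp)
#' compute_mtf(tabs$veg, tabs$soil, "IWW")
#' @export
generate_concentration_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) {
      if (!is.null(get0(".Random.seed", globalenv())))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)
  measure <- function(truth) {
    if (spec$replicate_cv == 0) return(c(mean = truth, sd = 0))
    reps <- draw_spec(dist_lognormal(truth, cv = spec$replicate_cv),
                      spec$n_replicates)
    c(mean = mean(reps), sd = stats::sd(reps))
  }
  soil_rows <- do.call(rbind, lapply(spec$metals, function(m) {
    ms <- measure(spec$true_soil[[m]])
    data.frame(medium = "soil", source = spec$source, item = "-",
               metal = m, mean = ms[["mean"]], sd = ms[["sd"]],
               unit = "mg/kg dw", stringsAsFactors = FALSE)
  }))
  veg_rows <- do.call(rbind, lapply(spec$vegetables, function(v) {
    do.call(rbind, lapply(spec$metals, function(m) {
      ms <- measure(spec$true_soil[[m]] * spec$true_mtf[v, m])
      data.frame(medium = "vegetable", source = spec$source, item = v,
                 metal = m, mean = ms[["mean"]], sd = ms[["sd"]],
                 unit = "mg/kg dw", stringsAsFactors = FALSE)
    }))
  }))
  list(soil = concentration_table(soil_rows),
       veg = concentration_table(veg_rows))
}

#' Replace every distribution by a point mass at its central value
#'
#' Degenerates a configuration using the same central-value rule as the
#' point estimate ([central_value()]). A simulation run under the
#' degenerate configuration reproduces [point_risk_assessment()] exactly,
#' which anchors the Monte Carlo engine to the deterministic model.
#'
#' @param base A [risk_config()].
#' @return A [risk_config()] in which every spec is `fixed`.
#' @export
generate_degenerate_config <- function(base) {
  stopifnot(inherits(base, "risk_config"))
  groups <- lapply(base$groups, function(g) {
    population_group(
      g$name,
      bw = dist_fixed(central_value(g$bw)),
      ed = dist_fixed(central_value(g$ed)),
      ef = dist_fixed(central_value(g$ef)),
      ir = lapply(g$ir, function(s) dist_fixed(central_value(s))),
      cf = g$cf, at_rule = g$at_rule)
  })
  risk_config(base$metals, groups, base$vegetables, base$source)
}

#' Closed-form expected hazard index under independent inputs
#'
#' Validation oracle for the Monte Carlo engine. When body weight is
#' degenerate (and averaging time is either fixed or given by the
#' AT = ED x 365 rule, under which ED cancels), the expected simulated
#' mean HI is the product of the factor expectations summed over cells:
#' `E[HI] = sum_{v,m} E[C] cf E[EF] (ED term) E[IR_v] / (BW * RfD_m * AT)`
#' using `E[XY] = E[X] E[Y]` for independent draws. Factor expectations
#' come from [dist_mean()], so the zero-truncation of normal ingestion
#' rates is accounted for.
#'
#' @param veg A [concentration_table] of vegetable concentrations.
#' @param config A [risk_config()] covering the table.
#' @param group Population group name.
#' @return The exact expected value of the simulated mean `hi_total`.
#' @export
analytic_mean_hi <- function(veg, config, group) {
  stopifnot(inherits(config, "risk_config"))
  veg <- as_concentration_table(veg)
  g <- group_or_stop(config, group)
  if (!is_degenerate(g$bw)) {
    stop(paste("analytic_mean_hi needs a degenerate body-weight spec:",
               "E[1/BW] has no product closed form"), call. = FALSE)
  }
  cm <- conc_matrix(veg, config)
  rfd <- vapply(config$metals, `[[`, 0, "rfd")
  ed_over_at <- if (g$at_rule$rule == "ed_times_365") {
    1 / 365  # ED cancels exactly inside every iteration
  } else {
    dist_mean(g$ed) / g$at_rule$days
  }
  bw <- dist_mean(g$bw)
  ir_mean <- vapply(config$vegetables, function(v) dist_mean(g$ir[[v]]), 0)
  cell_ir <- ir_mean[cm$cells$vegetable]
  cell_rfd <- rfd[cm$cells$metal]
  sum(cm$mean[1, ] * g$cf * dist_mean(g$ef) * ed_over_at * cell_ir /
        (bw * cell_rfd))
}
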