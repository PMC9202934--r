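#' Estimated daily intake of a metal through one food item
#'
#' `EDI = c_metal * cf * ef * ed * ir / (bw * at)` in mg metal per kg body
#' weight per day, where `c_metal` is the dry-weight concentration in the
#' item (mg/kg), `cf` the fresh-to-dry conversion factor, `ef` the exposure
#' frequency (days/year), `ed` the exposure duration (years), `ir` the
#' fresh-weight ingestion rate (kg/day), `bw` the body weight (kg) and `at`
#' the averaging time (days). All arguments recycle vectorized.
#'
#' @param c_metal,cf,ef,ed,ir Non-negative numerics.
#' @param bw,at Strictly positive numerics.
#' @return EDI in mg/kg bw/day.
#' @examples
#' compute_edi(3.51, 0.085, 345, 4, 0.0155, 32.7, 4 * 365)
#' @export
compute_edi <- function(c_metal, cf, ef, ed, ir, bw, at) {
  if (any(bw <= 0)) stop("bw must be > 0", call. = FALSE)
  if (any(at <= 0)) stop("at must be > 0", call. = FALSE)
  if (any(c(c_metal, cf, ef, ed, ir) < 0)) {
    stop("concentration and exposure factors must be >= 0", call. = FALSE)
  }
  c_metal * cf * ef * ed * ir / (bw * at)
}

#' Target hazard quotient
#'
#' `THQ = EDI / RfD`; values above 1 flag potential non-carcinogenic risk.
#'
#' @param edi Estimated daily intake, mg/kg bw/day.
#' @param rfd Oral reference dose, mg/kg bw/day (> 0).
#' @return Dimensionless hazard quotient.
#' @export
compute_thq <- function(edi, rfd) {
  if (any(rfd <= 0)) stop("rfd must be > 0", call. = FALSE)
  edi / rfd
}

#' Hazard index
#'
#' The exact sum of a collection of target hazard quotients; an empty
#' collection gives 0.
#'
#' @param thqs Numeric vector of THQ values (all >= 0).
#' @return Dimensionless hazard index.
#' @export
compute_hi <- function(thqs) {
  if (length(thqs) == 0) return(0)
  if (any(thqs < 0)) stop("THQ values must be >= 0", call. = FALSE)
  sum(thqs)
}

# Shared hazard kernel: given per-iteration (or scalar) parameter values,
# compute EDI/THQ per (vegetable, metal) cell and the HI aggregates.
# `conc` is an n x (V*M) matrix with columns ordered vegetable-major
# (all metals of vegetable 1, then vegetable 2, ...); `ir` is n x V.
# Both the point estimate and the Monte Carlo engine run through this
# kernel, so a degenerate simulation reproduces the point estimate exactly.
hi_kernel <- function(conc, cf, ef, ed, ir, bw, at, rfd, vegetables,
                      metals) {
  nv <- length(vegetables); nm <- length(metals)
  n <- nrow(conc)
  scale <- cf * ef * ed / (bw * at)        # length n (or 1)
  edi <- conc * (scale * ir[, rep(seq_len(nv), each = nm), drop = FALSE])
  thq <- sweep(edi, 2L, rep(rfd[metals], times = nv), `/`)
  hi_veg <- matrix(0, n, nv, dimnames = list(NULL, vegetables))
  for (j in seq_len(nv)) {
    hi_veg[, j] <- rowSums(thq[, (j - 1) * nm + seq_len(nm), drop = FALSE])
  }
  list(edi = edi, thq = thq, hi_by_vegetable = hi_veg,
       hi_total = rowSums(hi_veg))
}

# concentration means of `veg` arranged as the kernel's 1 x (V*M) matrix,
# plus matching sds; errors if a (vegetable, metal) cell is absent.
conc_matrix <- function(veg, config) {
  v <- veg[veg$medium == "vegetable" & veg$source == config$source, ,
           drop = FALSE]
  if (!nrow(v)) {
    stop(sprintf("no vegetable records for source '%s'", config$source),
         call. = FALSE)
  }
  check_config_covers(v, config)
  metals <- names(config$metals)
  cells <- expand.grid(metal = metals, vegetable = config$vegetables,
                       stringsAsFactors = FALSE)  # vegetable-major order
  key <- paste(v$item, v$metal, sep = "|")
  idx <- match(paste(cells$vegetable, cells$metal, sep = "|"), key)
  if (anyNA(idx)) {
    gap <- cells[is.na(idx), ]
    stop(sprintf("missing concentration for %s",
                 paste(sprintf("(%s, %s)", gap$vegetable, gap$metal),
                       collapse = ", ")), call. = FALSE)
  }
  list(mean = matrix(v$mean[idx], nrow = 1), sd = v$sd[idx],
       cells = cells, metals = metals)
}

group_or_stop <- function(config, group) {
  g <- config$groups[[group]]
  if (is.null(g)) {
    stop(sprintf("config error: no population group '%s' (have: %s)",
                 group, paste(names(config$groups), collapse = ", ")),
         call. = FALSE)
  }
  g
}

#' Deterministic point-estimate risk assessment
#'
#' Evaluates EDI, THQ and HI over every (vegetable, metal) pair using each
#' distribution's central value ([central_value()]): mean for normal,
#' arithmetic mean for lognormal, mode for triangular, midpoint for
#' uniform. The fresh-to-dry factor applies to the vegetable
#' concentrations; averaging time follows the group's `at_rule`.
#'
#' @param veg A [concentration_table] of vegetable concentrations.
#' @param config A [risk_config()] covering the table.
#' @param group Population group name, e.g. `"children"`.
#' @return An `exposure_result`: list with `group`, `source`, data frames
#'   `edi` and `thq` keyed by (vegetable, metal), `hi_by_vegetable` (named
#'   numeric) and `hi_total`.
#' @examples
#' veg <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' point_risk_assessment(veg, default_risk_config("IWW"), "children")
#' @export
point_risk_assessment <- function(veg, config, group) {
  stopifnot(inherits(config, "risk_config"))
  veg <- as_concentration_table(veg)
  g <- group_or_stop(config, group)
  cm <- conc_matrix(veg, config)
  rfd <- vapply(config$metals, `[[`, 0, "rfd")
  ed <- central_value(g$ed)
  at <- if (g$at_rule$rule == "ed_times_365") ed * 365 else g$at_rule$days
  ir <- matrix(vapply(config$vegetables,
                      function(v) central_value(g$ir[[v]]), 0),
               nrow = 1, dimnames = list(NULL, config$vegetables))
  k <- hi_kernel(cm$mean, g$cf, central_value(g$ef), ed, ir,
                 central_value(g$bw), at, rfd, config$vegetables,
                 cm$metals)
  res <- data.frame(vegetable = cm$cells$vegetable,
                    metal = cm$cells$metal,
                    edi = as.numeric(k$edi), thq = as.numeric(k$thq),
                    stringsAsFactors = FALSE)
  structure(list(group = group, source = config$source,
                 edi = res[c("vegetable", "metal", "edi")],
                 thq = res[c("vegetable", "metal", "thq")],
                 hi_by_vegetable = k$hi_by_vegetable[1, ],
                 hi_total = k$hi_total[1]),
            class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("<exposure_result> group %s, source %s\n", x$group, x$source))
  cat("HI by vegetable:\n")
  print(signif(x$hi_by_vegetable, 4))
  cat(sprintf("HI total: %.4g (%s)\n", x$hi_total,
              if (x$hi_total < 1) "below the safety threshold of 1"
              else "ABOVE the safety threshold of 1"))
  invisible(x)
}
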