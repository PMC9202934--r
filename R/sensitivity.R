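#' Spearman rank-order correlation
#'
#' Pearson correlation of average ranks; invariant under strictly monotone
#' transforms of either argument, ties handled by average ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` when either input has zero
#'   variance (flagged with attribute `zero_variance`).
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(NA_real_, zero_variance = TRUE))
  }
  stats::cor(rank(x), rank(y))
}

#' Contribution of each stochastic input to forecast variance
#'
#' The rank-correlation-squared attribution used by spreadsheet Monte
#' Carlo tools: for each recorded input parameter p,
#' `contribution(p) = 100 * rho(p)^2 / sum_q rho(q)^2`, where `rho` is the
#' Spearman correlation between the input's draws and the output. The
#' signed correlations are retained alongside. Inputs with zero variance
#' (degenerate specs) contribute 0.
#'
#' Because the attribution works on ranks it is invariant to relabeling
#' and to strictly monotone rescaling of any input.
#'
#' @param inputs Data frame (or named list) of per-iteration input draws,
#'   e.g. the `inputs` element of [run_simulation()]; at least 2 inputs.
#' @param output Numeric forecast vector, same length as the inputs.
#' @param output_name Label for the forecast.
#' @return A `sensitivity_result`: list with `contributions` (named, in
#'   percent, summing to 100 unless degenerate), `rho` (named, signed),
#'   `output_name`, and `degenerate` (`TRUE` when every rho is 0 or
#'   undefined, in which case contributions are all 0).
#' @seealso [pool_contributions()] to aggregate related inputs (e.g. the
#'   per-vegetable ingestion rates).
#' @examples
#' veg <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' sim <- run_simulation(veg, default_risk_config("IWW"), "children",
#'                       n_iter = 2000, seed = 1)
#' sens <- contribution_to_variance(sim$inputs, sim$hi_total)
#' pool_contributions(sens, "^IR\\.")
#' @export
contribution_to_variance <- function(inputs, output,
                                     output_name = "hi_total") {
  inputs <- as.data.frame(inputs, check.names = FALSE)
  if (ncol(inputs) < 2) stop("need at least 2 inputs", call. = FALSE)
  if (any(lengths(inputs) != length(output))) {
    stop("every input must have the length of the output", call. = FALSE)
  }
  rho <- vapply(inputs, function(x) as.numeric(spearman_rho(x, output)), 0)
  r2 <- ifelse(is.na(rho), 0, rho^2)
  degenerate <- sum(r2) == 0
  contributions <- if (degenerate) r2 else 100 * r2 / sum(r2)
  structure(list(contributions = contributions, rho = rho,
                 output_name = output_name, degenerate = degenerate),
            class = "sensitivity_result")
}

#' Pool contributions of related inputs
#'
#' Sums the percent contributions of all inputs whose name matches a
#' regular expression — e.g. `"^IR\\."` pools the per-vegetable ingestion
#' rates into the single ingestion-rate figure usually reported.
#'
#' @param result A `sensitivity_result`.
#' @param pattern Regular expression matched against input names.
#' @return Summed contribution in percent.
#' @export
pool_contributions <- function(result, pattern) {
  stopifnot(inherits(result, "sensitivity_result"))
  sum(result$contributions[grepl(pattern, names(result$contributions))])
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> forecast %s%s\n", x$output_name,
              if (x$degenerate) " (degenerate: no stochastic input)" else ""))
  ord <- order(-x$contributions)
  df <- data.frame(input = names(x$contributions)[ord],
                   contribution_pct = signif(x$contributions[ord], 4),
                   rho = signif(x$rho[ord], 4), row.names = NULL)
  print(utils::head(df, 10))
  if (nrow(df) > 10) cat(sprintf("... and %d more inputs\n", nrow(df) - 10))
  invisible(x)
}
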