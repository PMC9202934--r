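#' Soil-to-plant metal transfer factors
#'
#' The metal transfer factor of metal m in vegetable v is the dimensionless
#' ratio of its mean concentration in the edible plant part to its mean
#' concentration in the soil that grew it, under the same irrigation
#' source: `MTF(v, m) = C_plant(v, m) / C_soil(m)`. Values above 1 indicate
#' net accumulation in the plant. Only the mean concentrations enter; the
#' replicate standard deviations are not propagated.
#'
#' @param veg A [concentration_table] with `medium == "vegetable"` rows for
#'   `source`.
#' @param soil A [concentration_table] with `medium == "soil"` rows for
#'   `source`; every metal present in `veg` must have soil mean > 0.
#' @param source Irrigation source, `"IWW"` or `"TWW"`.
#' @return An `mtf_table`: a data frame with columns `vegetable`, `metal`,
#'   `mtf` (full floating precision) and attribute `source`.
#' @examples
#' soil <- load_concentration_table(hmrisk_example("soil.csv"))
#' veg <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' mtf <- compute_mtf(veg, soil, "IWW")
#' subset(mtf, mtf > 1)
#' @export
compute_mtf <- function(veg, soil, source = c("IWW", "TWW")) {
  source <- match.arg(source)
  veg <- as_concentration_table(veg)
  soil <- as_concentration_table(soil)
  v <- veg[veg$medium == "vegetable" & veg$source == source, , drop = FALSE]
  s <- soil[soil$medium == "soil" & soil$source == source, , drop = FALSE]
  if (!nrow(v)) stop(sprintf("no vegetable records for source '%s'", source),
                     call. = FALSE)
  if (!nrow(s)) stop(sprintf("no soil records for source '%s'", source),
                     call. = FALSE)
  smean <- stats::setNames(s$mean, s$metal)
  gap <- setdiff(unique(v$metal), names(smean))
  if (length(gap)) {
    stop(sprintf("no soil concentration for metal(s) %s (source %s)",
                 paste(sQuote(gap), collapse = ", "), source), call. = FALSE)
  }
  zero <- names(smean)[smean == 0 & names(smean) %in% v$metal]
  if (length(zero)) {
    stop(sprintf("undefined transfer ratio: soil mean is 0 for metal(s) %s",
                 paste(sQuote(zero), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(vegetable = v$item, metal = v$metal,
                    mtf = v$mean / smean[v$metal],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, source = source,
            class = c("mtf_table", "data.frame"))
}

#' Rank a vegetable's metals by transfer factor
#'
#' @param table An `mtf_table` from [compute_mtf()].
#' @param vegetable Vegetable name present in the table.
#' @return Character vector of metals sorted by decreasing MTF; exact ties
#'   fall back to alphabetical order and are flagged in the `ties`
#'   attribute. The sorted MTF values are attached as the `mtf` attribute.
#' @examples
#' soil <- load_concentration_table(hmrisk_example("soil.csv"))
#' veg <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' rank_mtf(compute_mtf(veg, soil, "IWW"), "Pumpkin")
#' @export
rank_mtf <- function(table, vegetable) {
  stopifnot(inherits(table, "mtf_table"))
  rows <- table[table$vegetable == vegetable, , drop = FALSE]
  if (!nrow(rows)) {
    stop(sprintf("vegetable '%s' not present in MTF table", vegetable),
         call. = FALSE)
  }
  ord <- order(-rows$mtf, rows$metal)
  metals <- rows$metal[ord]
  vals <- stats::setNames(rows$mtf[ord], metals)
  structure(metals, mtf = vals, ties = anyDuplicated(rows$mtf) > 0)
}

#' @export
print.mtf_table <- function(x, ...) {
  cat(sprintf("<mtf_table> source %s; %d entries, %d above 1\n",
              attr(x, "source"), nrow(x), sum(x$mtf > 1)))
  shown <- x
  shown$mtf <- signif(shown$mtf, 4)  # display only; stored at full precision
  print.data.frame(shown, ...)
  invisible(x)
}
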