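#' Concentration tables
#'
#' A `concentration_table` is a long-format data frame of mean +/- sd heavy
#' metal concentrations keyed by `(medium, source, item, metal)`:
#' * `medium` — `"water"`, `"soil"` or `"vegetable"`;
#' * `source` — irrigation water source, `"IWW"` (industrial wastewater) or
#'   `"TWW"` (tube well water);
#' * `item` — vegetable name, or `"-"` for water and soil rows;
#' * `metal`, `mean`, `sd`, `unit` — the measured triplicate summary.
#'
#' Soil and vegetable concentrations are on a dry-weight mass basis
#' (mg/kg dw); water is mg/l. Keys must be unique and `mean`/`sd`
#' non-negative.
#'
#' @param records A data frame with the columns above.
#' @return A `concentration_table` (a data frame subclass).
#' @seealso [load_concentration_table()], [validate_table()]
#' @export
concentration_table <- function(records) {
  tab <- as_concentration_table(records)
  bad <- validate_table(tab)
  if (length(bad)) {
    stop(paste(c("invalid concentration table:", bad), collapse = "\n  "),
         call. = FALSE)
  }
  tab
}

conc_columns <- c("medium", "source", "item", "metal", "mean", "sd", "unit")

# low-level coercion without invariant checks (validate_table reports them)
as_concentration_table <- function(records) {
  records <- as.data.frame(records)
  missing <- setdiff(conc_columns, names(records))
  if (length(missing)) {
    stop(sprintf("concentration table schema error: missing column(s) %s",
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  records <- records[conc_columns]
  for (col in c("medium", "source", "item", "metal", "unit")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$mean <- as.numeric(records$mean)
  records$sd <- as.numeric(records$sd)
  class(records) <- c("concentration_table", "data.frame")
  records
}

#' Check concentration-table invariants
#'
#' Unlike [concentration_table()] and [load_concentration_table()], which
#' raise on an invalid table, this returns the violations so that callers
#' can report them all.
#'
#' @param table A `concentration_table` or any data frame with its columns.
#' @return A character vector of violation descriptions; empty when all
#'   invariants hold. Each violation names the offending key or row and the
#'   rule breached.
#' @export
validate_table <- function(table) {
  tab <- as_concentration_table(table)
  out <- character()
  bad_medium <- !tab$medium %in% c("water", "soil", "vegetable")
  if (any(bad_medium)) {
    out <- c(out, sprintf(
      "row %d: medium '%s' not one of water/soil/vegetable",
      which(bad_medium), tab$medium[bad_medium]))
  }
  neg_mean <- !is.na(tab$mean) & tab$mean < 0
  if (any(neg_mean)) {
    out <- c(out, sprintf("row %d: mean %g < 0",
                          which(neg_mean), tab$mean[neg_mean]))
  }
  neg_sd <- !is.na(tab$sd) & tab$sd < 0
  if (any(neg_sd)) {
    out <- c(out, sprintf("row %d: sd %g < 0",
                          which(neg_sd), tab$sd[neg_sd]))
  }
  if (any(is.na(tab$mean)) || any(is.na(tab$sd))) {
    out <- c(out, sprintf("row %d: non-numeric mean or sd",
                          which(is.na(tab$mean) | is.na(tab$sd))))
  }
  key <- paste(tab$medium, tab$source, tab$item, tab$metal, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    out <- c(out, sprintf("duplicate key (%s)",
                          gsub("\\|", ", ", unique(key[dup]))))
  }
  out
}

#' Read a concentration table from a delimited file
#'
#' Expects a UTF-8 CSV with header
#' `medium,source,item,metal,mean,sd,unit`. Row order is preserved and
#' units are carried through verbatim.
#'
#' @param path Path to the CSV file.
#' @return A validated [concentration_table].
#' @examples
#' load_concentration_table(hmrisk_example("vegetables_iww.csv"))
#' @export
load_concentration_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  concentration_table(raw)
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table> %d record(s); media: %s; sources: %s\n",
              nrow(x), paste(unique(x$medium), collapse = "/"),
              paste(unique(x$source), collapse = "/")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Path to a packaged example/fixture file
#'
#' The package ships the study's field measurements as plain-text fixtures:
#' `water.csv` (irrigation water, both sources), `soil.csv` (irrigated
#' soil, both sources), `vegetables_iww.csv` and `vegetables_tww.csv`
#' (four vegetables under each irrigation source), and
#' `default_config.yaml` (the default risk-parameter configuration).
#'
#' @param file File name; omit to list the available files.
#' @return A path, or a character vector of file names.
#' @examples
#' hmrisk_example()
#' @export
hmrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "hmrisk")))
  }
  path <- system.file("extdata", file, package = "hmrisk")
  if (path == "") {
    stop(sprintf("no packaged file '%s'", file), call. = FALSE)
  }
  path
}
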