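#' Write a pipeline result to CSV or JSON
#'
#' Serializes any of the package's result objects so that reading the file
#' back ([read_report()]) reconstructs the numeric content to full double
#' precision (CSV numerics are written with 17 significant digits; JSON
#' with `digits = NA`).
#'
#' @param result A [concentration_table], `mtf_table`, `exposure_result`,
#'   `summary_stats`, `simulation_result` or `sensitivity_result`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("csv", "json")) {
  if (!is.character(format) || !all(format %in% c("csv", "json"))) {
    stop("unsupported format; supported formats: csv, json", call. = FALSE)
  }
  format <- match.arg(format)
  UseMethod("write_report")
}

# CSV writer preserving full double precision on round trip
write_csv_precise <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

write_json_precise <- function(x, path) {
  # digits = I(17): enough significant digits that parsing reconstructs
  # every double bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @export
write_report.concentration_table <- function(result, path,
                                             format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") write_csv_precise(as.data.frame(result), path)
  else write_json_precise(list(records = as.data.frame(result)), path)
  invisible(path)
}

#' @export
write_report.mtf_table <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(result)
  if (format == "csv") write_csv_precise(df, path)
  else write_json_precise(list(source = attr(result, "source"),
                               entries = df), path)
  invisible(path)
}

#' @export
write_report.exposure_result <- function(result, path,
                                         format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    write_json_precise(list(
      group = result$group, source = result$source,
      edi = result$edi, thq = result$thq,
      hi_by_vegetable = as.list(result$hi_by_vegetable),
      hi_total = result$hi_total), path)
  } else {
    df <- merge(result$edi, result$thq, by = c("vegetable", "metal"),
                sort = FALSE)
    df$group <- result$group
    df$source <- result$source
    write_csv_precise(df, path)
  }
  invisible(path)
}

#' @export
write_report.summary_stats <- function(result, path,
                                       format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write_csv_precise(as.data.frame(unclass(result)), path)
  } else {
    write_json_precise(unclass(result), path)
  }
  invisible(path)
}

#' @export
write_report.sensitivity_result <- function(result, path,
                                            format = c("csv", "json")) {
  format <- match.arg(format)
  ord <- order(-result$contributions)  # tornado order, largest first
  df <- data.frame(input = names(result$contributions)[ord],
                   contribution_pct = unname(result$contributions[ord]),
                   rho = unname(result$rho[ord]),
                   stringsAsFactors = FALSE)
  if (format == "csv") write_csv_precise(df, path)
  else write_json_precise(list(output_name = result$output_name,
                               degenerate = result$degenerate,
                               ranking = df), path)
  invisible(path)
}

#' @export
write_report.simulation_result <- function(result, path,
                                           format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- cbind(result$inputs,
                as.data.frame(result$hi_by_vegetable,
                              col.names = paste0("HI.", colnames(
                                result$hi_by_vegetable))),
                hi_total = result$hi_total)
    write_csv_precise(df, path)
  } else {
    write_json_precise(list(
      n_iter = result$n_iter, seed = result$seed, group = result$group,
      source = result$source, inputs = result$inputs,
      hi_by_vegetable = as.data.frame(result$hi_by_vegetable),
      hi_total = result$hi_total), path)
  }
  invisible(path)
}

#' @export
write_report.default <- function(result, path, format = c("csv", "json")) {
  stop(sprintf("write_report: no method for class '%s'",
               paste(class(result), collapse = "/")), call. = FALSE)
}

#' Read back a written report
#'
#' @param path File written by [write_report()].
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   omitted.
#' @return A data frame (CSV) or nested list/data frame structure (JSON)
#'   holding the report's content at full precision.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  }
  if (!format %in% c("csv", "json")) {
    stop("unsupported format; supported formats: csv, json", call. = FALSE)
  }
  if (format == "csv") {
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
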