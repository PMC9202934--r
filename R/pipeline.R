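#' Append a structured log line
#'
#' Writes one machine-parseable JSON line with a timestamp, level, pipeline
#' stage and message.
#'
#' @param level `"info"`, `"warning"` or `"error"`.
#' @param stage Pipeline stage name (e.g. `"simulate"`).
#' @param message Free-text message.
#' @param con Connection or file path to append to; defaults to stderr.
#' @return The log line, invisibly.
#' @export
log_event <- function(level = c("info", "warning", "error"), stage,
                      message, con = stderr()) {
  level <- match.arg(level)
  line <- jsonlite::toJSON(list(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    level = level, stage = stage, message = message), auto_unbox = TRUE)
  if (is.character(con)) cat(line, "\n", sep = "", file = con, append = TRUE)
  else writeLines(line, con)
  invisible(as.character(line))
}

#' Run the full risk-assessment pipeline
#'
#' Orchestrates every stage for all groups in the configuration and all
#' irrigation sources present in the vegetable tables: table validation,
#' transfer factors, the deterministic point estimate, Monte Carlo
#' simulation with forecast summaries per vegetable and in total,
#' contribution-to-variance sensitivity, and a convergence check between
#' two independent runs. All numeric outputs are reproduced exactly by a
#' rerun with the same seed.
#'
#' Stage seeds derive from `seed` via [derive_seeds()]: simulation run
#' `k` (in the order the group/source combinations are processed, two
#' independent runs each) uses the `k`-th derived seed.
#'
#' @param veg Character vector of vegetable concentration CSV paths (one
#'   or more sources).
#' @param soil Path to the soil concentration CSV.
#' @param config Path to a YAML/JSON risk configuration, or a
#'   [risk_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_iter Iterations per simulation run.
#' @param log Connection or path for [log_event()] lines.
#' @return Invisibly, the report bundle: nested list with `mtf` per
#'   source, and per group/source the point estimate, forecast summaries,
#'   sensitivity and convergence results, plus the run record.
#' @export
run_full_pipeline <- function(veg, soil, config, out_dir, seed = 42,
                              n_iter = 10000, log = stderr()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (inherits(config, "risk_config")) config
         else load_risk_config(config)
  log_event("info", "load", sprintf("reading %d vegetable table(s)",
                                    length(veg)), log)
  veg_tab <- do.call(rbind, lapply(veg, function(p)
    as.data.frame(load_concentration_table(p))))
  veg_tab <- as_concentration_table(veg_tab)
  soil_tab <- load_concentration_table(soil)
  for (bad in c(validate_table(veg_tab), validate_table(soil_tab))) {
    log_event("warning", "validate", bad, log)
  }
  sources <- unique(veg_tab$source[veg_tab$medium == "vegetable"])
  groups <- names(cfg$groups)
  seeds <- derive_seeds(seed, 2L * length(sources) * length(groups))
  outputs <- character()
  emit <- function(result, name, format) {
    path <- file.path(out_dir, paste0(name, ".", format))
    write_report(result, path, format)
    outputs <<- c(outputs, path)
    path
  }

  bundle <- list(mtf = list(), runs = list())
  for (src in sources) {
    log_event("info", "mtf", sprintf("transfer factors, source %s", src),
              log)
    mtf <- compute_mtf(veg_tab, soil_tab, src)
    emit(mtf, paste0("mtf_", tolower(src)), "csv")
    bundle$mtf[[src]] <- mtf
  }

  run_idx <- 0L
  for (src in sources) {
    cfg_src <- risk_config(cfg$metals, cfg$groups, cfg$vegetables, src)
    for (grp in groups) {
      tag <- paste0(grp, "_", tolower(src))
      log_event("info", "point-risk", tag, log)
      point <- point_risk_assessment(veg_tab, cfg_src, grp)
      emit(point, paste0("point_", tag), "json")

      log_event("info", "simulate",
                sprintf("%s: 2 runs x %d iterations", tag, n_iter), log)
      sims <- lapply(1:2, function(r) {
        run_idx <<- run_idx + 1L
        run_simulation(veg_tab, cfg_src, grp, n_iter = n_iter,
                       seed = seeds[run_idx])
      })
      stats_total <- summarize_forecast(sims[[1]]$hi_total)
      emit(stats_total, paste0("summary_", tag), "csv")
      per_veg <- lapply(colnames(sims[[1]]$hi_by_vegetable), function(v)
        summarize_forecast(sims[[1]]$hi_by_vegetable[, v]))
      names(per_veg) <- colnames(sims[[1]]$hi_by_vegetable)

      sens <- contribution_to_variance(sims[[1]]$inputs,
                                       sims[[1]]$hi_total)
      emit(sens, paste0("sensitivity_", tag), "csv")

      conv <- convergence_check(stats_total,
                                summarize_forecast(sims[[2]]$hi_total))
      conv_rec <- list(group = grp, source = src, n_iter = n_iter,
                       seeds = sims[[1]]$seed + c(0L, 0L),
                       max_relative_difference = as.numeric(conv),
                       by_stat = as.list(attr(conv, "by_stat")),
                       converged_1pct = as.numeric(conv) <= 0.01)
      conv_rec$seeds <- c(sims[[1]]$seed, sims[[2]]$seed)
      conv_path <- file.path(out_dir, paste0("convergence_", tag, ".json"))
      write_json_precise(conv_rec, conv_path)
      outputs <- c(outputs, conv_path)

      bundle$runs[[tag]] <- list(
        point = point, mean_hi = stats_total$mean,
        summary = stats_total, summary_by_vegetable = per_veg,
        sensitivity = sens,
        pooled_ir_pct = pool_contributions(sens, "^IR\\."),
        convergence = conv)
      log_event("info", "simulate",
                sprintf("%s done: mean HI %.4g, pooled IR %.1f%%", tag,
                        stats_total$mean, bundle$runs[[tag]]$pooled_ir_pct),
                log)
    }
  }

  record <- list(
    package = "hmrisk",
    version = as.character(utils::packageVersion("hmrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(veg = veg, soil = soil,
                  config = if (is.character(config)) config
                           else "<in-memory risk_config>"),
    input_digests = as.list(tools::md5sum(
      c(veg, soil, if (is.character(config)) config))),
    seed = seed, derived_seeds = seeds, n_iter = n_iter,
    outputs = outputs)
  write_json_precise(record, file.path(out_dir, "run_record.json"))
  log_event("info", "done",
            sprintf("pipeline complete: %d output file(s)",
                    length(outputs) + 1L), log)
  bundle$run_record <- record
  invisible(bundle)
}
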