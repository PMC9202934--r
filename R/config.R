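#' Risk-model configuration
#'
#' A `risk_config` bundles everything the exposure model needs besides the
#' concentration tables: the metals with their oral reference doses (RfD,
#' mg/kg bw/day), the population groups with their parameter distributions,
#' the vegetables in the diet, and the irrigation source under assessment.
#'
#' @section Population groups:
#' Each group carries distribution specs ([dist_spec]) for body weight
#' `bw` (kg), exposure duration `ed` (years), exposure frequency `ef`
#' (days/year), and one ingestion rate spec per vegetable `ir` (kg/day,
#' fresh weight), plus a fresh-to-dry conversion factor `cf` in (0, 1]
#' (default 0.085) and an averaging-time rule `at_rule`:
#' * `list(rule = "ed_times_365")` — the non-carcinogenic convention
#'   AT = ED x 365 days (the default);
#' * `list(rule = "fixed_days", days = <d>)` — a literal fixed averaging
#'   time in days.
#'
#' @param name Metal or group name.
#' @param rfd Oral reference dose, mg/kg bw/day (> 0).
#' @param who_limit Optional informational WHO limit for irrigation water
#'   (mg/l).
#' @return `metal_spec()`, `population_group()` and `risk_config()` return
#'   validated objects of the corresponding class.
#' @seealso [default_risk_config()], [load_risk_config()]
#' @export
metal_spec <- function(name, rfd, who_limit = NA_real_) {
  if (!is.numeric(rfd) || rfd <= 0) {
    stop(sprintf("metal '%s': rfd must be > 0", name), call. = FALSE)
  }
  structure(list(name = as.character(name), rfd = as.numeric(rfd),
                 who_limit = as.numeric(who_limit)),
            class = "metal_spec")
}

#' @rdname metal_spec
#' @param bw,ed,ef [dist_spec]s for body weight, exposure duration and
#'   exposure frequency.
#' @param ir Named list of [dist_spec]s, one per vegetable (kg/day).
#' @param cf Fresh-to-dry conversion factor in (0, 1].
#' @param at_rule Averaging-time rule (see Details).
#' @export
population_group <- function(name, bw, ed, ef, ir, cf = 0.085,
                             at_rule = list(rule = "ed_times_365")) {
  bw <- as_dist_spec(bw); ed <- as_dist_spec(ed); ef <- as_dist_spec(ef)
  if (!is.list(ir) || is.null(names(ir)) || any(names(ir) == "")) {
    stop(sprintf("group '%s': 'ir' must be a named list of specs", name),
         call. = FALSE)
  }
  ir <- lapply(ir, as_dist_spec)
  if (!is.numeric(cf) || cf <= 0 || cf > 1) {
    stop(sprintf("group '%s': cf must be in (0, 1]", name), call. = FALSE)
  }
  if (!is.list(at_rule) ||
      !at_rule$rule %in% c("ed_times_365", "fixed_days")) {
    stop(sprintf(
      "group '%s': at_rule must be 'ed_times_365' or 'fixed_days'", name),
      call. = FALSE)
  }
  if (at_rule$rule == "fixed_days" &&
      (is.null(at_rule$days) || at_rule$days <= 0)) {
    stop(sprintf("group '%s': fixed_days at_rule needs days > 0", name),
         call. = FALSE)
  }
  structure(list(name = as.character(name), bw = bw, ed = ed, ef = ef,
                 ir = ir, cf = as.numeric(cf), at_rule = at_rule),
            class = "population_group")
}

#' @rdname metal_spec
#' @param metals List of [metal_spec()]s.
#' @param groups List of [population_group()]s.
#' @param vegetables Character vector of vegetables in the assessed diet.
#' @param source `"IWW"` or `"TWW"`.
#' @export
risk_config <- function(metals, groups, vegetables, source = "IWW") {
  stopifnot(length(metals) >= 1, length(groups) >= 1,
            length(vegetables) >= 1, source %in% c("IWW", "TWW"))
  names(metals) <- vapply(metals, `[[`, "", "name")
  names(groups) <- vapply(groups, `[[`, "", "name")
  for (g in groups) {
    gap <- setdiff(vegetables, names(g$ir))
    if (length(gap)) {
      stop(sprintf("config error: group '%s' has no IR spec for %s",
                   g$name, paste(sQuote(gap), collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(metals = metals, groups = groups,
                 vegetables = as.character(vegetables),
                 source = source),
            class = "risk_config")
}

#' @export
print.risk_config <- function(x, ...) {
  cat(sprintf(
    "<risk_config> source %s; %d metal(s): %s; groups: %s; diet: %s\n",
    x$source, length(x$metals), paste(names(x$metals), collapse = ", "),
    paste(names(x$groups), collapse = ", "),
    paste(x$vegetables, collapse = ", ")))
  invisible(x)
}

#' Default risk configuration for the wastewater-irrigation study
#'
#' Builds the configuration used throughout the package: six metals (Fe,
#' Pb, Cr, Ni, Mn, Co) with their oral reference doses, and two population
#' groups:
#' * children — IR (kg/day): ladyfinger normal(0.0155, 0.01), pumpkin
#'   normal(0.045, 0.01), onion and green pepper normal(0.0058, 0.01);
#'   ED uniform(1, 7) years; BW lognormal mean 32.7 kg;
#' * adults — IR: ladyfinger normal(0.058, 0.01), pumpkin
#'   normal(0.0648, 0.01), onion and green pepper normal(0.0218, 0.01);
#'   ED uniform(26, 70) years; BW lognormal mean 73.5 kg.
#'
#' Both groups share EF triangular(180, 345, 365) days/year, fresh-to-dry
#' factor 0.085, and the AT = ED x 365 averaging rule. The body-weight
#' tables print only a central value for the lognormal; the spread is
#' supplied as a coefficient of variation (`bw_cv`, default 0.10,
#' overridable; 0 gives a degenerate body weight).
#'
#' Reference doses (mg/kg bw/day): Fe 0.7, Pb 0.004, Ni 0.02, Mn 0.033,
#' Co 0.090, and Cr `cr_rfd` (default 1.5, the oral RfD of trivalent
#' chromium; set 0.003 for hexavalent).
#'
#' @param source `"IWW"` or `"TWW"`.
#' @param bw_cv Coefficient of variation of the lognormal body weights.
#' @param cr_rfd Oral reference dose for chromium.
#' @param at_rule Averaging-time rule applied to both groups (see
#'   [population_group()]).
#' @return A [risk_config()].
#' @export
default_risk_config <- function(source = "IWW", bw_cv = 0.10, cr_rfd = 1.5,
                                at_rule = list(rule = "ed_times_365")) {
  metals <- list(
    metal_spec("Fe", 0.7,   5.00),
    metal_spec("Pb", 0.004, 0.01),
    metal_spec("Cr", cr_rfd, 0.05),
    metal_spec("Ni", 0.02,  0.07),
    metal_spec("Mn", 0.033, 0.20),
    metal_spec("Co", 0.090, 0.025))
  ef <- dist_triangular(180, 345, 365)
  children <- population_group(
    "children",
    bw = dist_lognormal(32.7, cv = bw_cv),
    ed = dist_uniform(1, 7),
    ef = ef,
    ir = list(
      "Ladyfinger"   = dist_normal(0.0155, 0.01),
      "Pumpkin"      = dist_normal(0.045, 0.01),
      "Onion"        = dist_normal(0.0058, 0.01),
      "Green pepper" = dist_normal(0.0058, 0.01)),
    at_rule = at_rule)
  adults <- population_group(
    "adults",
    bw = dist_lognormal(73.5, cv = bw_cv),
    ed = dist_uniform(26, 70),
    ef = ef,
    ir = list(
      "Ladyfinger"   = dist_normal(0.058, 0.01),
      "Pumpkin"      = dist_normal(0.0648, 0.01),
      "Onion"        = dist_normal(0.0218, 0.01),
      "Green pepper" = dist_normal(0.0218, 0.01)),
    at_rule = at_rule)
  risk_config(metals, list(children, adults),
              c("Ladyfinger", "Pumpkin", "Onion", "Green pepper"),
              source = source)
}

#' Read a risk configuration from YAML or JSON
#'
#' The document mirrors [risk_config()]: top-level `source`, `vegetables`,
#' `metals` (list of `{name, rfd, who_limit}`) and `groups` (list of
#' `{name, bw, ed, ef, ir, cf, at_rule}` with distribution specs as
#' `{family: ..., <params>}`). The packaged
#' `hmrisk_example("default_config.yaml")` reproduces
#' [default_risk_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [risk_config()].
#' @export
load_risk_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  metals <- lapply(doc$metals, function(m) {
    metal_spec(m$name, m$rfd,
               if (is.null(m$who_limit)) NA_real_ else m$who_limit)
  })
  groups <- lapply(doc$groups, function(g) {
    population_group(
      g$name,
      bw = as_dist_spec(g$bw), ed = as_dist_spec(g$ed),
      ef = as_dist_spec(g$ef), ir = lapply(g$ir, as_dist_spec),
      cf = if (is.null(g$cf)) 0.085 else g$cf,
      at_rule = if (is.null(g$at_rule)) list(rule = "ed_times_365")
                else g$at_rule)
  })
  risk_config(metals, groups, unlist(doc$vegetables),
              source = if (is.null(doc$source)) "IWW" else doc$source)
}

# Check that a config covers a vegetable concentration table: every
# vegetable item and every metal in the table must be configured.
check_config_covers <- function(veg, config) {
  items <- unique(veg$item[veg$medium == "vegetable"])
  gap_v <- setdiff(items, config$vegetables)
  if (length(gap_v)) {
    stop(sprintf("config error: table vegetable(s) %s not in config",
                 paste(sQuote(gap_v), collapse = ", ")), call. = FALSE)
  }
  gap_m <- setdiff(unique(veg$metal), names(config$metals))
  if (length(gap_m)) {
    stop(sprintf("config error: no RfD for metal(s) %s",
                 paste(sQuote(gap_m), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
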