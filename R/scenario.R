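# Scenario grids: a plain-text config format (one `[section]` per scenario,
# `key = value` lines, `#` comments) and a tidy-results runner.

#' Read a scenario grid file
#'
#' Each `[section]` starts one scenario; its `key = value` lines override
#' the [sim_config()] defaults (and any `defaults` passed here).  Values
#' that parse as numbers are treated as numeric; everything else is kept as
#' a string (e.g. `distribution = uniform`).  Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path file path.
#' @param defaults named list of overrides applied to every scenario before
#'   its own keys (e.g. `list(reps = 2000, B = 100)`).
#' @return Named list of [sim_config()] objects.
#' @export
#' @examples
#' f <- tempfile(fileext = ".ini")
#' writeLines(c("[null_cell]", "md = 0", "r = 1",
#'              "[shift_cell]", "md = 10", "r = 2"), f)
#' read_scenario_grid(f, defaults = list(reps = 2000))
read_scenario_grid <- function(path, defaults = list()) {
  if (!file.exists(path)) stop(sprintf("no such scenario file: %s", path),
                               call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0 || !startsWith(lines[1], "[")) {
    stop("scenario file must start with a [section] header", call. = FALSE)
  }
  section <- cumsum(startsWith(lines, "["))
  scenarios <- list()
  for (s in split(lines, section)) {
    name <- sub("^\\[(.*)\\]$", "\\1", s[1])
    fields <- defaults
    for (kv in s[-1]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop(sprintf("malformed scenario line: '%s'", kv), call. = FALSE)
      }
      key <- trimws(parts[1])
      val <- trimws(parts[2])
      num <- suppressWarnings(as.numeric(val))
      fields[[key]] <- if (!is.na(num)) num else val
    }
    bad <- setdiff(names(fields), names(formals(sim_config)))
    if (length(bad) > 0) {
      stop(sprintf("unknown scenario field(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    scenarios[[name]] <- do.call(sim_config, fields)
  }
  scenarios
}

#' Run a scenario grid
#'
#' Applies [estimate_type1_power()] (mode `"alpha"`) or
#' [fdr_power_comparison()] (mode `"fdr"`) to every scenario and stacks the
#' results in tidy long form.
#'
#' @param scenarios named list of [sim_config()] objects (from
#'   [read_scenario_grid()] or built directly).
#' @param methods statistics to evaluate.
#' @param mode `"alpha"`: per-gene rejection at each scenario's alpha;
#'   `"fdr"`: BH at `q` on permutation p-values.
#' @param null permutation p-value convention.
#' @param q FDR level for mode `"fdr"`.
#' @return Tidy data frame with columns `scenario`, `method`, `metric`,
#'   `estimate`, `mc_se`.
#' @export
run_scenario_grid <- function(scenarios, methods = HALF_SAM_METHODS,
                              mode = c("alpha", "fdr"),
                              null = NULL, q = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(scenarios) > 0, !is.null(names(scenarios)))
  rows <- lapply(names(scenarios), function(name) {
    cfg <- scenarios[[name]]
    if (mode == "alpha") {
      res <- estimate_type1_power(cfg, methods,
                                  null = if (is.null(null)) "pergene" else null)
      data.frame(scenario = name, method = res$method, metric = res$metric,
                 estimate = res$rejection_rate, mc_se = res$mc_se,
                 stringsAsFactors = FALSE)
    } else {
      res <- fdr_power_comparison(cfg, methods, q = q,
                                  null = if (is.null(null)) "pooled" else null)
      data.frame(scenario = name, method = res$method, metric = "fdr_power",
                 estimate = res$power, mc_se = res$mc_se,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
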