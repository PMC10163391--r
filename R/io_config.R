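# Run configuration plus readers/writers for metric tables, pre-computed
# score tables, and results.

METRIC_CSV_COLUMNS <- c("condition_id", "condition_name", "domain",
                        "metric_id", "year", "stratum", "value", "units")

#' Run configuration
#'
#' Every field has a default, so an empty configuration is valid; the returned
#' object echoes every effective value for provenance logging.
#'
#' @param domain_weights named positive weights for the three domains
#'   (default all 1, the pilot's equal weighting).
#' @param within_domain_weights optional named metric-level weights (default:
#'   equal within each domain).
#' @param normalization `"vector"` or `"minmax"` (see [topsis_normalize()]).
#' @param aggregation_mode `"hierarchical"` (overall TOPSIS on the three
#'   domain scores) or `"flat"` (one pooled matrix of all metrics with each
#'   domain's weight mass equalized).
#' @param missing_policy how a condition missing a criterion value is handled:
#'   `"zero"` (default; mirrors "no recorded deaths", with a warning),
#'   `"drop_criterion"`, or `"mean_impute"`.
#' @param quantile_convention quartile method label for IQR tiering;
#'   `"linear"` (interpolated order statistics, [stats::quantile()] type 7),
#'   `"tukey"` (type 2) or `"nearest"` (type 3).
#' @param reference_years list of per-domain reference years; pilot defaults:
#'   burden cross-section 2019 with a 2015-2019 trend window, cost
#'   cross-section 2016 with a 2012-2016 trend window, innovation averaged
#'   annually over 2015-2019.
#' @param trend_form per-domain scale for trend criteria: `"relative"`
#'   (fractional change; rates) or `"absolute"` (level change; dollar totals).
#' @param display_digits decimals for the human-readable scores CSV.
#' @param seed optional integer seed echoed into results for determinism.
#' @return object of class `gap_config`.
#' @export
gap_config <- function(domain_weights = c(burden = 1, cost = 1, innovation = 1),
                       within_domain_weights = NULL,
                       normalization = c("vector", "minmax"),
                       aggregation_mode = c("hierarchical", "flat"),
                       missing_policy = c("zero", "drop_criterion",
                                          "mean_impute"),
                       quantile_convention = "linear",
                       reference_years = NULL,
                       trend_form = c(burden = "relative", cost = "absolute"),
                       display_digits = 2L,
                       seed = NULL) {
  normalization <- match.arg(normalization)
  aggregation_mode <- match.arg(aggregation_mode)
  missing_policy <- match.arg(missing_policy)

  dw <- c(burden = 1, cost = 1, innovation = 1)
  dw[names(domain_weights)] <- unlist(domain_weights)
  if (any(!is.finite(dw)) || any(dw <= 0)) {
    stop("domain weights must be positive", call. = FALSE)
  }
  if (!is.null(within_domain_weights)) {
    wdw <- unlist(within_domain_weights)
    if (any(!is.finite(wdw)) || any(wdw <= 0)) {
      stop("within-domain weights must be positive", call. = FALSE)
    }
    within_domain_weights <- wdw
  }

  ry <- list(burden = 2019L, burden_trend = c(2015L, 2019L),
             cost = 2016L, cost_trend = c(2012L, 2016L),
             innovation = 2015L:2019L)
  if (!is.null(reference_years)) ry <- modifyList(ry, reference_years)

  tf <- c(burden = "relative", cost = "absolute")
  tf[names(trend_form)] <- unlist(trend_form)
  if (!all(tf %in% c("relative", "absolute"))) {
    stop("trend_form values must be 'relative' or 'absolute'", call. = FALSE)
  }

  structure(
    list(domain_weights = dw, within_domain_weights = within_domain_weights,
         normalization = normalization, aggregation_mode = aggregation_mode,
         missing_policy = missing_policy,
         quantile_convention = quantile_convention,
         reference_years = ry, trend_form = tf,
         display_digits = as.integer(display_digits),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "gap_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unspecified keys take the documented defaults (an empty file yields the
#' default configuration).
#'
#' @param path YAML file; keys mirror the arguments of [gap_config()].
#' @return a [gap_config()] object echoing every effective value.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(gap_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  for (k in c("domain_weights", "within_domain_weights", "trend_form")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(gap_config, raw)
}

#' Read a long-format metrics CSV
#'
#' Expected header: `condition_id, condition_name, domain, metric_id, year,
#' stratum, value, units` (any order). An empty `stratum` cell means "no
#' stratum". Metric definitions are registered from the file with
#' domain-default directions; kind is `disparity` for metrics observed with
#' strata and `cross_sectional` otherwise.
#'
#' @param path CSV file path.
#' @param validate if `TRUE` (default), fail on validation findings; set
#'   `FALSE` to obtain the table and run [validate_table()] separately.
#' @return a validated [metric_table()].
#' @export
read_metric_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("metrics file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(METRIC_CSV_COLUMNS, names(df))
  if (length(missing)) {
    stop("malformed metrics CSV header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(val) & !(is.na(df$value) | df$value == ""))
  if (length(bad)) {
    stop("unparseable value(s) at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  yr <- suppressWarnings(as.integer(df$year))
  bad <- which(is.na(yr) & !(is.na(df$year) | df$year == ""))
  if (length(bad)) {
    stop("unparseable year(s) at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }

  obs <- tibble::tibble(condition_id = df$condition_id,
                        metric_id = df$metric_id, year = yr,
                        stratum = df$stratum, value = val)
  cons <- unique(tibble::tibble(condition_id = df$condition_id,
                                name = df$condition_name, icd10_codes = ""))
  mk <- !duplicated(df$metric_id)
  stratified <- tapply(!is.na(df$stratum) & df$stratum != "", df$metric_id,
                       any)
  defs <- tibble::tibble(
    metric_id = df$metric_id[mk], domain = df$domain[mk],
    direction = default_direction(df$domain[mk]),
    kind = ifelse(stratified[df$metric_id[mk]], "disparity",
                  "cross_sectional"),
    units = ifelse(is.na(df$units[mk]), "", df$units[mk])
  )
  tab <- metric_table(obs, cons, defs)
  if (!validate) return(tab)
  findings <- validate_table(tab)
  if (nrow(findings)) {
    stop("metrics file failed validation:\n",
         paste(" -", findings$rule, ":", findings$detail, collapse = "\n"),
         call. = FALSE)
  }
  tab
}

#' Write a metric table back to the long CSV format
#'
#' Inverse of [read_metric_csv()]: a valid table round-trips with keys and
#' values preserved to full precision.
#'
#' @param table a [metric_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  obs <- table$observations
  con <- table$conditions
  def <- table$definitions
  out <- tibble::tibble(
    condition_id = obs$condition_id,
    condition_name = con$name[match(obs$condition_id, con$condition_id)],
    domain = def$domain[match(obs$metric_id, def$metric_id)],
    metric_id = obs$metric_id,
    year = obs$year,
    stratum = ifelse(is.na(obs$stratum), "", obs$stratum),
    value = obs$value,
    units = def$units[match(obs$metric_id, def$metric_id)]
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pre-computed score table
#'
#' Ingests a table of per-condition domain scores (and optionally an overall
#' gap score), e.g. a published composite-score table, for report-only runs
#' that apply ranking, IQR tiering and opportunity flagging without
#' recomputing scores from raw metrics.
#'
#' @param path CSV with columns `condition`, `burden`, `cost`, `innovation`
#'   and optionally `overall_gap`, all scores in \[0, 1\].
#' @return tibble of scores.
#' @export
read_score_csv <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    condition = "c", .default = "d"), progress = FALSE)
  req <- c("condition", "burden", "cost", "innovation")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("malformed score CSV; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- setdiff(names(df), "condition")
  rng <- unlist(df[num])
  if (any(is.na(rng)) || any(rng < 0 | rng > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Path to the bundled pilot composite-score table
#'
#' The published 13-condition pilot table of composite burden, cost,
#' innovation and overall gap scores, shipped as the package's worked
#' example for report-only runs.
#'
#' @return file path to the CSV.
#' @export
pilot_scores_path <- function() {
  system.file("extdata", "pilot_scores.csv", package = "gapscore",
              mustWork = TRUE)
}

#' Write gap results to disk
#'
#' Writes three files: `gap_scores.csv` (one row per condition, scores rounded
#' for display), `gap_results.json` (full precision, deterministic: identical
#' inputs give byte-identical output), and `multifactor_plot.csv` (burden
#' score vs cost score with the innovation tier, the axes of the multifactor
#' classification plot).
#'
#' @param results a `gap_results` object (see [gap_pipeline()]) or the scores
#'   tibble it carries.
#' @param out_dir output directory, created if needed.
#' @param digits decimals for the display CSV (default 2).
#' @return named character vector of written paths (the manifest), invisibly.
#' @export
write_results <- function(results, out_dir, digits = 2L) {
  scores <- if (inherits(results, "gap_results")) results$scores else
    tibble::as_tibble(results)
  if (nrow(scores) == 0L) stop("results are empty", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  num <- vapply(scores, is.numeric, logical(1)) &
    !names(scores) %in% c("rank")
  display <- scores
  display[num] <- lapply(display[num], round, digits = digits)
  paths <- c(
    scores_csv = file.path(out_dir, "gap_scores.csv"),
    results_json = file.path(out_dir, "gap_results.json"),
    plot_csv = file.path(out_dir, "multifactor_plot.csv")
  )
  readr::write_csv(display, paths[["scores_csv"]], progress = FALSE)
  payload <- if (inherits(results, "gap_results")) {
    list(scores = scores, quartiles = results$quartiles)
  } else {
    list(scores = scores)
  }
  jsonlite::write_json(payload, paths[["results_json"]], digits = NA,
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  plot_df <- tibble::tibble(
    condition = scores$condition,
    burden_score = scores$burden,
    cost_score = scores$cost,
    innovation_tier = if ("innovation_tier" %in% names(scores))
      scores$innovation_tier else NA_character_
  )
  readr::write_csv(plot_df, paths[["plot_csv"]], progress = FALSE)
  invisible(paths)
}
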