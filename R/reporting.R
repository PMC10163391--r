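# Command-style entry points and the human-readable report. Each entry point
# returns a stable exit code: 0 success, 2 validation failure, 3 computation
# failure, 4 I/O failure.

GAP_EXIT_OK <- 0L
GAP_EXIT_VALIDATION <- 2L
GAP_EXIT_COMPUTE <- 3L
GAP_EXIT_IO <- 4L

run_stage <- function(name, code, expr) {
  tryCatch(expr, error = function(e) {
    message("gapscore: stage '", name, "' failed: ", conditionMessage(e))
    structure(list(code = code), class = "gap_failure")
  })
}

failed <- function(x) inherits(x, "gap_failure")

write_manifest <- function(out_dir, config, inputs, warnings) {
  digests <- vapply(inputs, function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p))
    else NA_character_
  }, character(1))
  manifest <- list(
    package = "gapscore",
    version = as.character(utils::packageVersion("gapscore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(digests),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Run the scoring pipeline end to end
#'
#' Full mode ingests a long-format metrics CSV and executes ingest,
#' indicators, domain scores, overall gap, tiers, opportunity flags, and
#' writes results plus a run manifest. Report-only mode ingests a
#' pre-computed per-condition score table (e.g. a published composite-score
#' table) and applies only ranking, tiering and flagging.
#'
#' @param metrics_path metrics CSV (full mode) or score CSV (report-only).
#' @param out_dir output directory.
#' @param config_path optional YAML configuration ([read_config()]).
#' @param mode `"full"` or `"report-only"`.
#' @return exit code, invisibly (0 success, 2 validation failure, 3
#'   computation failure, 4 I/O failure); the `gap_results` object is
#'   attached as attribute `"results"` on success.
#' @export
gap_run <- function(metrics_path, out_dir, config_path = NULL,
                    mode = c("full", "report-only")) {
  mode <- match.arg(mode)
  warnings <- character()
  config <- run_stage("config", GAP_EXIT_VALIDATION, {
    if (is.null(config_path)) gap_config() else read_config(config_path)
  })
  if (failed(config)) return(invisible(config$code))

  results <- withCallingHandlers(
    {
      if (mode == "full") {
        tab <- run_stage("ingest", GAP_EXIT_IO, {
          if (!file.exists(metrics_path)) {
            stop("metrics file not found: ", metrics_path, call. = FALSE)
          }
          read_metric_csv(metrics_path, validate = FALSE)
        })
        if (failed(tab)) return(invisible(tab$code))
        val <- run_stage("validate", GAP_EXIT_VALIDATION, {
          findings <- validate_table(tab)
          if (nrow(findings)) {
            stop(paste(findings$rule, findings$detail, collapse = "; "),
                 call. = FALSE)
          }
          findings
        })
        if (failed(val)) return(invisible(val$code))
        run_stage("score", GAP_EXIT_COMPUTE, gap_pipeline(tab, config))
      } else {
        sc <- run_stage("ingest", GAP_EXIT_IO, {
          if (!file.exists(metrics_path)) {
            stop("score file not found: ", metrics_path, call. = FALSE)
          }
          read_score_csv(metrics_path)
        })
        if (failed(sc)) return(invisible(sc$code))
        run_stage("rank", GAP_EXIT_COMPUTE, rank_conditions(sc, config))
      }
    },
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (failed(results)) return(invisible(results$code))

  out <- run_stage("write", GAP_EXIT_IO, {
    write_results(results, out_dir, digits = config$display_digits)
    write_manifest(out_dir, config, list(metrics = metrics_path,
                                         config = config_path), warnings)
  })
  if (failed(out)) return(invisible(out$code))
  for (w in warnings) message("gapscore: warning: ", w)
  invisible(structure(GAP_EXIT_OK, results = results))
}

#' Generate a synthetic metrics table from a spec file
#'
#' @param spec_path optional YAML file with [synthetic_spec()] arguments; if
#'   `NULL` the default spec is used.
#' @param out_dir output directory; receives `metrics.csv` and a run
#'   manifest.
#' @return exit code, invisibly (see [gap_run()]).
#' @export
gap_simulate <- function(out_dir, spec_path = NULL) {
  spec <- run_stage("spec", GAP_EXIT_VALIDATION, {
    args <- if (is.null(spec_path)) list() else {
      if (!file.exists(spec_path)) {
        stop("spec file not found: ", spec_path, call. = FALSE)
      }
      raw <- yaml::read_yaml(spec_path)
      if (is.null(raw)) list() else raw
    }
    do.call(synthetic_spec, args)
  })
  if (failed(spec)) return(invisible(spec$code))
  tab <- run_stage("generate", GAP_EXIT_COMPUTE, generate_metric_table(spec))
  if (failed(tab)) return(invisible(tab$code))
  out <- run_stage("write", GAP_EXIT_IO, {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory: ", out_dir,
                    call. = FALSE)
    }
    write_metric_csv(tab, file.path(out_dir, "metrics.csv"))
    cfg <- gap_config(seed = spec$seed)
    write_manifest(out_dir, cfg, list(spec = spec_path), character())
  })
  if (failed(out)) return(invisible(out$code))
  invisible(structure(GAP_EXIT_OK, table = tab))
}

dominant_domain <- function(burden, cost, innovation, tol = 1e-9) {
  cand <- c("public health burden" = burden,
            "health care cost" = cost,
            "low biomedical product innovation" = 1 - innovation)
  if (max(cand) - min(cand) < tol) return("no dominant domain")
  names(cand)[which.max(cand)]
}

#' Narrative report of gap results
#'
#' One line per condition naming its rank, overall and per-domain scores and
#' tiers, the dominant contributing domain (largest gap-increasing domain
#' score, or the innovation deficit when that dominates), and the
#' opportunity flag with its reason.
#'
#' @param results a `gap_results` object, or a path to a `gap_results.json`
#'   written by [write_results()].
#' @return character vector of report lines, invisibly; also printed.
#' @export
gap_report <- function(results) {
  if (is.character(results)) {
    if (!file.exists(results)) {
      stop("results file not found: ", results, call. = FALSE)
    }
    payload <- jsonlite::read_json(results, simplifyVector = TRUE)
    scores <- tibble::as_tibble(payload$scores)
  } else if (inherits(results, "gap_results")) {
    scores <- results$scores
  } else {
    stop("results must be a gap_results object or a JSON path",
         call. = FALSE)
  }
  scores <- scores[order(scores$rank), ]
  lines <- vapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    dom <- dominant_domain(s$burden, s$cost, s$innovation)
    line <- sprintf(
      paste0("%d. %s: overall gap %.2f (%s); burden %.2f (%s), ",
             "cost %.2f (%s), innovation %.2f (%s); dominant domain: %s"),
      s$rank, s$condition, s$overall_gap, s$overall_tier,
      s$burden, s$burden_tier, s$cost, s$cost_tier,
      s$innovation, s$innovation_tier, dom)
    if (isTRUE(s$opportunity_flag)) {
      line <- paste0(line, " [innovation opportunity: ", s$reason, "]")
    } else if (nzchar(s$reason)) {
      line <- paste0(line, " [", s$reason, "]")
    }
    line
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}
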