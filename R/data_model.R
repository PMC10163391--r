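# Core domain containers: conditions, metric definitions, long-format
# observations, and the metric_table that bundles them for the pipeline.

#' Assemble a metric table
#'
#' A `metric_table` is the long-format container every pipeline stage consumes:
#' per-condition metric observations plus the condition and metric registries
#' they reference.
#'
#' @param observations tibble with columns `condition_id`, `metric_id`,
#'   `year` (integer calendar year), `stratum` (character, `NA` for
#'   unstratified values) and `value` (nonnegative real, in the metric's
#'   units).
#' @param conditions tibble with columns `condition_id`, `name` and
#'   `icd10_codes` (semicolon-separated code string, may be empty). If `NULL`,
#'   conditions are registered from the observations with `name = condition_id`.
#' @param definitions tibble with columns `metric_id`, `domain` (one of
#'   `burden`, `cost`, `innovation`), `direction` (`gap_increasing` or
#'   `gap_decreasing`), `kind` (`cross_sectional`, `trend` or `disparity`) and
#'   `units` (free text).
#' @return an object of class `metric_table`.
#' @seealso [validate_table()], [read_metric_csv()]
#' @export
metric_table <- function(observations, conditions = NULL, definitions) {
  observations <- tibble::as_tibble(observations)
  req <- c("condition_id", "metric_id", "year", "stratum", "value")
  if (!all(req %in% names(observations))) {
    stop("observations missing columns: ",
         paste(setdiff(req, names(observations)), collapse = ", "),
         call. = FALSE)
  }
  observations$condition_id <- as.character(observations$condition_id)
  observations$metric_id <- as.character(observations$metric_id)
  observations$year <- as.integer(observations$year)
  observations$stratum <- as.character(observations$stratum)
  # empty-string stratum means "no stratum"
  observations$stratum[!is.na(observations$stratum) &
                         observations$stratum == ""] <- NA_character_
  observations$value <- as.numeric(observations$value)

  if (is.null(conditions)) {
    ids <- unique(observations$condition_id)
    conditions <- tibble::tibble(condition_id = ids, name = ids,
                                 icd10_codes = "")
  }
  conditions <- tibble::as_tibble(conditions)
  if (!"icd10_codes" %in% names(conditions)) conditions$icd10_codes <- ""
  conditions$icd10_codes[is.na(conditions$icd10_codes)] <- ""

  definitions <- tibble::as_tibble(definitions)
  dreq <- c("metric_id", "domain", "direction", "kind", "units")
  if (!all(dreq %in% names(definitions))) {
    stop("definitions missing columns: ",
         paste(setdiff(dreq, names(definitions)), collapse = ", "),
         call. = FALSE)
  }

  structure(
    list(observations = observations[req],
         conditions = conditions[c("condition_id", "name", "icd10_codes")],
         definitions = definitions[dreq]),
    class = "metric_table"
  )
}

#' Build metric definitions with domain defaults
#'
#' @param metric_id character vector of metric tokens.
#' @param domain domain label per metric.
#' @param direction optional direction flags; defaults to
#'   [default_direction()] of the domain.
#' @param kind metric kind; default `cross_sectional`.
#' @param units free-text units per metric.
#' @return tibble of metric definitions.
#' @export
metric_definitions <- function(metric_id, domain, direction = NULL,
                               kind = "cross_sectional", units = "") {
  if (is.null(direction)) direction <- default_direction(domain)
  tibble::tibble(metric_id = metric_id, domain = domain,
                 direction = direction, kind = kind, units = units)
}

#' Validate a metric table
#'
#' Checks every structural invariant the scoring stages rely on and returns
#' findings rather than throwing: each row names the violated rule and the
#' offending record. An empty result means the table is valid.
#'
#' @param table a [metric_table()].
#' @return tibble with columns `rule` and `detail`; zero rows iff valid.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  obs <- table$observations
  con <- table$conditions
  def <- table$definitions
  findings <- list()
  add <- function(rule, detail) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(rule = rule,
                                                         detail = detail)
  }

  if (anyDuplicated(con$condition_id)) {
    dup <- unique(con$condition_id[duplicated(con$condition_id)])
    add("condition_id_unique", paste("duplicated condition_id:", dup))
  }
  bad_name <- is.na(con$name) | con$name == ""
  if (any(bad_name)) {
    add("condition_name_nonempty",
        paste("empty name for condition:", con$condition_id[bad_name]))
  }
  if (nrow(con) < 2L) {
    add("min_conditions", "fewer than 2 conditions; scoring undefined")
  }

  if (anyDuplicated(def$metric_id)) {
    dup <- unique(def$metric_id[duplicated(def$metric_id)])
    add("metric_id_unique", paste("duplicated metric_id:", dup))
  }
  bad_dom <- !def$domain %in% GAP_DOMAINS
  if (any(bad_dom)) {
    add("domain_vocabulary",
        paste0("metric ", def$metric_id[bad_dom], ": unknown domain '",
               def$domain[bad_dom], "'"))
  }
  bad_dir <- !def$direction %in% GAP_DIRECTIONS
  if (any(bad_dir)) {
    add("direction_vocabulary",
        paste0("metric ", def$metric_id[bad_dir], ": unknown direction '",
               def$direction[bad_dir], "'"))
  }
  bad_kind <- !def$kind %in% GAP_METRIC_KINDS
  if (any(bad_kind)) {
    add("kind_vocabulary",
        paste0("metric ", def$metric_id[bad_kind], ": unknown kind '",
               def$kind[bad_kind], "'"))
  }

  bad_val <- is.na(obs$value) | obs$value < 0 | !is.finite(obs$value)
  if (any(bad_val)) {
    add("value_nonnegative",
        sprintf("observation %s/%s/%s: value %s violates value >= 0",
                obs$condition_id[bad_val], obs$metric_id[bad_val],
                obs$year[bad_val], obs$value[bad_val]))
  }
  orphan_con <- !obs$condition_id %in% con$condition_id
  if (any(orphan_con)) {
    add("observation_condition_registered",
        paste("unregistered condition_id:",
              unique(obs$condition_id[orphan_con])))
  }
  orphan_met <- !obs$metric_id %in% def$metric_id
  if (any(orphan_met)) {
    add("observation_metric_registered",
        paste("unregistered metric_id:", unique(obs$metric_id[orphan_met])))
  }
  key <- paste(obs$condition_id, obs$metric_id, obs$year,
               ifelse(is.na(obs$stratum), "", obs$stratum), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    add("observation_key_unique",
        paste("duplicated (condition, metric, year, stratum) key:",
              gsub("\r", "/", dup)))
  }

  if (length(findings) == 0L) {
    return(tibble::tibble(rule = character(), detail = character()))
  }
  do.call(rbind, findings)
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table> ", nrow(x$conditions), " conditions, ",
      nrow(x$definitions), " metrics, ", nrow(x$observations),
      " observations\n", sep = "")
  tab <- table(x$definitions$domain)
  cat("  metrics by domain:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
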