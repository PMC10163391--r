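# Derived indicators: the Healthy People 2020 disparity summary rate ratio,
# longitudinal trend metrics, and the innovation-deficit complement.

#' Stratified rates for one outcome
#'
#' @param rates named nonnegative numeric vector, one rate per group
#'   (conventionally per 100 000).
#' @param adverse logical; `TRUE` when a lower rate is more favorable
#'   (mortality, YLD), `FALSE` for favorable outcomes.
#' @param outcome optional outcome label.
#' @return object of class `stratified_rates`.
#' @export
stratified_rates <- function(rates, adverse = TRUE, outcome = "") {
  rates <- unlist(rates)
  if (length(rates) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(is.na(rates)) || any(rates < 0)) {
    stop("all rates must be nonnegative", call. = FALSE)
  }
  if (!any(rates > 0)) stop("at least one rate must be positive", call. = FALSE)
  structure(list(rates = rates, adverse = isTRUE(adverse), outcome = outcome),
            class = "stratified_rates")
}

#' Disparity summary rate ratio
#'
#' Ratio of the average rate across all non-reference groups to the most
#' favorable group's rate, oriented so the result is always >= 1 and equals 1
#' exactly when every group has the same rate. For adverse outcomes the most
#' favorable group has the minimum rate and the ratio is
#' `mean(others) / min`; for favorable outcomes it is `max / mean(others)`.
#' Scale-invariant: multiplying all rates by c > 0 leaves the ratio unchanged.
#'
#' @param strata a [stratified_rates()] object, or a named numeric vector of
#'   group rates.
#' @param adverse used when `strata` is a bare numeric vector; see
#'   [stratified_rates()].
#' @return disparity ratio, a scalar >= 1.
#' @export
disparity_ratio <- function(strata, adverse = TRUE) {
  if (!inherits(strata, "stratified_rates")) {
    strata <- stratified_rates(strata, adverse = adverse)
  }
  r <- strata$rates
  if (strata$adverse) {
    ref <- which.min(r)
    if (r[ref] == 0) {
      stop("most favorable rate is 0; disparity ratio undefined",
           call. = FALSE)
    }
    unname(mean(r[-ref]) / r[ref])
  } else {
    ref <- which.max(r)
    others <- mean(r[-ref])
    if (others == 0) {
      stop("mean rate of non-reference groups is 0; disparity ratio undefined",
           call. = FALSE)
    }
    unname(r[ref] / others)
  }
}

#' Summary disparity across stratifications
#'
#' Computes the disparity ratio within each stratification (sex, age,
#' race/ethnicity, ...) and returns the maximum together with the
#' stratification attaining it.
#'
#' @param per_stratification named list of [stratified_rates()] objects (or
#'   named rate vectors), one per stratification.
#' @param adverse applied to bare numeric elements.
#' @return list with `ratio` (max disparity ratio) and `stratification`
#'   (label attaining it).
#' @export
summary_disparity <- function(per_stratification, adverse = TRUE) {
  if (length(per_stratification) < 1L) {
    stop("need at least one stratification", call. = FALSE)
  }
  labs <- names(per_stratification)
  if (is.null(labs)) labs <- as.character(seq_along(per_stratification))
  ratios <- vapply(seq_along(per_stratification), function(i) {
    tryCatch(disparity_ratio(per_stratification[[i]], adverse = adverse),
             error = function(e) {
               stop("stratification '", labs[i], "': ", conditionMessage(e),
                    call. = FALSE)
             })
  }, numeric(1))
  k <- which.max(ratios)
  list(ratio = ratios[[k]], stratification = labs[[k]], ratios = setNames(ratios, labs))
}

#' Longitudinal change between two years
#'
#' @param series named numeric vector of values keyed by calendar year.
#' @param start_year,end_year integer years, both present in `series`,
#'   `end_year > start_year`.
#' @param metric_id optional label carried into the result.
#' @return list with `metric_id`, `start_year`, `end_year`, `absolute_change`
#'   (end minus start, metric units) and `relative_change` (signed fraction of
#'   the start value; `NA` when the start value is 0).
#' @export
trend <- function(series, start_year, end_year, metric_id = "") {
  if (end_year <= start_year) stop("end_year must exceed start_year",
                                   call. = FALSE)
  yrs <- as.character(c(start_year, end_year))
  missing <- yrs[!yrs %in% names(series)]
  if (length(missing)) {
    stop("year(s) missing from series: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v0 <- unname(series[[as.character(start_year)]])
  v1 <- unname(series[[as.character(end_year)]])
  abs_change <- v1 - v0
  rel_change <- if (v0 > 0) abs_change / v0 else NA_real_
  list(metric_id = metric_id, start_year = as.integer(start_year),
       end_year = as.integer(end_year), absolute_change = abs_change,
       relative_change = rel_change)
}

#' Innovation deficit
#'
#' Complement `1 - s` of an innovation activity score: the form in which a
#' lack of innovation is quoted (an activity score of 0.05 is a deficit of
#' 0.95). An involution: `innovation_deficit(innovation_deficit(s)) == s`.
#'
#' @param score numeric vector of innovation activity scores in \[0, 1\].
#' @return `1 - score`.
#' @export
innovation_deficit <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    stop("innovation score must lie in [0, 1]", call. = FALSE)
  }
  1 - score
}
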