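# Scoring pipeline: pilot-condition selection, per-domain TOPSIS scores,
# overall gap, ranking, IQR tiering, and opportunity identification.

#' Select pilot conditions from burden rankings
#'
#' Compiles the top-`k` conditions by each of the named burden metrics at the
#' reference year and returns the deduplicated union, ordered by first
#' appearance (first list first).
#'
#' @param table a [metric_table()] containing the ranking metrics.
#' @param k top-list size per metric (default 10).
#' @param metrics metric ids to rank on, in priority order (default
#'   mortality, prevalence, yld).
#' @param year reference year (default 2019).
#' @return character vector of condition ids.
#' @export
select_pilot_conditions <- function(table, k = 10L,
                                    metrics = c("mortality", "prevalence",
                                                "yld"),
                                    year = 2019L) {
  stopifnot(inherits(table, "metric_table"))
  obs <- table$observations
  lists <- lapply(metrics, function(m) {
    sub <- obs[obs$metric_id == m & obs$year == year & is.na(obs$stratum), ]
    if (nrow(sub) < k) {
      warning("metric '", m, "' has only ", nrow(sub), " conditions at ",
              year, "; using all", call. = FALSE)
    }
    sub$condition_id[order(-sub$value, sub$condition_id)][seq_len(min(k, nrow(sub)))]
  })
  unique(unlist(lists))
}

# Assemble the decision matrix for one domain: cross-sectional criteria,
# trend criteria, and (for stratified metrics) the disparity summary ratio.
# Returns list(values, directions, weights) with NA where a condition lacks a
# value; missing policy is applied by domain_score().
build_domain_criteria <- function(table, domain, config) {
  defs <- table$definitions[table$definitions$domain == domain, ]
  if (nrow(defs) == 0L) {
    stop("no metrics registered for domain '", domain, "'", call. = FALSE)
  }
  conds <- table$conditions$condition_id
  obs <- table$observations
  ry <- config$reference_years

  pull_year <- function(metric, yr) {
    sub <- obs[obs$metric_id == metric & obs$year == yr & is.na(obs$stratum), ]
    out <- setNames(rep(NA_real_, length(conds)), conds)
    out[sub$condition_id] <- sub$value
    out
  }
  cols <- list()
  dirs <- character()

  cs <- defs[defs$kind == "cross_sectional", ]
  for (i in seq_len(nrow(cs))) {
    m <- cs$metric_id[i]
    if (domain == "innovation") {
      sub <- obs[obs$metric_id == m & obs$year %in% ry$innovation &
                   is.na(obs$stratum), ]
      out <- setNames(rep(NA_real_, length(conds)), conds)
      if (nrow(sub)) {
        mu <- tapply(sub$value, sub$condition_id, mean)
        out[names(mu)] <- as.numeric(mu)
      }
      cols[[m]] <- out
    } else {
      yr <- if (domain == "burden") ry$burden else ry$cost
      cols[[m]] <- pull_year(m, yr)
    }
    dirs <- c(dirs, cs$direction[i])
  }

  # longitudinal trend criteria for burden and cost (innovation enters as
  # multi-year means, so no separate trend column)
  if (domain %in% c("burden", "cost")) {
    win <- if (domain == "burden") ry$burden_trend else ry$cost_trend
    form <- config$trend_form[[domain]]
    for (i in seq_len(nrow(cs))) {
      m <- cs$metric_id[i]
      v0 <- pull_year(m, win[1])
      v1 <- pull_year(m, win[2])
      ch <- v1 - v0
      if (form == "relative") {
        ch <- ifelse(!is.na(v0) & v0 > 0, ch / v0, NA_real_)
      }
      cols[[paste0(m, "_trend")]] <- ch
      dirs <- c(dirs, cs$direction[i])
    }
  }

  # disparity summary ratio from stratified metrics; stratum labels are
  # "<stratification>:<group>", e.g. "race_ethnicity:hispanic"
  ds <- defs[defs$kind == "disparity", ]
  for (i in seq_len(nrow(ds))) {
    m <- ds$metric_id[i]
    yr <- if (domain == "burden") ry$burden else ry$cost
    sub <- obs[obs$metric_id == m & obs$year == yr & !is.na(obs$stratum), ]
    out <- setNames(rep(NA_real_, length(conds)), conds)
    for (cid in unique(sub$condition_id)) {
      rows <- sub[sub$condition_id == cid, ]
      strat <- sub("^([^:]*):.*$", "\\1", rows$stratum)
      grp <- sub("^[^:]*:", "", rows$stratum)
      per <- split(setNames(rows$value, grp), strat)
      ok <- vapply(per, function(r) length(r) >= 2 && any(r > 0) && min(r) > 0,
                   logical(1))
      if (any(!ok)) {
        warning("condition '", cid, "', metric '", m,
                "': dropping stratification(s) with absent or zero rates: ",
                paste(names(per)[!ok], collapse = ", "), call. = FALSE)
      }
      per <- per[ok]
      if (length(per)) out[cid] <- summary_disparity(per, adverse = TRUE)$ratio
    }
    cols[[m]] <- out
    dirs <- c(dirs, "gap_increasing")
  }

  values <- do.call(cbind, cols)
  rownames(values) <- conds
  w <- rep(1, ncol(values))
  if (!is.null(config$within_domain_weights)) {
    hit <- match(colnames(values), names(config$within_domain_weights))
    w[!is.na(hit)] <- config$within_domain_weights[hit[!is.na(hit)]]
  }
  list(values = values, directions = dirs, weights = w)
}

apply_missing_policy <- function(values, directions, weights, policy) {
  empty <- colSums(!is.na(values)) == 0L
  if (any(empty)) {
    warning("dropping criterion(s) with no data: ",
            paste(colnames(values)[empty], collapse = ", "), call. = FALSE)
    values <- values[, !empty, drop = FALSE]
    directions <- directions[!empty]
    weights <- weights[!empty]
  }
  miss <- is.na(values)
  if (any(miss)) {
    if (policy == "zero") {
      warning(sum(miss), " missing criterion value(s) set to 0",
              call. = FALSE)
      values[miss] <- 0
    } else if (policy == "drop_criterion") {
      drop <- apply(miss, 2L, any)
      warning("dropping criterion(s) with missing values: ",
              paste(colnames(values)[drop], collapse = ", "), call. = FALSE)
      values <- values[, !drop, drop = FALSE]
      directions <- directions[!drop]
      weights <- weights[!drop]
    } else {
      mu <- colMeans(values, na.rm = TRUE)
      idx <- which(miss, arr.ind = TRUE)
      values[idx] <- mu[idx[, 2L]]
    }
  }
  if (policy == "drop_criterion") {
    zero <- colSums(values != 0) == 0
    if (any(zero)) {
      warning("dropping all-zero criterion(s): ",
              paste(colnames(values)[zero], collapse = ", "), call. = FALSE)
      values <- values[, !zero, drop = FALSE]
      directions <- directions[!zero]
      weights <- weights[!zero]
    }
  }
  if (ncol(values) == 0L) {
    stop("no criteria left after applying missing policy", call. = FALSE)
  }
  list(values = values, directions = directions, weights = weights)
}

#' Compute one domain's score
#'
#' Builds the domain's decision matrix (cross-sectional metrics, trend
#' metrics over the domain's trend window, and the disparity summary ratio
#' for stratified metrics), runs TOPSIS, and orients the score: for burden
#' and cost, high score = high burden/cost (the gap orientation); for
#' innovation, high score = high innovation activity.
#'
#' @param table a validated [metric_table()].
#' @param domain `"burden"`, `"cost"` or `"innovation"`.
#' @param config a [gap_config()].
#' @return object of class `domain_score_set`: list with `domain`, `scores`
#'   (named per condition, in \[0, 1\]), `criteria`, `matrix` (the
#'   [decision_matrix()] used), `trace` (the [gap_scores()] trace) and
#'   `reference_years`.
#' @export
domain_score <- function(table, domain, config = gap_config()) {
  stopifnot(inherits(table, "metric_table"))
  domain <- match.arg(domain, GAP_DOMAINS)
  if (nrow(table$conditions) < 2L) {
    stop("need at least 2 conditions", call. = FALSE)
  }
  crit <- build_domain_criteria(table, domain, config)
  crit <- apply_missing_policy(crit$values, crit$directions, crit$weights,
                               config$missing_policy)
  dm <- decision_matrix(crit$values, crit$directions, crit$weights)
  trace <- gap_scores(dm, normalization = config$normalization)
  scores <- if (domain == "innovation") 1 - trace$gap else trace$gap
  ry <- config$reference_years
  structure(
    list(domain = domain, scores = scores, criteria = colnames(crit$values),
         matrix = dm, trace = trace,
         reference_years = switch(domain,
                                  burden = ry[c("burden", "burden_trend")],
                                  cost = ry[c("cost", "cost_trend")],
                                  innovation = ry["innovation"])),
    class = "domain_score_set"
  )
}

#' Integrate domain scores into the overall gap
#'
#' Hierarchical mode (default) runs TOPSIS on the three domain scores with
#' directions (gap-increasing, gap-increasing, gap-decreasing) and the
#' configured domain weights: the ideal point is the theoretical condition
#' with the lowest burden, lowest cost and highest innovation, the anti-ideal
#' the reverse, and the overall gap is closeness to the anti-ideal. Flat mode
#' pools every underlying metric into one matrix with each domain's weight
#' mass equalized. Ranks are assigned descending by gap score with ties
#' broken by condition name.
#'
#' @param domain_scores named list of three `domain_score_set`s
#'   (`burden`, `cost`, `innovation`) over the same condition set.
#' @param config a [gap_config()].
#' @param conditions optional conditions tibble for display names.
#' @return tibble with `condition_id`, `condition`, `burden`, `cost`,
#'   `innovation`, `overall_gap` and `rank`.
#' @export
overall_gap <- function(domain_scores, config = gap_config(),
                        conditions = NULL) {
  stopifnot(all(GAP_DOMAINS %in% names(domain_scores)))
  ids <- names(domain_scores$burden$scores)
  for (d in GAP_DOMAINS) {
    other <- names(domain_scores[[d]]$scores)
    if (!setequal(ids, other)) {
      stop("condition set mismatch across domains; missing: ",
           paste(union(setdiff(ids, other), setdiff(other, ids)),
                 collapse = ", "), call. = FALSE)
    }
  }
  sb <- domain_scores$burden$scores[ids]
  sc <- domain_scores$cost$scores[ids]
  si <- domain_scores$innovation$scores[ids]

  if (config$aggregation_mode == "hierarchical") {
    values <- cbind(burden = sb, cost = sc, innovation = si)
    dm <- decision_matrix(values,
                          directions = c("gap_increasing", "gap_increasing",
                                         "gap_decreasing"),
                          weights = config$domain_weights[GAP_DOMAINS])
    g <- gap_scores(dm, normalization = config$normalization)$gap
  } else {
    pooled <- lapply(GAP_DOMAINS, function(d) {
      m <- domain_scores[[d]]$matrix
      w <- m$weights / sum(m$weights) * config$domain_weights[[d]]
      list(values = m$values[ids, , drop = FALSE], directions = m$directions,
           weights = w)
    })
    dm <- decision_matrix(do.call(cbind, lapply(pooled, `[[`, "values")),
                          unlist(lapply(pooled, `[[`, "directions")),
                          unlist(lapply(pooled, `[[`, "weights")))
    g <- gap_scores(dm, normalization = config$normalization)$gap
  }

  name <- if (!is.null(conditions)) {
    conditions$name[match(ids, conditions$condition_id)]
  } else ids
  out <- tibble::tibble(condition_id = ids, condition = name,
                        burden = unname(sb), cost = unname(sc),
                        innovation = unname(si),
                        overall_gap = unname(g[ids]))
  out$rank <- rank_by_gap(out$overall_gap, out$condition)
  out
}

# descending rank on the gap score; ties broken by condition name ascending
rank_by_gap <- function(gap, name) {
  ord <- order(-gap, name)
  rk <- integer(length(gap))
  rk[ord] <- seq_along(gap)
  rk
}

#' IQR tier classification
#'
#' Classifies scores as `high` (strictly above Q3), `low` (strictly below
#' Q1) or `middle` (boundary values inclusive).
#'
#' @param scores named numeric vector (at least 4 values).
#' @param quantile_convention `"linear"` ([stats::quantile()] type 7,
#'   interpolated order statistics; the default), `"tukey"` (type 2) or
#'   `"nearest"` (type 3).
#' @return list with `tiers` (named character), `q1` and `q3`.
#' @export
iqr_tiers <- function(scores, quantile_convention = "linear") {
  if (length(scores) < 4L) {
    stop("need at least 4 scores for quartile tiering", call. = FALSE)
  }
  type <- switch(quantile_convention,
                 linear = 7L, tukey = 2L, nearest = 3L,
                 stop("unknown quantile convention: ", quantile_convention,
                      call. = FALSE))
  q <- quantile(scores, c(0.25, 0.75), type = type, names = FALSE)
  tiers <- ifelse(scores > q[2], "high", ifelse(scores < q[1], "low",
                                                "middle"))
  if (is.null(names(tiers)) && !is.null(names(scores))) {
    names(tiers) <- names(scores)
  }
  list(tiers = tiers, q1 = q[1], q3 = q[2])
}

#' Flag innovation-investment opportunities
#'
#' A condition is an innovation opportunity when its innovation activity tier
#' is low while its burden or cost tier is middle or high — innovation lags
#' relative to need. Conditions with both high cost and high innovation are
#' annotated as the high-cost/high-innovation paradox (innovation spending
#' itself may drive cost) but not flagged by this rule.
#'
#' @param scores tibble with columns `condition_id`, `burden_tier`,
#'   `cost_tier`, `innovation_tier`.
#' @return tibble with `condition_id`, `opportunity_flag` and `reason`.
#' @export
identify_opportunities <- function(scores) {
  req <- c("condition_id", "burden_tier", "cost_tier", "innovation_tier")
  stopifnot(all(req %in% names(scores)))
  up <- c("middle", "high")
  flag <- scores$innovation_tier == "low" &
    (scores$burden_tier %in% up | scores$cost_tier %in% up)
  reason <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    if (flag[i]) {
      parts <- c(
        if (scores$burden_tier[i] %in% up)
          paste0(scores$burden_tier[i], " public health burden"),
        if (scores$cost_tier[i] %in% up)
          paste0(scores$cost_tier[i], " health care cost")
      )
      reason[i] <- paste0("low innovation activity relative to ",
                          paste(parts, collapse = " and "))
    } else if (scores$innovation_tier[i] == "high" &&
               scores$cost_tier[i] == "high") {
      reason[i] <- paste("high-cost/high-innovation paradox:",
                         "cost growth may itself reflect innovation uptake")
    }
  }
  tibble::tibble(condition_id = scores$condition_id,
                 opportunity_flag = flag, reason = reason)
}

#' Run the full scoring pipeline
#'
#' Validates the table, computes the three domain scores, integrates them
#' into the overall gap, assigns ranks, IQR tiers (per domain and overall),
#' and opportunity flags.
#'
#' @param table a [metric_table()].
#' @param config a [gap_config()].
#' @return object of class `gap_results`: list with `scores` (one tibble row
#'   per condition), `quartiles` (Q1/Q3 per score kind), `domains` (the three
#'   `domain_score_set`s) and `config`.
#' @export
gap_pipeline <- function(table, config = gap_config()) {
  findings <- validate_table(table)
  if (nrow(findings)) {
    stop("metric table failed validation:\n",
         paste(" -", findings$rule, ":", findings$detail, collapse = "\n"),
         call. = FALSE)
  }
  domains <- setNames(
    lapply(GAP_DOMAINS, function(d) domain_score(table, d, config)),
    GAP_DOMAINS
  )
  scores <- overall_gap(domains, config, conditions = table$conditions)
  finalize_results(scores, config, domains = domains)
}

# shared tail of full and report-only runs: tiers, flags, result object
finalize_results <- function(scores, config, domains = NULL) {
  tiers <- list()
  quartiles <- list()
  for (kind in c("burden", "cost", "innovation", "overall_gap")) {
    t <- iqr_tiers(setNames(scores[[kind]], scores$condition_id),
                   config$quantile_convention)
    col <- sub("_gap$", "", kind)
    scores[[paste0(col, "_tier")]] <- unname(t$tiers)
    quartiles[[col]] <- c(q1 = t$q1, q3 = t$q3)
  }
  opp <- identify_opportunities(scores)
  scores$opportunity_flag <- opp$opportunity_flag
  scores$reason <- opp$reason
  scores <- scores[order(scores$rank), ]
  structure(list(scores = scores, quartiles = quartiles, domains = domains,
                 config = config),
            class = "gap_results")
}

#' Rank and tier a pre-computed score table
#'
#' Report-only entry point: takes per-condition domain scores (and optionally
#' an already-computed overall gap score, which is then used as-is rather
#' than recomputed), assigns ranks, IQR tiers and opportunity flags.
#'
#' @param scores tibble from [read_score_csv()]: `condition`, `burden`,
#'   `cost`, `innovation`, optional `overall_gap`.
#' @param config a [gap_config()].
#' @return a `gap_results` object (see [gap_pipeline()]).
#' @export
rank_conditions <- function(scores, config = gap_config()) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (!"condition_id" %in% names(scores)) {
    scores$condition_id <- scores$condition
  }
  if (!"overall_gap" %in% names(scores)) {
    dm <- decision_matrix(
      as.matrix(scores[, c("burden", "cost", "innovation")]),
      directions = c("gap_increasing", "gap_increasing", "gap_decreasing"),
      weights = config$domain_weights[GAP_DOMAINS]
    )
    scores$overall_gap <- unname(
      gap_scores(dm, normalization = config$normalization)$gap)
  }
  scores$rank <- rank_by_gap(scores$overall_gap, scores$condition)
  cols <- c("condition_id", "condition", "burden", "cost", "innovation",
            "overall_gap", "rank")
  finalize_results(scores[cols], config)
}

#' @export
print.gap_results <- function(x, ...) {
  cat("<gap_results> ", nrow(x$scores), " conditions\n", sep = "")
  print(x$scores[, c("condition", "burden", "cost", "innovation",
                     "overall_gap", "rank", "opportunity_flag")])
  invisible(x)
}
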