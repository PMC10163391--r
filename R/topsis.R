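# TOPSIS engine: normalization, weighting, ideal/anti-ideal reference points,
# Euclidean separations, and the gap score (closeness to the anti-ideal).

#' Construct a decision matrix
#'
#' Alternatives (conditions) by criteria (metrics or domain scores), with a
#' direction flag and a positive weight per criterion.
#'
#' @param values numeric matrix, alternatives in rows, criteria in columns.
#'   Row and column names, if absent, are generated.
#' @param directions length-`ncol` character vector; `gap_increasing` means
#'   larger raw values push an alternative towards the anti-ideal (worst)
#'   point, `gap_decreasing` the reverse.
#' @param weights length-`ncol` positive weights; default equal. Only relative
#'   magnitude matters: the engine normalizes weights to sum to 1.
#' @return object of class `decision_matrix`.
#' @export
decision_matrix <- function(values, directions, weights = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("alt", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("crit", seq_len(ncol(values)))
  }
  m <- ncol(values)
  if (length(directions) == 1L) directions <- rep(directions, m)
  if (length(directions) != m || !all(directions %in% GAP_DIRECTIONS)) {
    stop("directions must be length ", m, " with values in {",
         paste(GAP_DIRECTIONS, collapse = ", "), "}", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) == 1L) weights <- rep(weights, m)
  if (length(weights) != m || any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be ", m, " positive finite values", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(list(values = values, directions = unname(directions),
                 weights = unname(as.numeric(weights))),
            class = "decision_matrix")
}

#' Normalize a decision matrix
#'
#' @param x a [decision_matrix()] or plain numeric matrix.
#' @param method `"vector"` (root-sum-square per column, the classic TOPSIS
#'   choice) or `"minmax"` (column range scaling; constant columns map to
#'   0.5).
#' @return normalized numeric matrix `r_ij`.
#' @export
topsis_normalize <- function(x, method = c("vector", "minmax")) {
  method <- match.arg(method)
  v <- if (inherits(x, "decision_matrix")) x$values else as.matrix(x)
  if (method == "vector") {
    nrm <- sqrt(colSums(v^2))
    if (any(nrm == 0)) {
      stop("degenerate all-zero column(s) under vector normalization: ",
           paste(colnames(v)[nrm == 0], collapse = ", "), call. = FALSE)
    }
    sweep(v, 2L, nrm, "/")
  } else {
    lo <- apply(v, 2L, min)
    hi <- apply(v, 2L, max)
    rng <- hi - lo
    r <- sweep(sweep(v, 2L, lo, "-"), 2L, ifelse(rng == 0, 1, rng), "/")
    r[, rng == 0] <- 0.5
    r
  }
}

#' Ideal and anti-ideal reference points
#'
#' The ideal point `a_best` holds, per criterion, the most favorable weighted
#' value (the minimum for `gap_increasing` criteria, the maximum for
#' `gap_decreasing`); `a_worst` holds the least favorable.
#'
#' @param weighted weighted normalized matrix `v_ij`.
#' @param directions per-column direction flags.
#' @return list with numeric vectors `a_best` and `a_worst` (length `ncol`).
#' @export
reference_points <- function(weighted, directions) {
  stopifnot(ncol(weighted) == length(directions),
            all(directions %in% GAP_DIRECTIONS))
  lo <- apply(weighted, 2L, min)
  hi <- apply(weighted, 2L, max)
  inc <- directions == "gap_increasing"
  list(a_best = ifelse(inc, lo, hi), a_worst = ifelse(inc, hi, lo))
}

#' TOPSIS gap scores
#'
#' Runs the full TOPSIS computation on a decision matrix: normalize, weight
#' (weights rescaled to sum to 1), locate the ideal and anti-ideal reference
#' points, take Euclidean separations, and score each alternative by its
#' relative closeness to the *anti-ideal*:
#' `G_i = d_best_i / (d_best_i + d_worst_i)`. High scores mean a large gap
#' (close to the worst point: high burden/cost, low innovation); an
#' alternative coinciding with the ideal point scores 0, with the anti-ideal
#' 1. When all alternatives are identical (`d_best = d_worst = 0`) every score
#' is 0.5 by convention.
#'
#' @param matrix a [decision_matrix()] with at least 2 alternatives.
#' @param normalization `"vector"` or `"minmax"`; see [topsis_normalize()].
#' @return object of class `topsis_trace`: list with `normalized`, `weighted`,
#'   `ideal`, `anti_ideal`, `d_best`, `d_worst` and `gap` (named per
#'   alternative).
#' @examples
#' dm <- decision_matrix(rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6)),
#'                       directions = "gap_increasing")
#' gap_scores(dm)$gap
#' @export
gap_scores <- function(matrix, normalization = c("vector", "minmax")) {
  stopifnot(inherits(matrix, "decision_matrix"))
  normalization <- match.arg(normalization)
  n <- nrow(matrix$values)
  if (n < 2L) {
    stop("need at least 2 alternatives; relative ranking undefined",
         call. = FALSE)
  }
  r <- topsis_normalize(matrix, normalization)
  w <- matrix$weights / sum(matrix$weights)
  v <- sweep(r, 2L, w, "*")
  ref <- reference_points(v, matrix$directions)
  d_best <- sqrt(rowSums(sweep(v, 2L, ref$a_best, "-")^2))
  d_worst <- sqrt(rowSums(sweep(v, 2L, ref$a_worst, "-")^2))
  denom <- d_best + d_worst
  gap <- ifelse(denom > 0, d_best / denom, 0.5)
  structure(
    list(normalized = r, weighted = v, ideal = ref$a_best,
         anti_ideal = ref$a_worst, d_best = d_best, d_worst = d_worst,
         gap = setNames(as.numeric(gap), rownames(matrix$values))),
    class = "topsis_trace"
  )
}

#' @export
print.topsis_trace <- function(x, ...) {
  cat("<topsis_trace> ", length(x$gap), " alternatives, ",
      length(x$ideal), " criteria\n", sep = "")
  print(round(x$gap, 4))
  invisible(x)
}
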