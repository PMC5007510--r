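# Exhaustive simplex grid search for aggregation weights.

#' Enumerate the standard probability simplex on a grid
#'
#' All k-tuples of non-negative multiples of `step` that sum to 1, in
#' ascending lexicographic order. `1/step` must be an integer; the grid
#' has `choose(1/step + k - 1, k - 1)` points.
#'
#' @param k Number of predictors (>= 1).
#' @param step Grid resolution in (0, 1].
#' @return An object of class `weight_grid`: `step`, `k`, and `points`
#'   (matrix, one row per grid point).
#' @export
#' @examples
#' enumerate_simplex(2, 0.5)$points  # (0,1), (0.5,0.5), (1,0)
enumerate_simplex <- function(k, step) {
  stopifnot(k >= 1, step > 0, step <= 1)
  n <- 1 / step
  if (abs(n - round(n)) > 1e-9) stop("non-integral 1/step")
  n <- as.integer(round(n))
  compose <- function(total, parts) {
    if (parts == 1L) return(matrix(total, ncol = 1L))
    out <- vector("list", total + 1L)
    for (i in 0:total) {
      rest <- compose(total - i, parts - 1L)
      out[[i + 1L]] <- cbind(i, rest)
    }
    do.call(rbind, out)
  }
  counts <- compose(n, as.integer(k))
  dimnames(counts) <- NULL
  structure(list(step = step, k = as.integer(k), points = counts / n),
            class = "weight_grid")
}

#' @export
print.weight_grid <- function(x, ...) {
  cat("Simplex grid: k = ", x$k, ", step = ", x$step, ", ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

# Per-query precomputation shared by every grid point: union targets,
# the (targets x k) min-max-normalized score matrix (missing target -> 0),
# jackknife labels and label totals.
precompute_query_matrices <- function(score_lists, benchmark, queries,
                                      exclude_same_family = FALSE) {
  k <- length(score_lists)
  lapply(queries, function(q) {
    per_pred <- lapply(score_lists, function(by_query) by_query[[q]])
    targets <- sort(unique(unlist(lapply(per_pred, function(rl) {
      if (is.null(rl)) character(0) else rl$targets
    }))), method = "radix")
    N <- matrix(0, nrow = length(targets), ncol = k)
    for (j in seq_len(k)) {
      rl <- per_pred[[j]]
      if (is.null(rl) || length(rl$targets) == 0) next
      nv <- minmax_normalize(rl)
      N[match(names(nv), targets), j] <- nv
    }
    labs <- label_targets(q, benchmark, exclude_same_family)
    list(query_id = q, targets = targets, N = N,
         lab_in = labs[match(targets, names(labs))],
         p_total = sum(labs == "positive"),
         n_total = sum(labs == "negative"))
  })
}

# Mean ROC_n across evaluable queries for one weight vector, using the
# precomputed matrices. Ordering per query: S descending, then target id
# ascending — identical to aggregate_rankings().
mean_roc_at_weights <- function(pre, w, n) {
  vals <- vapply(pre, function(qd) {
    if (qd$p_total == 0) return(NA_real_)
    s <- as.vector(qd$N %*% w)
    ord <- c_order(-s, qd$targets)
    lab <- qd$lab_in[ord]
    keep <- !is.na(lab) & lab != "ignore"
    roc_from_ordered(lab[keep] == "positive", qd$p_total, qd$n_total, n)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Grid search for aggregation weights on the simplex
#'
#' For every point of a simplex grid, aggregates the predictors' ranking
#' lists with those weights and evaluates mean ROC1 (or ROC50) under the
#' jackknife protocol; returns the argmax. Ties are broken by the earliest
#' grid point in ascending lexicographic weight order. The per-query
#' min-max normalizations are computed once and re-weighted per grid
#' point, which is exactly equivalent to re-running
#' [aggregate_rankings()] + [jackknife_evaluate()] at each point.
#'
#' @param score_lists Named list (by predictor id) of named lists (by
#'   query id) of [ranking_list] objects. A predictor missing a query
#'   contributes 0 for every target of that query.
#' @param benchmark A [benchmark_dataset].
#' @param grid A `weight_grid` from [enumerate_simplex()] with
#'   `k = length(score_lists)`.
#' @param objective `"mean_roc1"` (default) or `"mean_roc50"`.
#' @param exclude_same_family Passed to [label_targets()].
#' @return An object of class `search_result`: `best_weights` (named),
#'   `best_score`, `objective`, and `trace` (data frame of all grid
#'   points with their scores).
#' @export
grid_search_weights <- function(score_lists, benchmark, grid,
                                objective = c("mean_roc1", "mean_roc50"),
                                exclude_same_family = FALSE) {
  objective <- match.arg(objective)
  stopifnot(inherits(grid, "weight_grid"))
  if (is.null(names(score_lists)) || any(names(score_lists) == "")) {
    stop("score_lists must be named by predictor id")
  }
  if (grid$k != length(score_lists)) {
    stop("grid k (", grid$k, ") != number of predictors (",
         length(score_lists), ")")
  }
  if (nrow(grid$points) == 0) stop("empty grid")
  queries <- sort(unique(unlist(lapply(score_lists, names))),
                  method = "radix")
  if (!length(queries)) stop("no queries in score_lists")
  pre <- precompute_query_matrices(score_lists, benchmark, queries,
                                   exclude_same_family)
  n_trunc <- if (objective == "mean_roc1") 1 else 50
  scores <- apply(grid$points, 1L, function(w) {
    mean_roc_at_weights(pre, w, n_trunc)
  })
  best <- which.max(scores)  # first max = earliest lexicographic point
  trace <- as.data.frame(grid$points)
  names(trace) <- names(score_lists)
  trace$score <- scores
  structure(list(best_weights = setNames(grid$points[best, ],
                                         names(score_lists)),
                 best_score = scores[best],
                 objective = objective,
                 trace = trace),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Weight search (", x$objective, "): best score ",
      format(x$best_score, digits = 4), " at\n  ",
      paste0(names(x$best_weights), " = ", round(x$best_weights, 6),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a weight-search result to JSON
#'
#' @param result A `search_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_weights_json <- function(result, path) {
  jsonlite::write_json(
    list(predictors = names(result$best_weights),
         weights = unname(result$best_weights),
         objective = result$objective,
         score = result$best_score),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
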