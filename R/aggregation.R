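# Ranking lists and min-max-normalized linear weighted rank aggregation.

#' Construct a ranking list
#'
#' One predictor's scored candidate list for one query. Scores are raw,
#' higher-is-better values (direction conversion is the parsers' job);
#' entries are re-sorted by score descending on construction (stable, so
#' tied entries keep input order).
#'
#' @param query_id Query identifier.
#' @param predictor_id Predictor identifier.
#' @param targets Character vector of target ids (unique).
#' @param scores Numeric vector of raw scores, same length.
#' @return An object of class `ranking_list` with elements `query_id`,
#'   `predictor_id`, `targets`, `scores` (sorted descending).
#' @export
ranking_list <- function(query_id, predictor_id, targets = character(0),
                         scores = numeric(0)) {
  targets <- as.character(targets)
  scores <- as.numeric(scores)
  if (length(targets) != length(scores)) {
    stop("targets and scores must have equal length")
  }
  if (anyDuplicated(targets)) stop("duplicate target ids in ranking list")
  if (length(scores) && any(!is.finite(scores))) {
    stop("ranking scores must be finite")
  }
  ord <- order(-scores)
  structure(list(query_id = query_id, predictor_id = predictor_id,
                 targets = targets[ord], scores = scores[ord]),
            class = "ranking_list")
}

#' @export
print.ranking_list <- function(x, ...) {
  cat("Ranking list [", x$predictor_id, "] query '", x$query_id, "': ",
      length(x$targets), " targets\n", sep = "")
  if (length(x$targets)) {
    show <- head(seq_along(x$targets), 5L)
    cat(paste0("  ", x$targets[show], "\t", signif(x$scores[show], 6),
               collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @export
length.ranking_list <- function(x) length(x$targets)

#' Min-max normalize a ranking list's scores
#'
#' Maps each raw score s to (s - min) / (max - min) over this query's list
#' only, so the best hit gets 1 and the worst 0. Degenerate lists
#' (max == min, including single-hit lists) map every entry to 1.0: a
#' predictor's only or equally-scored hits are its best hits.
#'
#' @param rl A [ranking_list].
#' @return Named numeric vector (names = target ids) in `[0, 1]`.
#' @export
#' @examples
#' rl <- ranking_list("q", "p", c("t1", "t2", "t3"), c(10, 5, 0))
#' minmax_normalize(rl)  # 1.0 0.5 0.0
minmax_normalize <- function(rl) {
  stopifnot(inherits(rl, "ranking_list"))
  if (length(rl$scores) == 0) stop("empty ranking list")
  rng <- range(rl$scores)
  norm <- if (rng[1] == rng[2]) {
    rep(1, length(rl$scores))
  } else {
    (rl$scores - rng[1]) / (rng[2] - rng[1])
  }
  setNames(norm, rl$targets)
}

#' Construct an aggregation model
#'
#' Holds per-predictor weights w_j (a convex combination: non-negative,
#' summing to 1) and the fixed policies: a target absent from a
#' predictor's list contributes 0 for that predictor, and degenerate
#' normalization maps to 1.
#'
#' @param weights Named numeric vector, names = predictor ids.
#' @return An object of class `aggregation_model`.
#' @export
aggregation_model <- function(weights) {
  weights <- unlist(weights)
  if (is.null(names(weights)) || any(names(weights) == "")) {
    stop("weights must be named by predictor id")
  }
  if (any(weights < 0)) stop("negative weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(list(weights = weights,
                 missing_score_policy = "zero",
                 degenerate_norm_policy = "all_one"),
            class = "aggregation_model")
}

#' Aggregate several predictors' ranking lists for one query
#'
#' Over the union of target ids, computes the aggregation score
#' S(p_i) = sum_j w_j * norm_j(p_i), where norm_j is the per-predictor
#' min-max normalized score and norm_j(p_i) = 0 when predictor j did not
#' return target p_i. The result is sorted by S descending, ties broken by
#' ascending target id (C collation). Predictors named in the model but
#' absent from `lists` (or supplying an empty list) contribute 0
#' everywhere.
#'
#' @param lists List of [ranking_list] objects sharing one query id, at
#'   most one per predictor.
#' @param model An [aggregation_model] with a weight for every predictor
#'   appearing in `lists`.
#' @return An object of class `aggregated_ranking` with elements
#'   `query_id`, `targets`, `scores` (S values in `[0, 1]`, descending).
#' @export
aggregate_rankings <- function(lists, model) {
  stopifnot(inherits(model, "aggregation_model"))
  if (inherits(lists, "ranking_list")) lists <- list(lists)
  if (!length(lists)) stop("no ranking lists supplied")
  qids <- unique(vapply(lists, `[[`, character(1), "query_id"))
  if (length(qids) != 1L) stop("mismatched query_ids")
  pids <- vapply(lists, `[[`, character(1), "predictor_id")
  if (anyDuplicated(pids)) stop("duplicate predictor in lists")
  missing_w <- setdiff(pids, names(model$weights))
  if (length(missing_w)) {
    stop("no weight for predictor(s): ", paste(missing_w, collapse = ", "))
  }
  union_targets <- sort(unique(unlist(lapply(lists, `[[`, "targets"))),
                        method = "radix")
  s <- setNames(numeric(length(union_targets)), union_targets)
  for (rl in lists) {
    if (length(rl$targets) == 0) next  # absent predictor: 0 contribution
    nv <- minmax_normalize(rl)
    s[names(nv)] <- s[names(nv)] + model$weights[[rl$predictor_id]] * nv
  }
  ord <- c_order(-s, union_targets)
  structure(list(query_id = qids, targets = union_targets[ord],
                 scores = unname(s[ord])),
            class = "aggregated_ranking")
}

#' @export
print.aggregated_ranking <- function(x, ...) {
  cat("Aggregated ranking for query '", x$query_id, "': ",
      length(x$targets), " targets\n", sep = "")
  invisible(x)
}

#' @export
length.aggregated_ranking <- function(x) length(x$targets)

#' Aggregate a single predictor with weight 1
#'
#' Equivalence harness: min-max normalization is strictly increasing on
#' non-degenerate lists, so the output order equals the input order (up to
#' the lexicographic tie rule on tied scores).
#'
#' @param rl A [ranking_list].
#' @return An `aggregated_ranking`.
#' @export
single_predictor_aggregate <- function(rl) {
  stopifnot(inherits(rl, "ranking_list"))
  aggregate_rankings(list(rl), aggregation_model(setNames(1, rl$predictor_id)))
}

#' Read a generic 3-column ranking TSV
#'
#' Format: `query_id <TAB> target_id <TAB> score`, no header; lines
#' starting with `#` are skipped. By default the file must hold a single
#' query; with `multi = TRUE` it is split into one list per query.
#' Duplicate (query, target) rows keep the maximum score.
#'
#' @param path Path to the TSV.
#' @param predictor_id Predictor id to stamp on the result(s); defaults to
#'   the file name without extension.
#' @param multi Allow multiple queries (returns a named list of
#'   [ranking_list], names = query ids).
#' @return A [ranking_list], or a named list of them when `multi = TRUE`.
#' @export
parse_generic_tsv <- function(path, predictor_id = NULL, multi = FALSE) {
  if (is.null(predictor_id)) {
    predictor_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  if (ncol(df) != 3L) stop("expected 3 columns in generic ranking TSV")
  names(df) <- c("query_id", "target_id", "score")
  qids <- unique(df$query_id)
  if (!multi && length(qids) > 1L) {
    stop("mixed query_ids in one file (use multi = TRUE)")
  }
  build <- function(sub, qid) {
    best <- tapply(sub$score, sub$target_id, max)
    ranking_list(qid, predictor_id, names(best), as.numeric(best))
  }
  if (!multi) {
    build(df, qids)
  } else {
    setNames(lapply(qids, function(q) build(df[df$query_id == q, ], q)), qids)
  }
}

#' Write ranking lists to a generic TSV
#'
#' @param rl A [ranking_list], `aggregated_ranking`, or list of either.
#' @param path Output path.
#' @param weights Optional named weights; when given, a
#'   `# weights: predictor=weight,...` header line is written (the
#'   aggregated-output convention).
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(rl, path, weights = NULL) {
  if (inherits(rl, c("ranking_list", "aggregated_ranking"))) rl <- list(rl)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(weights)) {
    writeLines(paste0("# weights: ",
                      paste0(names(weights), "=", weights, collapse = ",")),
               con)
  }
  for (x in rl) {
    if (length(x$targets)) {
      writeLines(paste(x$query_id, x$targets,
                       format(x$scores, digits = 17, trim = TRUE,
                              scientific = FALSE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
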