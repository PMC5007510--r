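# Benchmark container, truncated-ROC metrics and jackknife evaluation.

#' Construct a family/superfamily labelled benchmark
#'
#' SCOP-style hierarchy: each sequence belongs to one family, each family
#' to exactly one superfamily. Same-superfamily pairs are presumed
#' homologous and form the positives of ranked-retrieval evaluation.
#'
#' @param records Data frame with columns `seq_id`, `family_id`,
#'   `superfamily_id` (coerced to character).
#' @param sequences Optional named character vector of residue strings.
#' @return An object of class `benchmark_dataset`.
#' @export
benchmark_dataset <- function(records, sequences = NULL) {
  need <- c("seq_id", "family_id", "superfamily_id")
  if (!all(need %in% names(records))) {
    stop("records must have columns seq_id, family_id, superfamily_id")
  }
  records <- data.frame(lapply(records[need], as.character),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(records$seq_id)) stop("duplicate seq_ids in benchmark")
  fam_sf <- unique(records[c("family_id", "superfamily_id")])
  if (anyDuplicated(fam_sf$family_id)) {
    stop("a family maps to more than one superfamily")
  }
  if (length(unique(records$superfamily_id)) < 2L) {
    warning("fewer than 2 superfamilies: evaluation is degenerate")
  }
  if (!is.null(sequences)) {
    missing <- setdiff(records$seq_id, names(sequences))
    if (length(missing)) {
      stop("sequences missing for: ", paste(head(missing, 3), collapse = ", "))
    }
    sequences <- sequences[records$seq_id]
  }
  structure(list(records = records, sequences = sequences),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  s <- benchmark_summary(x)
  cat("Benchmark: ", s$n_sequences, " sequences, ", s$n_families,
      " families, ", s$n_superfamilies, " superfamilies\n", sep = "")
  invisible(x)
}

#' Integrity summary of a benchmark
#'
#' @param benchmark A [benchmark_dataset].
#' @return List with `n_sequences`, `n_families`, `n_superfamilies`.
#' @export
benchmark_summary <- function(benchmark) {
  r <- benchmark$records
  list(n_sequences = nrow(r),
       n_families = length(unique(r$family_id)),
       n_superfamilies = length(unique(r$superfamily_id)))
}

#' Read a benchmark label TSV
#'
#' Format: `seq_id <TAB> family_id <TAB> superfamily_id`, no header,
#' `#` comments skipped.
#'
#' @param path Path to the TSV.
#' @param fasta Optional FASTA of the sequences.
#' @return A [benchmark_dataset].
#' @export
read_benchmark_tsv <- function(path, fasta = NULL) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) != 3L) stop("expected 3 columns in benchmark TSV")
  names(df) <- c("seq_id", "family_id", "superfamily_id")
  sequences <- NULL
  if (!is.null(fasta)) {
    set <- Biostrings::readAAStringSet(fasta)
    sequences <- as.character(set)
    names(sequences) <- vapply(strsplit(names(set), "\\s+"), `[`,
                               character(1), 1L)
  }
  benchmark_dataset(df, sequences)
}

#' Write benchmark labels to TSV
#' @param benchmark A [benchmark_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(benchmark, path) {
  write.table(benchmark$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Label benchmark members relative to one query
#'
#' Jackknife labelling: a target is `positive` iff it shares the query's
#' superfamily (and is not the query itself); every other benchmark member
#' is `negative`. With `exclude_same_family = TRUE`, same-family members
#' are labelled `ignore` (neither positive nor negative), leaving only
#' remote (same superfamily, different family) positives.
#'
#' @param query_id Query sequence id (must be in the benchmark).
#' @param benchmark A [benchmark_dataset].
#' @param exclude_same_family Flip same-family members to `ignore`.
#' @return Named character vector over all non-query seq_ids with values
#'   `"positive"`, `"negative"` or `"ignore"`.
#' @export
label_targets <- function(query_id, benchmark, exclude_same_family = FALSE) {
  r <- benchmark$records
  qi <- match(query_id, r$seq_id)
  if (is.na(qi)) stop("unknown query: ", query_id)
  others <- r[-qi, , drop = FALSE]
  lab <- ifelse(others$superfamily_id == r$superfamily_id[qi],
                "positive", "negative")
  if (exclude_same_family) {
    lab[others$family_id == r$family_id[qi]] <- "ignore"
  }
  setNames(lab, others$seq_id)
}

# Truncated ROC area from an ordered positive-indicator vector.
# is_pos: labels of ranking entries in rank order (labeled pos/neg only);
# p_total / n_neg_total: label totals including targets absent from the
# ranking. Absent positives rank after every entry and every false
# positive, so they never contribute; absent negatives supply "virtual"
# false positives after the list's end, before which every returned
# positive counts.
roc_from_ordered <- function(is_pos, p_total, n_neg_total, n) {
  if (p_total == 0) stop("no positives")
  pos_in <- sum(is_pos)
  if (n_neg_total == 0) {
    return(pos_in / p_total)
  }
  m <- min(n, n_neg_total)
  fp_idx <- which(!is_pos)
  nf <- length(fp_idx)
  cum_pos <- cumsum(is_pos)
  k <- seq_len(min(m, nf))
  tp_sum <- sum(cum_pos[fp_idx[k]]) + max(0L, m - nf) * pos_in
  tp_sum / (m * p_total)
}

#' Truncated ROC score (ROC_n) of a ranking
#'
#' Area under the true-positive vs false-positive step curve up to the
#' n-th false positive, normalized to `[0, 1]`:
#' `ROC_n = sum_{k=1..m} TP(k) / (m * P)`, where `TP(k)` is the number of
#' positives ranked strictly before the k-th false positive,
#' `m = min(n, #negatives)` and `P` the number of labelled positives.
#' Positives absent from the ranking count as ranked after every returned
#' entry and after all false positives. With zero labelled negatives the
#' score is the fraction of positives returned. Entries labelled `ignore`
#' or not present in `labels` (e.g. the query itself) are dropped before
#' scoring.
#'
#' @param ranking A [ranking_list] or `aggregated_ranking` (entry order is
#'   the rank order; ties were already resolved upstream).
#' @param labels Named label vector from [label_targets()].
#' @param n Truncation point (1 for ROC1, 50 for ROC50).
#' @return ROC_n in `[0, 1]`.
#' @export
#' @examples
#' labs <- c(a = "positive", b = "negative", c = "positive", d = "negative")
#' rl <- ranking_list("q", "p", c("a", "b", "c", "d"), c(4, 3, 2, 1))
#' roc_n(rl, labs, 2)  # (1 + 2) / (2 * 2) = 0.75
roc_n <- function(ranking, labels, n) {
  stopifnot(n >= 1)
  lab_in <- labels[match(ranking$targets, names(labels))]
  keep <- !is.na(lab_in) & lab_in != "ignore"
  roc_from_ordered(lab_in[keep] == "positive",
                   p_total = sum(labels == "positive"),
                   n_neg_total = sum(labels == "negative"),
                   n = n)
}

#' Jackknife ranked-retrieval evaluation
#'
#' Each query's ranking is scored against the remaining benchmark members
#' (leave-one-out: the query's own hit is removed before scoring) with
#' ROC1 and ROC50. Queries with no labelled positive (sole members of
#' their superfamily) are reported as non-evaluable and excluded from the
#' means.
#'
#' @param rankings List of per-query rankings ([ranking_list] or
#'   `aggregated_ranking`), one per query.
#' @param benchmark A [benchmark_dataset] covering every query.
#' @param exclude_same_family Passed to [label_targets()].
#' @return An object of class `eval_summary`: `mean_roc1`, `mean_roc50`,
#'   and `per_query` (data frame with `query_id`, `roc1`, `roc50`,
#'   `n_pos`, `n_neg`, `evaluable`).
#' @export
jackknife_evaluate <- function(rankings, benchmark,
                               exclude_same_family = FALSE) {
  if (inherits(rankings, c("ranking_list", "aggregated_ranking"))) {
    rankings <- list(rankings)
  }
  qids <- vapply(rankings, `[[`, character(1), "query_id")
  if (anyDuplicated(qids)) stop("duplicate query in rankings")
  rows <- lapply(seq_along(rankings), function(i) {
    labs <- label_targets(qids[i], benchmark, exclude_same_family)
    n_pos <- sum(labs == "positive")
    n_neg <- sum(labs == "negative")
    if (n_pos == 0) {
      data.frame(query_id = qids[i], roc1 = NA_real_, roc50 = NA_real_,
                 n_pos = n_pos, n_neg = n_neg, evaluable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(query_id = qids[i],
                 roc1 = roc_n(rankings[[i]], labs, 1),
                 roc50 = roc_n(rankings[[i]], labs, 50),
                 n_pos = n_pos, n_neg = n_neg, evaluable = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  per_query <- do.call(rbind, rows)
  ev <- per_query$evaluable
  structure(list(mean_roc1 = mean(per_query$roc1[ev]),
                 mean_roc50 = mean(per_query$roc50[ev]),
                 per_query = per_query),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Jackknife evaluation over ", sum(x$per_query$evaluable),
      " evaluable / ", nrow(x$per_query), " queries\n",
      "  mean ROC1  = ", format(x$mean_roc1, digits = 4), "\n",
      "  mean ROC50 = ", format(x$mean_roc50, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Exceedance curve of per-query performance
#'
#' For each distinct per-query score t (plus t = 0), the fraction of
#' evaluable queries whose score is >= t: the "percentage of queries
#' exceeding a given performance" survival curve. Monotone non-increasing;
#' the fraction at threshold 0 is 1.
#'
#' @param summary An `eval_summary`.
#' @param metric `"roc1"` or `"roc50"`.
#' @return Data frame with columns `threshold`, `fraction`.
#' @export
exceedance_curve <- function(summary, metric = c("roc1", "roc50")) {
  metric <- match.arg(metric)
  scores <- summary$per_query[[metric]][summary$per_query$evaluable]
  if (!length(scores)) stop("no evaluable queries")
  thresholds <- sort(unique(c(0, scores)))
  fraction <- vapply(thresholds, function(t) mean(scores >= t), numeric(1))
  data.frame(threshold = thresholds, fraction = fraction)
}

#' Pairwise per-query comparison of two evaluations
#'
#' Pairs per-query scores of two methods over the same query set (the
#' scatter-around-the-diagonal comparison) and counts wins, ties and
#' losses for method a.
#'
#' @param summary_a,summary_b `eval_summary` objects over identical query
#'   sets.
#' @param metric `"roc1"` or `"roc50"`.
#' @param tol Tie tolerance (default 1e-9).
#' @return List with `table` (data frame `query_id`, `score_a`, `score_b`)
#'   and counts `wins`, `ties`, `losses`.
#' @export
pairwise_compare <- function(summary_a, summary_b,
                             metric = c("roc1", "roc50"), tol = 1e-9) {
  metric <- match.arg(metric)
  a <- summary_a$per_query[summary_a$per_query$evaluable, ]
  b <- summary_b$per_query[summary_b$per_query$evaluable, ]
  if (!setequal(a$query_id, b$query_id)) stop("query-set mismatch")
  b <- b[match(a$query_id, b$query_id), ]
  sa <- a[[metric]]
  sb <- b[[metric]]
  d <- sa - sb
  list(table = data.frame(query_id = a$query_id, score_a = sa, score_b = sb,
                          stringsAsFactors = FALSE),
       wins = sum(d > tol), ties = sum(abs(d) <= tol), losses = sum(d < -tol))
}
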