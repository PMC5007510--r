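# Independent oracles and fixture builders shared by the test files.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n) paste0(sample(AA, n, replace = TRUE),
                                    collapse = "")

# Brute-force truncated step-curve ROC_n: walks the ranking entry by
# entry, accumulating the rectangle under the TP-vs-FP step curve at each
# false positive. Independent control flow from the package's
# cumsum-based implementation.
oracle_roc_n <- function(is_pos, p_total, n_neg_total, n) {
  if (p_total == 0) stop("no positives")
  if (n_neg_total == 0) return(sum(is_pos) / p_total)
  m <- min(n, n_neg_total)
  area <- 0
  tp <- 0
  fp <- 0
  for (lab in is_pos) {
    if (lab) {
      tp <- tp + 1
    } else {
      fp <- fp + 1
      area <- area + tp
      if (fp >= m) break
    }
  }
  if (fp < m) area <- area + (m - fp) * sum(is_pos)
  area / (m * p_total)
}

# roc_n() on a plain ordered label pattern (all labelled targets present
# in the ranking, rank order = target order given).
roc_of_pattern <- function(is_pos, n) {
  ids <- sprintf("t%03d", seq_along(is_pos))
  labs <- setNames(ifelse(is_pos, "positive", "negative"), ids)
  rl <- ranking_list("q", "p", ids, rev(seq_along(ids)))
  roc_n(rl, labs, n)
}

# Minimal PSI-BLAST -out_ascii_pssm writer. `percs` is a 20 x L integer
# matrix in PSI-BLAST residue order; each column should sum to 100 (or 0
# for a deliberately broken column).
PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

write_fake_pssm <- function(path, residues, percs) {
  stopifnot(nrow(percs) == 20, ncol(percs) == length(residues))
  hdr <- paste0("            ",
                paste(sprintf("%3s", c(PSSM_ORDER, PSSM_ORDER)),
                      collapse = " "))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    hdr)
  for (j in seq_along(residues)) {
    logodds <- paste(sprintf("%3d", rep(0L, 20)), collapse = " ")
    pc <- paste(sprintf("%3d", percs[, j]), collapse = " ")
    lines <- c(lines, sprintf("%5d %s  %s  %s  %.2f %.2f",
                              j, residues[j], logodds, pc, 0.5, 1.0))
  }
  lines <- c(lines, "", "                      K         Lambda")
  writeLines(lines, path)
  path
}

# Fixed-width .hhr report writer (query line + hit summary table).
write_fake_hhr <- function(path, query_id, hits, scores, probs = NULL) {
  if (is.null(probs)) probs <- rep(99.9, length(hits))
  lines <- c(paste0("Query         ", query_id),
             "Match_columns 60",
             "No_of_seqs    10 out of 50",
             "",
             sprintf(" %-3s %-30s %5s %7s %7s %7s %4s %4s  %s",
                     "No", "Hit", "Prob", "E-value", "P-value", "Score",
                     "SS", "Cols", "Query HMM"))
  for (i in seq_along(hits)) {
    lines <- c(lines,
               sprintf(" %3d %-30s %5.1f %7.1e %7.1e %7.1f %4.1f %4d  %s",
                       i, hits[i], probs[i], 1e-10, 1e-12, scores[i],
                       0, 60, "1-60"))
  }
  lines <- c(lines, "", "alignments follow...")
  writeLines(lines, path)
  path
}

# Small deterministic benchmark: 3 superfamilies of sizes 3 / 2 / 1.
toy_benchmark <- function() {
  benchmark_dataset(data.frame(
    seq_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    family_id = c("fA", "fA", "fA2", "fB", "fB", "fC"),
    superfamily_id = c("SFA", "SFA", "SFA", "SFB", "SFB", "SFC"),
    stringsAsFactors = FALSE))
}
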