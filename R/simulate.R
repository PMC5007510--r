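# Seeded generators: benchmark hierarchies, MSAs and predictor score
# lists with known ground truth. Deliberately minimal sequence model (no
# substitution matrices, indels or rate heterogeneity): just enough
# structure to exercise profiles, aggregation and evaluation offline.

#' Simulation configuration
#'
#' Defaults are the desk-scale testing world used throughout the test
#' suite: 10 superfamilies x 2 families x 4 sequences of length 60, a
#' strong/medium/uninformative predictor trio (signals 3.0 / 1.5 / 0.0)
#' and unit Gaussian score noise.
#'
#' @param n_superfamilies,families_per_superfamily,seqs_per_family Counts
#'   (all >= 1).
#' @param seq_length Sequence length in residues.
#' @param within_family_mut_rate Per-site substitution probability from
#'   family ancestor to member (default 0.2).
#' @param within_superfamily_mut_rate Per-site substitution probability
#'   from superfamily ancestor to family ancestor (default 0.7; must be
#'   >= the within-family rate — families are tighter than superfamilies).
#' @param background Expected identity between unrelated sequences under
#'   the uniform residue model (1/20); a reference constant, not a dial.
#' @param predictor_signals Named vector a_j >= 0: mean score offset a
#'   predictor adds to true same-superfamily pairs.
#' @param noise_sd Standard deviation of the Gaussian score noise (> 0).
#' @param seed Integer seed; all generators are fully deterministic in it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_superfamilies = 10L,
                       families_per_superfamily = 2L,
                       seqs_per_family = 4L,
                       seq_length = 60L,
                       within_family_mut_rate = 0.2,
                       within_superfamily_mut_rate = 0.7,
                       background = 0.05,
                       predictor_signals = c(strong = 3.0, medium = 1.5,
                                             uninformative = 0.0),
                       noise_sd = 1.0,
                       seed = 1L) {
  if (n_superfamilies < 1 || families_per_superfamily < 1 ||
      seqs_per_family < 1 || seq_length < 1) {
    stop("all counts must be >= 1")
  }
  rates <- c(within_family_mut_rate, within_superfamily_mut_rate, background)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (within_family_mut_rate > within_superfamily_mut_rate) {
    stop("within_family_mut_rate must be <= within_superfamily_mut_rate")
  }
  if (any(predictor_signals < 0)) stop("predictor signals must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(list(n_superfamilies = as.integer(n_superfamilies),
                 families_per_superfamily = as.integer(families_per_superfamily),
                 seqs_per_family = as.integer(seqs_per_family),
                 seq_length = as.integer(seq_length),
                 within_family_mut_rate = within_family_mut_rate,
                 within_superfamily_mut_rate = within_superfamily_mut_rate,
                 background = background,
                 predictor_signals = predictor_signals,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Redraw each selected site uniformly over the full alphabet, so rate 1
# yields a uniformly random offspring (expected identity to the parent =
# 1/20, the background level) and rate 0 an identical copy.
mutate_chars <- function(chars, rate) {
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  }
  chars
}

#' Simulate a family/superfamily benchmark with sequences
#'
#' Superfamily ancestors are drawn uniformly over the 20 residues; family
#' ancestors are the superfamily ancestor substituted per site with
#' probability `within_superfamily_mut_rate`; members are the family
#' ancestor substituted at `within_family_mut_rate`. Fully deterministic
#' in `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `benchmark` (a [benchmark_dataset] carrying the
#'   sequences) and `sequences` (named character vector).
#' @export
simulate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    ids <- character(0)
    fams <- character(0)
    sfs <- character(0)
    seqs <- character(0)
    for (s in seq_len(cfg$n_superfamilies)) {
      sf_anc <- sample(AA20, cfg$seq_length, replace = TRUE)
      sf_id <- sprintf("SF%03d", s)
      for (f in seq_len(cfg$families_per_superfamily)) {
        fam_anc <- mutate_chars(sf_anc, cfg$within_superfamily_mut_rate)
        fam_id <- sprintf("%s.F%02d", sf_id, f)
        for (m in seq_len(cfg$seqs_per_family)) {
          member <- mutate_chars(fam_anc, cfg$within_family_mut_rate)
          ids <- c(ids, sprintf("%s.S%02d", fam_id, m))
          fams <- c(fams, fam_id)
          sfs <- c(sfs, sf_id)
          seqs <- c(seqs, paste0(member, collapse = ""))
        }
      }
    }
    names(seqs) <- ids
    bench <- benchmark_dataset(
      data.frame(seq_id = ids, family_id = fams, superfamily_id = sfs,
                 stringsAsFactors = FALSE),
      sequences = seqs)
    list(benchmark = bench, sequences = seqs)
  })
}

#' Simulate a multiple sequence alignment around one member sequence
#'
#' Row i keeps the member residue at column c with probability
#' `conservation[c]`; otherwise the residue is replaced by one of the 19
#' other amino acids, uniformly. The master (first) row is the unmutated
#' member. Gap-free by construction.
#'
#' @param member_sequence Residue string (the query).
#' @param n_rows Number of homolog rows to simulate (master row excluded).
#' @param conservation Numeric vector in `[0, 1]`, one value per column.
#' @param seed Integer seed.
#' @param query_id Id of the master row (default `"query"`).
#' @return An [msa] with `n_rows + 1` rows, master first.
#' @export
simulate_msa <- function(member_sequence, n_rows, conservation, seed,
                         query_id = "query") {
  chars <- strsplit(member_sequence, "")[[1]]
  if (length(conservation) != length(chars)) {
    stop("conservation length must equal sequence length")
  }
  if (any(conservation < 0) || any(conservation > 1)) {
    stop("conservation values must lie in [0, 1]")
  }
  with_seed(seed, {
    rows <- character(n_rows)
    for (i in seq_len(n_rows)) {
      keep <- runif(length(chars)) < conservation
      row <- chars
      if (any(!keep)) {
        row[!keep] <- vapply(chars[!keep], function(a) {
          sample(setdiff(AA20, a), 1L)
        }, character(1))
      }
      rows[i] <- paste0(row, collapse = "")
    }
    all_rows <- c(member_sequence, rows)
    names(all_rows) <- c(query_id, sprintf("hom%03d", seq_len(n_rows)))
    msa(all_rows, master = 1L, query_id = query_id)
  })
}

#' Simulate per-predictor ranking lists over a benchmark
#'
#' For every query-target pair (target != query), predictor j scores
#' `a_j * 1[same superfamily] + Normal(0, noise_sd)`, independently
#' across predictors and pairs; per-query lists are sorted descending.
#' This realizes the complementary-predictor premise: predictors with
#' equal signal still err on different pairs because their noise is
#' independent.
#'
#' @param benchmark A [benchmark_dataset].
#' @param predictor_signals Named vector of signal strengths a_j >= 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Named list (by predictor) of named lists (by query) of
#'   [ranking_list] objects — the layout [grid_search_weights()] expects.
#' @export
simulate_scores <- function(benchmark, predictor_signals, noise_sd, seed) {
  stopifnot(inherits(benchmark, "benchmark_dataset"))
  r <- benchmark$records
  with_seed(seed, {
    out <- lapply(seq_along(predictor_signals), function(j) {
      a <- predictor_signals[[j]]
      pid <- names(predictor_signals)[j]
      per_query <- lapply(seq_len(nrow(r)), function(qi) {
        targets <- r$seq_id[-qi]
        same_sf <- r$superfamily_id[-qi] == r$superfamily_id[qi]
        scores <- a * as.numeric(same_sf) + rnorm(length(targets), 0, noise_sd)
        ranking_list(r$seq_id[qi], pid, targets, scores)
      })
      setNames(per_query, r$seq_id)
    })
    setNames(out, names(predictor_signals))
  })
}

#' Write a complete simulated fixture set to a directory
#'
#' Emits the benchmark FASTA, the label TSV and one generic ranking TSV
#' per predictor, plus a JSON echo of the resolved configuration.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_to_dir <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_benchmark(cfg)
  scores <- simulate_scores(sim$benchmark, cfg$predictor_signals,
                            cfg$noise_sd, cfg$seed + 1L)
  fasta <- file.path(outdir, "benchmark.fasta")
  set <- Biostrings::AAStringSet(sim$sequences)
  Biostrings::writeXStringSet(set, fasta)
  labels <- file.path(outdir, "labels.tsv")
  write_benchmark_tsv(sim$benchmark, labels)
  score_paths <- vapply(names(scores), function(pid) {
    p <- file.path(outdir, paste0("scores_", pid, ".tsv"))
    write_ranking_tsv(unname(scores[[pid]]), p)
    p
  }, character(1))
  cfg_path <- file.path(outdir, "sim_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fasta = fasta, labels = labels, scores = score_paths,
                 config = cfg_path))
}
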