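# Parsers for native homology-search output formats -> ranking_list.
# All adapters emit one finite, higher-is-better score per target
# (duplicate hits collapse to the max).

# E-value -> higher-is-better score; E = 0 (or below 1e-300) clamps to
# the finite ceiling -log10(1e-300) = 300.
neg_log_evalue <- function(e) {
  -log10(pmax(as.numeric(e), 1e-300))
}

#' Parse BLAST tabular output (-outfmt 6)
#'
#' Standard 12-column tabular output. Target = column 2 (subject id);
#' score = column 12 (bit score). Multiple HSPs against one target keep
#' the maximum bit score. Rows whose query id differs from the first row's
#' raise an error (one query per file).
#'
#' @param path Path to the tabular file.
#' @param predictor_id Predictor id stamp (default `"psiblast"`).
#' @return A [ranking_list].
#' @export
parse_blast_tabular <- function(path, predictor_id = "psiblast") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(ranking_list(sub("\\.[^.]*$", "", basename(path)), predictor_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) {
    stop("expected 12 tab-separated columns at line ", bad[1L])
  }
  qid <- vapply(parts, `[`, character(1), 1L)
  if (length(unique(qid)) > 1L) stop("multiple query ids in BLAST tabular file")
  target <- vapply(parts, `[`, character(1), 2L)
  bits <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 12L)))
  if (anyNA(bits)) {
    stop("non-numeric bit score at line ", which(is.na(bits))[1L])
  }
  best <- tapply(bits, target, max)
  ranking_list(qid[1L], predictor_id, names(best), as.numeric(best))
}

#' Parse HMMER3 per-target table output (--tblout)
#'
#' `#`-comment lines are skipped. Target = field 1; score = field 6 (full
#' sequence bit score); duplicates keep the max. The query id is taken
#' from field 3 of the first hit.
#'
#' @param path Path to the tblout file.
#' @param predictor_id Predictor id stamp (default `"hmmer"`).
#' @return A [ranking_list].
#' @export
parse_hmmer_tblout <- function(path, predictor_id = "hmmer") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(ranking_list(sub("\\.[^.]*$", "", basename(path)), predictor_id))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 6L)
  if (length(bad)) stop("malformed tblout line ", bad[1L])
  target <- vapply(parts, `[`, character(1), 1L)
  qid <- vapply(parts, `[`, character(1), 3L)
  if (length(unique(qid)) > 1L) stop("multiple query ids in tblout file")
  score <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 6L)))
  if (anyNA(score)) {
    stop("non-numeric full-sequence score at line ", which(is.na(score))[1L])
  }
  best <- tapply(score, target, max)
  ranking_list(qid[1L], predictor_id, names(best), as.numeric(best))
}

#' Parse an HHblits/HHsearch .hhr report
#'
#' Extracts the hit summary table (between the ` No Hit ...` header and
#' the first blank line). Target = the hit identifier (first token of the
#' Hit column); score = the `Score` column (higher is better); duplicates
#' keep the max. A report whose summary table holds no hits yields an
#' empty [ranking_list].
#'
#' @param path Path to the `.hhr` file.
#' @param predictor_id Predictor id stamp (default `"hhblits"`).
#' @return A [ranking_list].
#' @export
parse_hhr <- function(path, predictor_id = "hhblits") {
  lines <- readLines(path, warn = FALSE)
  qid <- sub("\\.[^.]*$", "", basename(path))
  qline <- grep("^Query\\s+", lines, value = TRUE)
  if (length(qline)) {
    qid <- strsplit(trimws(sub("^Query\\s+", "", qline[1L])), "\\s+")[[1]][1L]
  }
  hdr <- grep("^\\s*No\\s+Hit\\s+", lines)
  if (!length(hdr)) stop("missing summary table")
  # fixed-width columns: Score starts where the header says
  score_start <- regexpr("Score", lines[hdr[1L]])[1L]
  i <- hdr[1L] + 1L
  targets <- character(0)
  scores <- numeric(0)
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    ln <- lines[i]
    hit_field <- trimws(substr(ln, 1L, score_start - 1L))
    toks <- strsplit(hit_field, "\\s+")[[1]]
    if (length(toks) < 2L) stop("malformed summary-table line ", i)
    tail_field <- trimws(substring(ln, score_start))
    score <- suppressWarnings(as.numeric(strsplit(tail_field, "\\s+")[[1]][1L]))
    if (is.na(score)) stop("non-numeric Score at line ", i)
    targets <- c(targets, toks[2L])  # toks[1] is the hit rank number
    scores <- c(scores, score)
    i <- i + 1L
  }
  if (!length(targets)) {
    return(ranking_list(qid, predictor_id))
  }
  best <- tapply(scores, targets, max)
  ranking_list(qid, predictor_id, names(best), as.numeric(best))
}

#' Describe an external predictor invocation
#'
#' Records, per predictor, which output field supplies the ranking score
#' and the documented invocation parameters. Profile generation upstream
#' of the pseudo-sequence path uses PSI-BLAST with 10 iterations at
#' E = 0.001; search-time invocations use PSI-BLAST with 3 iterations,
#' HHblits with 2 iterations, and HMMER/COMA defaults. Nothing is
#' executed unless [run_predictor()] is called explicitly.
#'
#' @param predictor_id One of `"psiblast"`, `"hhblits"`, `"hmmer"`,
#'   `"coma"`, `"generic"`.
#' @return An object of class `adapter_spec` with `predictor_id`,
#'   `binary`, `score_field`, `invocation_params`.
#' @export
adapter_spec <- function(predictor_id = c("psiblast", "hhblits", "hmmer",
                                          "coma", "generic")) {
  predictor_id <- match.arg(predictor_id)
  info <- switch(predictor_id,
    psiblast = list(binary = "psiblast", score_field = "bit_score",
                    invocation_params =
                      "-num_iterations 3 -outfmt 6 (v2.2.30; profile generation: -num_iterations 10 -evalue 0.001)"),
    hhblits = list(binary = "hhblits", score_field = "raw_column",
                   invocation_params = "-n 2 (v2.0.16, otherwise defaults)"),
    hmmer = list(binary = "phmmer", score_field = "bit_score",
                 invocation_params = "--tblout <out> (v3.1b2 defaults)"),
    coma = list(binary = "coma", score_field = "raw_column",
                invocation_params =
                  "v1.10 defaults; convert output to generic 3-column TSV"),
    generic = list(binary = NA_character_, score_field = "raw_column",
                   invocation_params = "none (pre-computed TSV)"))
  structure(c(list(predictor_id = predictor_id), info),
            class = "adapter_spec")
}

#' Run an external predictor and parse its output
#'
#' Shells out to a user-installed search binary with the documented
#' parameters and dispatches the captured output to the matching parser.
#' Optional plumbing: never invoked by the test suite; requires the
#' binary on `PATH`.
#'
#' @param spec An [adapter_spec()].
#' @param pseudo_fasta Path to the (pseudo-)sequence query FASTA.
#' @param database_path Path to the formatted target database.
#' @return A [ranking_list].
#' @export
run_predictor <- function(spec, pseudo_fasta, database_path) {
  stopifnot(inherits(spec, "adapter_spec"))
  if (spec$predictor_id == "generic") {
    stop("generic adapter has no binary; parse the TSV directly")
  }
  if (!nzchar(Sys.which(spec$binary))) {
    stop("predictor not installed: '", spec$binary,
         "' not found on PATH (install ", spec$predictor_id,
         " or supply its output via the matching parser)")
  }
  out <- tempfile(fileext = ".out")
  args <- switch(spec$predictor_id,
    psiblast = c("-query", pseudo_fasta, "-db", database_path,
                 "-num_iterations", "3", "-outfmt", "6", "-out", out),
    hhblits = c("-i", pseudo_fasta, "-d", database_path, "-n", "2",
                "-o", out),
    hmmer = c("--tblout", out, pseudo_fasta, database_path),
    coma = stop("coma output is not parsed natively; convert to generic TSV"))
  status <- suppressWarnings(
    system2(spec$binary, args, stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("predictor '", spec$binary, "' exited with status ", code, ":\n",
         paste(status, collapse = "\n"))
  }
  switch(spec$predictor_id,
         psiblast = parse_blast_tabular(out, spec$predictor_id),
         hhblits = parse_hhr(out, spec$predictor_id),
         hmmer = parse_hmmer_tblout(out, spec$predictor_id))
}
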