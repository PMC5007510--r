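# Frequency profiles and profile-based pseudo protein sequences.

#' Construct a multiple sequence alignment object
#'
#' A thin container for an aligned set of sequences with one designated
#' master (query) row. All rows must have equal aligned length; gaps are
#' `-` (or `.`, normalized to `-`).
#'
#' @param rows Named character vector of aligned sequences (names = seq ids).
#' @param master Id or index of the master/query row. Default: first row.
#' @param query_id Id for the query; defaults to the master row's name.
#' @return An object of class `msa` with elements `query_id`, `rows`
#'   (named character vector) and `master_index`.
#' @export
msa <- function(rows, master = 1L, query_id = NULL) {
  if (length(rows) == 0) stop("empty alignment")
  rows <- vapply(rows, function(x) chartr(".", "-", toupper(x)), character(1))
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == "")) {
    names(rows) <- paste0("seq", seq_along(rows))
  }
  if (length(unique(nchar(rows))) != 1L) stop("ragged alignment")
  if (is.character(master)) {
    master_index <- match(master, names(rows))
    if (is.na(master_index)) {
      stop("master row '", master, "' not found in alignment")
    }
  } else {
    master_index <- as.integer(master)
    if (master_index < 1L || master_index > length(rows)) {
      stop("master row index out of range")
    }
  }
  if (is.null(query_id)) query_id <- names(rows)[master_index]
  structure(list(query_id = query_id, rows = rows,
                 master_index = master_index),
            class = "msa")
}

#' Read an aligned FASTA file into an `msa`
#'
#' The master (query) row defaults to the first record; override with
#' `master` (a record id).
#'
#' @param path Path to an aligned FASTA file (`-` gaps).
#' @param master Optional id of the master row.
#' @return An [msa] object.
#' @export
read_msa_fasta <- function(path, master = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment")
  rows <- as.character(set)
  # FASTA headers may carry descriptions; the id is the first token
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  msa(rows, master = if (is.null(master)) 1L else master)
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$rows), " rows x ",
      nchar(x$rows[[1]]), " columns; master = ",
      names(x$rows)[x$master_index], "\n", sep = "")
  invisible(x)
}

#' Construct a frequency profile
#'
#' A 20 x L matrix of per-position amino-acid frequencies for one query,
#' with L the ungapped query length. Rows are the canonical alphabet in
#' alphabetical order; each counted column sums to 1.
#'
#' @param query_id Query identifier.
#' @param freqs 20 x L numeric matrix, rownames the canonical alphabet.
#' @param query_residues Length-L character vector: the master residue at
#'   each kept column.
#' @return An object of class `frequency_profile`.
#' @export
frequency_profile <- function(query_id, freqs, query_residues) {
  if (!is.matrix(freqs) || nrow(freqs) != 20L) {
    stop("frequency matrix must be 20 x L")
  }
  if (is.null(rownames(freqs))) rownames(freqs) <- AA20
  if (!identical(rownames(freqs), AA20)) freqs <- freqs[AA20, , drop = FALSE]
  if (length(query_residues) != ncol(freqs)) {
    stop("query_residues length must equal profile length")
  }
  if (any(freqs < -1e-12) || any(freqs > 1 + 1e-12)) {
    stop("frequencies must lie in [0, 1]")
  }
  sums <- colSums(freqs)
  counted <- sums > 0
  if (any(abs(sums[counted] - 1) > 1e-9)) {
    stop("counted profile columns must sum to 1")
  }
  structure(list(query_id = query_id, freqs = freqs,
                 query_residues = query_residues),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("Frequency profile for '", x$query_id, "': 20 x ", ncol(x$freqs),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.frequency_profile <- function(x) ncol(x$freqs)

#' Build a frequency profile from a multiple sequence alignment
#'
#' One profile column is emitted per non-gap master position, in master
#' order. Column frequencies are the count of each canonical residue in
#' that alignment column divided by the number of non-gap canonical
#' residues there; gaps and ambiguity codes (B, Z, X, U, O, J, `*`) are
#' excluded from the denominator. A column where no row holds a canonical
#' residue is emitted as all zeros (possible only when the master residue
#' itself is non-canonical).
#'
#' @param aln An [msa] object.
#' @return A [frequency_profile].
#' @export
#' @examples
#' a <- msa(c(q = "ACD", h1 = "ACD", h2 = "ACD"))
#' p <- msa_to_frequency_profile(a)
#' profile_to_pseudo_sequence(p)$residues  # "ACD"
msa_to_frequency_profile <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  chars <- do.call(rbind, strsplit(aln$rows, ""))
  master <- chars[aln$master_index, ]
  keep <- which(master != "-")
  if (length(keep) == 0) {
    stop("master row contains no non-gap characters")
  }
  L <- length(keep)
  freqs <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- chars[, keep[j]]
    col <- col[col %in% AA20]
    if (length(col)) {
      counts <- tabulate(factor(col, levels = AA20), nbins = 20L)
      freqs[, j] <- counts / length(col)
    }
  }
  frequency_profile(aln$query_id, freqs, master[keep])
}

#' Derive the pseudo protein sequence from a frequency profile
#'
#' Residue i is the amino acid with maximal frequency in column i. Ties:
#' if the master residue at that column is among the tied maxima it is
#' chosen, otherwise the alphabetically first tied residue. An all-zero
#' column (possible in malformed PSSMs) falls back to the master residue
#' so a residue is always emitted.
#'
#' @param profile A [frequency_profile].
#' @param source Provenance tag stored on the result, `"msa"` or `"pssm"`.
#' @return An object of class `pseudo_sequence` with elements `query_id`,
#'   `residues` (single string) and `source`.
#' @export
profile_to_pseudo_sequence <- function(profile, source = c("msa", "pssm")) {
  stopifnot(inherits(profile, "frequency_profile"))
  source <- match.arg(source)
  f <- profile$freqs
  out <- character(ncol(f))
  for (j in seq_len(ncol(f))) {
    col <- f[, j]
    mx <- max(col)
    if (mx <= 0) {
      m <- profile$query_residues[j]
      out[j] <- if (m %in% AA20) m else AA20[1L]
      next
    }
    tied <- AA20[col == mx]
    m <- profile$query_residues[j]
    out[j] <- if (m %in% tied) m else tied[1L]
  }
  structure(list(query_id = profile$query_id,
                 residues = paste0(out, collapse = ""),
                 source = source),
            class = "pseudo_sequence")
}

#' @export
print.pseudo_sequence <- function(x, ...) {
  cat(">", x$query_id, " pseudo=1 [", x$source, "]\n",
      x$residues, "\n", sep = "")
  invisible(x)
}

# PSI-BLAST prints the two 20-column blocks in this residue order.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse a PSI-BLAST ASCII PSSM into a frequency profile
#'
#' Reads the output of `psiblast -out_ascii_pssm`. The second 20-column
#' block (weighted observed percentages) is taken, divided by 100, and
#' renormalized per column to sum to 1 (PSI-BLAST prints integer
#' percentages whose sum drifts from 100 by rounding). All-zero columns
#' are kept as zeros and recorded in the `zero_columns` attribute; the
#' pseudo-sequence step then falls back to the master residue there.
#'
#' @param path Path to the ASCII PSSM file.
#' @param query_id Query id; defaults to the file name without extension.
#' @return A [frequency_profile] with attribute `zero_columns` (integer
#'   vector of flagged positions, possibly empty).
#' @export
parse_ascii_pssm <- function(path, query_id = NULL) {
  if (is.null(query_id)) {
    query_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  header_idx <- NA_integer_
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) == 40L && all(toks %in% AA20)) {
      header_idx <- i
      break
    }
  }
  if (is.na(header_idx)) stop("no frequency block")
  row_re <- "^\\s*[0-9]+\\s+[A-Za-z]"
  residues <- character(0)
  freq_cols <- list()
  for (i in seq((header_idx + 1L), length(lines))) {
    ln <- lines[i]
    if (!grepl(row_re, ln)) {
      if (length(residues)) break  # past the matrix body
      next
    }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(toks) < 42L) {
      stop("malformed PSSM row at line ", i)
    }
    pct <- suppressWarnings(as.numeric(toks[23:42]))
    if (anyNA(pct)) stop("malformed PSSM row at line ", i)
    residues <- c(residues, toupper(toks[2L]))
    freq_cols[[length(freq_cols) + 1L]] <- pct / 100
  }
  if (!length(freq_cols)) stop("no frequency block")
  freqs <- matrix(unlist(freq_cols), nrow = 20L,
                  dimnames = list(PSSM_AA_ORDER, NULL))
  freqs <- freqs[AA20, , drop = FALSE]
  sums <- colSums(freqs)
  zero_columns <- which(sums == 0)
  pos <- sums > 0
  freqs[, pos] <- sweep(freqs[, pos, drop = FALSE], 2, sums[pos], "/")
  out <- frequency_profile(query_id, freqs, residues)
  attr(out, "zero_columns") <- zero_columns
  out
}

#' Write pseudo sequences to FASTA
#'
#' Headers are the query id with a ` pseudo=1` suffix.
#'
#' @param pseudo A `pseudo_sequence` or list of them.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pseudo_fasta <- function(pseudo, path) {
  if (inherits(pseudo, "pseudo_sequence")) pseudo <- list(pseudo)
  seqs <- vapply(pseudo, `[[`, character(1), "residues")
  ids <- vapply(pseudo, `[[`, character(1), "query_id")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- paste0(ids, " pseudo=1")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
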