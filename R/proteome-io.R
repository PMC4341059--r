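#' Read a proteome from a FASTA file
#'
#' Parses a (possibly multi-line) amino-acid FASTA file into a proteome table.
#' UniProt-style headers (`>sp|ACC|NAME description`) yield the accession as
#' `protein_id`; any other header yields its first whitespace-delimited token.
#' `*` stop characters are stripped. Nonstandard residue codes
#' (U, O, B, Z, J and pre-existing X) are replaced by `"X"` with a warning;
#' downstream, `X` positions are unlabelable, non-cleavable and never anchors,
#' so every simulation rule stays well defined.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`, one row per
#'   FASTA record (zero rows for an empty file).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P69905|HBA_HUMAN desc", "MVLS"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(tibble(protein_id = character(), sequence = character()))
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    abort(sprintf("Malformed FASTA: sequence data before first header at line %d.", first))
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- vapply(headers, fasta_header_id, character(1), USE.NAMES = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate protein identifiers in FASTA: %s",
                  paste(dup, collapse = ", ")))
  }
  sequences <- sanitize_sequences(toupper(gsub("*", "", as.character(seqs), fixed = TRUE)))
  tibble(protein_id = ids, sequence = unname(sequences))
}

fasta_header_id <- function(header) {
  token <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  m <- regmatches(token, regexec("^(?:sp|tr)\\|([^|]+)\\|", token))[[1]]
  if (length(m) == 2L) m[2] else token
}

# Replace nonstandard residue codes with "X", warning with per-code counts.
sanitize_sequences <- function(sequences) {
  bad_pat <- sprintf("[^%s]", paste(AA20, collapse = ""))
  hits <- gregexpr(bad_pat, sequences)
  bad_chars <- unlist(regmatches(sequences, hits))
  if (length(bad_chars) > 0L) {
    tab <- table(bad_chars)
    warn(sprintf(
      "Replaced %d nonstandard residue(s) with 'X': %s",
      length(bad_chars),
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")
    ))
    sequences <- gsub(bad_pat, "X", sequences)
  }
  empty <- !nzchar(sequences)
  if (any(empty)) abort("FASTA contains records with empty sequences.")
  sequences
}

#' Write a proteome to FASTA
#'
#' Emits 60-column wrapped FASTA, one record per row of `proteome`.
#'
#' @param proteome A proteome table (`protein_id`, `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  check_proteome(proteome)
  set <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, proteome$protein_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Uniform amino-acid composition
#'
#' @return A named numeric vector of frequencies over the 20 standard
#'   residues, each 1/20.
#' @export
composition_uniform <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

#' Human-like amino-acid composition
#'
#' Average residue frequencies of reviewed human/vertebrate protein sequences
#' (UniProtKB release statistics, renormalized over the 20 standard codes).
#' Useful when a synthetic proteome should mimic the residue usage of a real
#' proteome, e.g. the relative scarcity of Cys, Trp and Met that drives
#' anchor and cleavage-site density.
#'
#' @return A named numeric vector of frequencies summing to 1.
#' @export
composition_human <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.65, T = 5.35, W = 1.10,
         Y = 2.92, V = 6.86)
  f <- f / sum(f)
  f[AA20]
}

#' Log-normal protein length sampler
#'
#' Returns a sampler function drawing integer protein lengths from a
#' log-normal distribution (floored, minimum 1). The defaults give a median
#' length of about 375 residues with a long right tail, a reasonable stand-in
#' for eukaryotic protein length distributions.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @param min_length Minimum length after flooring.
#' @return A function of `n` returning `n` integer lengths.
#' @export
length_sampler_lognormal <- function(meanlog = log(375), sdlog = 0.6, min_length = 50L) {
  function(n) pmax(as.integer(floor(rlnorm(n, meanlog, sdlog))), as.integer(min_length))
}

#' Generate a synthetic proteome
#'
#' Draws protein sequences i.i.d. from a residue composition, with lengths
#' from a sampler (or a fixed length), so the whole pipeline is testable
#' without downloading a reference proteome. Deterministic for a fixed seed.
#'
#' @param n_proteins Number of proteins (>= 0).
#' @param length_sampler Either a single number (all proteins that length) or
#'   a function of `n` returning `n` lengths >= 1. Default:
#'   [length_sampler_lognormal()].
#' @param composition Named residue-frequency vector over the 20 standard
#'   codes, summing to 1 within 1e-9. Default: [composition_uniform()].
#' @param seed Integer seed; the same seed always yields the same proteome.
#' @return A proteome tibble with ids `"SYN000001"`, ...
#' @export
#' @examples
#' generate_synthetic_proteome(3, length_sampler = 8, seed = 1)
generate_synthetic_proteome <- function(n_proteins,
                                        length_sampler = length_sampler_lognormal(),
                                        composition = composition_uniform(),
                                        seed = 1L) {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 0 ||
      n_proteins != floor(n_proteins)) {
    abort("`n_proteins` must be a single non-negative integer.")
  }
  if (n_proteins == 0L) {
    return(tibble(protein_id = character(), sequence = character()))
  }
  if (is.null(names(composition)) || !all(names(composition) %in% AA20) ||
      anyDuplicated(names(composition)) || any(composition < 0)) {
    abort("`composition` must be a named non-negative vector over the 20 standard residue codes.")
  }
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("`composition` frequencies must sum to 1 (tolerance 1e-9).")
  }
  withr::with_seed(as.integer(seed), {
    lengths <- if (is.function(length_sampler)) {
      length_sampler(n_proteins)
    } else {
      rep(as.integer(length_sampler), n_proteins)
    }
    if (length(lengths) != n_proteins || any(lengths < 1)) {
      abort("`length_sampler` must yield one length >= 1 per protein.")
    }
    total <- sum(lengths)
    residues <- sample(names(composition), total, replace = TRUE, prob = composition)
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1
    big <- paste(residues, collapse = "")
    tibble(
      protein_id = sprintf("SYN%06d", seq_len(n_proteins)),
      sequence = substring(big, starts, ends)
    )
  })
}

#' Toy peptide fixtures
#'
#' Small peptides used throughout the documentation and tests: `X` (`GKEGC`)
#' and `Y` (`GKGKEC`) from the two-peptide trie example, `swap_demo`
#' (`GKEGK`) used to illustrate dye-failure and photobleaching artifacts, and
#' `wkkxy` (`WKKAY`), a 5-mer whose ideal read is the pattern `WKKxY` when
#' Trp, Lys and Tyr carry distinguishable labels.
#'
#' @return A tibble with columns `name` and `sequence`.
#' @export
toy_fixtures <- function() {
  tibble(
    name = c("X", "Y", "swap_demo", "wkkxy"),
    sequence = c("GKEGC", "GKGKEC", "GKEGK", "WKKAY")
  )
}
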