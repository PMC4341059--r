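#' Protease cleavage rules
#'
#' A protease rule cuts C-terminal to every occurrence of its target
#' residues; digestion is complete (no missed cleavages) and the cleaved
#' residue stays at the peptide's C-terminus. Presets:
#' \describe{
#'   \item{`"gluc"`}{GluC, cleaves after Glu (`E`) only.}
#'   \item{`"cnbr"`}{cyanogen bromide, cleaves after Met (`M`); the simulated
#'     fragment keeps `M` as its C-terminal residue even though the real
#'     chemistry converts it to homoserine lactone -- only the cleavage
#'     position matters here.}
#'   \item{`"trypsin"`}{cleaves after Lys or Arg (`K`, `R`), no proline
#'     exception.}
#'   \item{`"none"`}{no proteolysis; each protein is one peptide.}
#' }
#'
#' @param name Preset name, or any label when `cleave_after` is supplied.
#' @param cleave_after Optional character vector of residue codes for a
#'   custom rule (must be non-empty standard codes).
#' @return A `protease_rule` object.
#' @export
#' @examples
#' protease("trypsin")
#' protease("gluc+aspn", cleave_after = c("E", "D"))
protease <- function(name, cleave_after = NULL) {
  if (inherits(name, "protease_rule")) return(name)
  if (is.null(cleave_after)) {
    presets <- list(
      gluc = "E",
      cnbr = "M",
      trypsin = c("K", "R"),
      none = character(0)
    )
    key <- tolower(name)
    if (!key %in% names(presets)) {
      abort(sprintf("Unknown protease preset '%s' (have: %s).",
                    name, paste(names(presets), collapse = ", ")))
    }
    cleave_after <- presets[[key]]
    name <- key
  } else {
    if (length(cleave_after) == 0L || !all(cleave_after %in% AA20)) {
      abort("`cleave_after` must be a non-empty set of standard residue codes.")
    }
    cleave_after <- unique(cleave_after)
  }
  structure(list(name = name, cleave_after = cleave_after),
            class = "protease_rule")
}

#' @export
print.protease_rule <- function(x, ...) {
  targets <- if (length(x$cleave_after)) paste(x$cleave_after, collapse = ", ") else "(none)"
  cat(sprintf("<protease_rule> %s: cleave C-terminal to {%s}\n", x$name, targets))
  invisible(x)
}

#' Digest proteins into peptides
#'
#' Splits every protein C-terminal to each occurrence of the rule's target
#' residues (complete digestion). Concatenating a protein's peptides in
#' `pep_index` order reconstructs its sequence.
#'
#' @param proteome A proteome table (`protein_id`, `sequence`).
#' @param rule A [protease()] rule or preset name.
#' @return A tibble of peptides: `protein_id`, `pep_index`, `peptide`.
#' @export
#' @examples
#' digest(tibble::tibble(protein_id = "P1", sequence = "GKEGKC"), "gluc")
digest <- function(proteome, rule) {
  check_proteome(proteome)
  rule <- protease(rule)
  if (nrow(proteome) == 0L) {
    return(tibble(protein_id = character(), pep_index = integer(), peptide = character()))
  }
  if (length(rule$cleave_after) == 0L) {
    frags <- as.list(proteome$sequence)
  } else {
    pat <- sprintf("(?<=[%s])", paste(rule$cleave_after, collapse = ""))
    frags <- strsplit(proteome$sequence, pat, perl = TRUE)
  }
  n_per <- lengths(frags)
  tibble(
    protein_id = rep(proteome$protein_id, n_per),
    pep_index = unlist(lapply(n_per, seq_len), use.names = FALSE),
    peptide = unlist(frags, use.names = FALSE)
  )
}

#' Retain peptides by surface anchor
#'
#' In `"cysteine"` mode only Cys-containing peptides are retained (thioether
#' surface attachment via the first Cys from the N-terminus); `anchor_index`
#' is the position of that first Cys. In `"c_terminus"` mode every peptide is
#' retained and `anchor_index` is the peptide length.
#'
#' @param peptides A peptide table from [digest()].
#' @param anchor `"cysteine"` or `"c_terminus"`.
#' @return The filtered peptide table with an `anchor_index` column added.
#' @export
filter_by_anchor <- function(peptides, anchor = c("cysteine", "c_terminus")) {
  check_peptides(peptides)
  anchor <- match.arg(anchor)
  if (anchor == "cysteine") {
    pos <- regexpr("C", peptides$peptide, fixed = TRUE)
    keep <- pos > 0L
    out <- peptides[keep, , drop = FALSE]
    out$anchor_index <- as.integer(pos[keep])
  } else {
    out <- peptides
    out$anchor_index <- nchar(out$peptide)
  }
  as_tibble(out)
}

# Count occurrences of a residue set in each peptide (vectorized).
count_residues <- function(sequences, residues) {
  stripped <- gsub(sprintf("[^%s]", paste(residues, collapse = "")), "", sequences)
  nchar(stripped)
}

new_stats <- function(values, what) {
  histogram <- count(tibble(value = as.integer(values)), .data$value, name = "n")
  structure(
    list(histogram = histogram, median = median_low(values),
         n_peptides = length(values), what = what),
    class = "fluorosim_stats"
  )
}

#' @export
print.fluorosim_stats <- function(x, ...) {
  cat(sprintf("<fluorosim_stats> %s over %d peptides; median (lower) = %d\n",
              x$what, x$n_peptides, x$median))
  print(x$histogram, n = 10)
  invisible(x)
}

#' Labelable-residue counts per peptide
#'
#' Counts, for each peptide, the residues belonging to a target (labelable)
#' set, and summarizes the counts as a frequency histogram and a lower
#' median. Peptides containing none of the targets contribute a count of 0.
#'
#' @param peptides A peptide table.
#' @param residues Character vector of residue codes, e.g. `c("D", "E")`.
#' @return A `fluorosim_stats` object: `$histogram` (tibble `value`, `n`),
#'   `$median`, `$n_peptides`.
#' @export
#' @examples
#' p <- tibble::tibble(protein_id = "P", pep_index = 1:2, peptide = c("GKC", "KKC"))
#' labelable_count_stats(p, "K")
labelable_count_stats <- function(peptides, residues) {
  check_peptides(peptides)
  if (nrow(peptides) == 0L) abort("`peptides` must be non-empty.")
  if (length(residues) == 0L || !all(residues %in% AA20)) {
    abort("`residues` must be standard residue codes.")
  }
  new_stats(count_residues(peptides$peptide, residues),
            sprintf("count of {%s}", paste(residues, collapse = ",")))
}

#' Peptide length distribution
#'
#' @param peptides A peptide table.
#' @return A `fluorosim_stats` object over peptide lengths (lower median).
#' @export
peptide_length_stats <- function(peptides) {
  check_peptides(peptides)
  if (nrow(peptides) == 0L) abort("`peptides` must be non-empty.")
  new_stats(nchar(peptides$peptide), "peptide length")
}

#' Write a statistics histogram as two-column TSV
#'
#' @param stats A `fluorosim_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  stopifnot(inherits(stats, "fluorosim_stats"))
  readr::write_tsv(stats$histogram, path)
  invisible(path)
}
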