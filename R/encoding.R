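#' Fluorescent labeling schemes
#'
#' A labeling scheme maps labelable residue types to fluorescent channel
#' identifiers. A residue maps to at most one channel; several residues may
#' share a channel when their labeling chemistries are indistinguishable
#' (Asp and Glu in the four-label preset). Presets:
#' \describe{
#'   \item{`"K"`}{Lys on channel `K`.}
#'   \item{`"K+Y"`}{Lys and Tyr on two distinguishable channels.}
#'   \item{`"K+Y+W"`}{Lys, Tyr, Trp on three channels.}
#'   \item{`"K+Y+W+DE"`}{four distinguishable labels; Asp and Glu share the
#'     fourth channel (rendered `E`).}
#' }
#' The anchor residue's side chain is occupied by the surface linkage, so a
#' scheme that labels the anchor residue is rejected at simulation time
#' (cysteine mode never labels `C`; no preset does).
#'
#' @param x A preset name, or a named character vector mapping residue codes
#'   to channel identifiers, e.g. `c(K = "K", Y = "Y")`.
#' @param name Optional display name for a custom scheme.
#' @return A `labeling_scheme` object.
#' @export
#' @examples
#' labeling_scheme("K+Y+W+DE")
labeling_scheme <- function(x, name = NULL) {
  if (inherits(x, "labeling_scheme")) return(x)
  presets <- list(
    "K" = c(K = "K"),
    "K+Y" = c(K = "K", Y = "Y"),
    "K+Y+W" = c(K = "K", Y = "Y", W = "W"),
    "K+Y+W+DE" = c(K = "K", Y = "Y", W = "W", D = "E", E = "E")
  )
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    if (!x %in% names(presets)) {
      abort(sprintf("Unknown labeling scheme preset '%s' (have: %s).",
                    x, paste(names(presets), collapse = ", ")))
    }
    channel_of <- presets[[x]]
    name <- name %||% x
  } else {
    channel_of <- x
    if (is.null(names(channel_of)) || !all(names(channel_of) %in% AA20) ||
        anyDuplicated(names(channel_of))) {
      abort("A custom scheme must be a named character vector over distinct standard residue codes.")
    }
    name <- name %||% paste(names(channel_of), collapse = "+")
  }
  structure(list(channel_of = channel_of, name = name),
            class = "labeling_scheme")
}

#' @export
print.labeling_scheme <- function(x, ...) {
  cat(sprintf("<labeling_scheme> %s: %s\n", x$name,
              paste(sprintf("%s->%s", names(x$channel_of), x$channel_of),
                    collapse = ", ")))
  invisible(x)
}

# Reject schemes that label the anchor residue (cysteine mode only).
check_scheme_anchor <- function(scheme, anchor) {
  if (anchor == "cysteine" && "C" %in% names(scheme$channel_of)) {
    abort("Labeling scheme must not label the anchor residue 'C' in cysteine anchor mode.")
  }
  invisible(scheme)
}

#' Labeled positions of a peptide
#'
#' Lists, N-terminus to C-terminus, every residue position whose amino acid
#' type is in the labeling scheme, with its channel.
#'
#' @param sequence A single peptide sequence string.
#' @param scheme A [labeling_scheme()] (object or preset name).
#' @return A tibble with columns `position` (1-based) and `channel`.
#' @export
#' @examples
#' label_positions("GKGKEC", "K")
label_positions <- function(sequence, scheme) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  scheme <- labeling_scheme(scheme)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- chars %in% names(scheme$channel_of)
  tibble(
    position = which(hit),
    channel = unname(scheme$channel_of[chars[hit]])
  )
}

#' Ideal (error-free) fluorosequence of a peptide
#'
#' Under ideal chemistry every Edman cycle removes exactly one residue, so a
#' label at position p drops in cycle p. Sequencing cannot proceed past the
#' anchor: positions beyond `anchor_index` are never removed and contribute
#' no drops (the anchor position itself, which is never labeled in cysteine
#' mode, is the last observable position). Drops past the cycle budget are
#' not observed.
#'
#' @param sequence Peptide sequence string.
#' @param scheme A [labeling_scheme()].
#' @param cycles Cycle budget `n >= 0`.
#' @param anchor_index 1-based anchor position; defaults to the peptide
#'   length (C-terminal anchoring; a free peptide behaves identically).
#' @return A `fluoroseq` object.
#' @export
#' @examples
#' encode_ideal("GKEGC", "K", cycles = 30, anchor_index = 5)   # (K,2)
#' encode_ideal("WKKAY", "K+Y+W", cycles = 5)                  # WKKxY
encode_ideal <- function(sequence, scheme, cycles = 30L,
                         anchor_index = nchar(sequence)) {
  stopifnot(cycles >= 0)
  labels <- label_positions(sequence, scheme)
  keep <- labels$position <= anchor_index & labels$position <= cycles
  fluoroseq(labels$channel[keep], labels$position[keep], cycles = as.integer(cycles))
}

# Bulk ideal encoding: one canonical read string per peptide row.
# Internal hot path used by ideal_coverage_curve().
encode_peptides <- function(peptides, scheme, cycles) {
  check_peptides(peptides, need_anchor = TRUE)
  scheme <- labeling_scheme(scheme)
  residues <- names(scheme$channel_of)
  pat <- sprintf("[%s]", paste(residues, collapse = ""))
  hits <- gregexpr(pat, peptides$peptide)
  n_hit <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), integer(1))
  pos <- unlist(lapply(hits, function(h) if (h[1] == -1L) integer(0) else as.integer(h)),
                use.names = FALSE)
  pep_row <- rep(seq_len(nrow(peptides)), n_hit)
  res <- substring(peptides$peptide[pep_row], pos, pos)
  chn <- unname(scheme$channel_of[res])
  keep <- pos <= peptides$anchor_index[pep_row] & pos <= cycles
  pep_row <- pep_row[keep]; pos <- pos[keep]; chn <- chn[keep]
  out <- rep("", nrow(peptides))
  if (length(pep_row) > 0L) {
    ord <- order(pep_row, pos, chn)
    tok <- sprintf("(%s,%d)", chn[ord], pos[ord])
    grp <- split(tok, pep_row[ord])
    vals <- vapply(grp, paste, "", collapse = ",")
    out[as.integer(names(vals))] <- vals
  }
  out
}
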