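# The 20 standard one-letter amino-acid codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Codes that occasionally occur in curated FASTA but are not standard
# residues (selenocysteine, pyrrolysine, ambiguity codes).
AA_NONSTANDARD <- c("U", "O", "B", "Z", "J", "X")

#' Lower median
#'
#' Median convention used for all integer-valued summaries (peptide lengths,
#' labelable-residue counts): for even-sized samples the lower of the two
#' central order statistics is reported, so the median of a set of integers
#' is always an attained integer value.
#'
#' @param x Numeric vector, non-empty.
#' @return The lower median of `x`.
#' @export
#' @examples
#' median_low(c(3, 1, 2, 10))  # 2, not 2.5
median_low <- function(x) {
  if (length(x) == 0L) abort("`x` must be non-empty.")
  sort(x)[floor((length(x) + 1) / 2)]
}

# --- deterministic seed derivation -----------------------------------------
#
# Independent substreams (per protein, per sweep combination, per shard) are
# derived from the master seed with modular integer arithmetic carried out
# exactly in doubles (all intermediates < 2^53), so a run is reproducible and
# sharding cannot change results. Modulus is the Mersenne prime 2^31 - 1,
# keeping every derived seed a valid 32-bit R seed.

SEED_MOD <- 2147483647

# (a * b) %% SEED_MOD without overflow: split b into 15-bit halves.
mulmod31 <- function(a, b) {
  a <- a %% SEED_MOD
  b <- b %% SEED_MOD
  hi <- b %/% 32768
  lo <- b %% 32768
  (((a * hi) %% SEED_MOD) * 32768 + a * lo) %% SEED_MOD
}

# Polynomial rolling hash of a string into [0, SEED_MOD).
hash_string31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% SEED_MOD
  h
}

#' Derive a substream seed from a master seed
#'
#' Mixes a master seed with a string key (e.g. a protein identifier) and an
#' integer counter into a new seed in `[1, 2^31 - 2]`. Used so that per-protein
#' and per-sweep-combination random streams are independent of execution order
#' and sharding.
#'
#' @param master Integer master seed.
#' @param key Character key (may be `""`).
#' @param counter Integer counter (default 0).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, key = "", counter = 0L) {
  h <- hash_string31(as.character(key))
  s <- mulmod31(h + 1, 48271)
  s <- (s + mulmod31(as.double(master) %% SEED_MOD, 69621)) %% SEED_MOD
  s <- (s + mulmod31(as.double(counter) %% SEED_MOD, 16807)) %% SEED_MOD
  as.integer(s %% (SEED_MOD - 2) + 1)
}

# Validate a proteome table: tibble with protein_id and sequence columns.
check_proteome <- function(proteome, arg = "proteome") {
  if (!is.data.frame(proteome) ||
      !all(c("protein_id", "sequence") %in% names(proteome))) {
    abort(sprintf("`%s` must be a data frame with columns `protein_id` and `sequence`.", arg))
  }
  invisible(proteome)
}

# Validate a peptide table (output of digest()/filter_by_anchor()).
check_peptides <- function(peptides, need_anchor = FALSE, arg = "peptides") {
  cols <- c("protein_id", "peptide", if (need_anchor) "anchor_index")
  if (!is.data.frame(peptides) || !all(cols %in% names(peptides))) {
    abort(sprintf("`%s` must be a peptide table with columns %s.",
                  arg, paste0("`", cols, "`", collapse = ", ")))
  }
  invisible(peptides)
}
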