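#' Attribution tries
#'
#' Observed reads are collated into a prefix trie keyed by (channel, cycle)
#' drop events; each node tallies, per source protein, how often the
#' fluorosequence ending at that node was observed. Because a node is
#' addressed exactly by its canonical read string (drops sorted by cycle,
#' then channel), the trie is stored as a count table keyed by that string
#' -- the flattened form of the trie that is also its serialization format.
#' Prefix relations between nodes are recovered from the strings themselves;
#' per-node counts, merging, attribution p.m.f.s and coverage are identical
#' to an explicitly linked trie. Empty reads are kept in a dedicated empty
#' tally (key `""`) for count conservation but are never attributable.
#'
#' @param counts Optional tibble (`fs`, `protein_id`, `n`) to initialize
#'   from; reads must already be canonical.
#' @return An `attribution_trie` object.
#' @export
#' @examples
#' tr <- attribution_trie()
#' tr <- trie_insert(tr, "(K,2)", "X")
attribution_trie <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- tibble(fs = character(), protein_id = character(), n = integer())
  }
  stopifnot(all(c("fs", "protein_id", "n") %in% names(counts)))
  structure(list(counts = as_tibble(counts)), class = "attribution_trie")
}

# Build a trie from a vector of read strings and their source proteins.
# Internal bulk path: reads produced by the simulator are canonical by
# construction, so per-read validation is skipped.
trie_from_reads <- function(fs, protein_id) {
  stopifnot(length(fs) == length(protein_id))
  counts <- count(tibble(fs = fs, protein_id = protein_id),
                  .data$fs, .data$protein_id, name = "n")
  attribution_trie(counts)
}

#' @export
print.attribution_trie <- function(x, ...) {
  n_node <- length(unique(x$counts$fs[x$counts$fs != ""]))
  cat(sprintf("<attribution_trie> %d nodes, %d proteins, %d observations (%d empty)\n",
              n_node, length(unique(x$counts$protein_id)), trie_total(x),
              sum(x$counts$n[x$counts$fs == ""])))
  invisible(x)
}

#' Total observations in a trie
#'
#' Sum of all per-protein counts, including the empty-read tally.
#'
#' @param trie An `attribution_trie`.
#' @return Integer total.
#' @export
trie_total <- function(trie) {
  stopifnot(inherits(trie, "attribution_trie"))
  sum(trie$counts$n)
}

#' Insert an observation into a trie
#'
#' Increments the count of `protein_id` at the node addressed by the read.
#' The read must be in canonical form (sorted by cycle then channel, no
#' duplicate drops); non-canonical input is an error. The empty read (`""`
#' or an empty `fluoroseq`) goes to the empty tally.
#'
#' @param trie An `attribution_trie`.
#' @param fs A canonical read string or `fluoroseq` object.
#' @param protein_id Source protein identifier.
#' @param n Count to add (default 1).
#' @return The updated trie.
#' @export
trie_insert <- function(trie, fs, protein_id, n = 1L) {
  stopifnot(inherits(trie, "attribution_trie"))
  if (inherits(fs, "fluoroseq")) {
    key <- fs_string(fs)
  } else {
    stopifnot(is.character(fs), length(fs) == 1L)
    if (nzchar(fs) && !is_canonical_fs(fs)) {
      abort(sprintf("Read is not in canonical sorted form: '%s'", fs))
    }
    key <- fs
  }
  counts <- trie$counts
  i <- which(counts$fs == key & counts$protein_id == protein_id)
  if (length(i) == 1L) {
    counts$n[i] <- counts$n[i] + n
  } else {
    counts <- bind_rows(counts, tibble(fs = key, protein_id = protein_id, n = as.integer(n)))
  }
  attribution_trie(counts)
}

#' Merge two attribution tries
#'
#' Per-node, per-protein counts add; the node set is the union of paths.
#' Merging is commutative and associative with the empty trie as identity,
#' so tries built over proteome shards merge into the same master trie
#' regardless of order.
#'
#' @param x,y `attribution_trie` objects.
#' @param ... Ignored.
#' @return The merged trie.
#' @export
merge.attribution_trie <- function(x, y, ...) {
  stopifnot(inherits(y, "attribution_trie"))
  counts <- bind_rows(x$counts, y$counts)
  counts <- summarise(group_by(counts, .data$fs, .data$protein_id),
                      n = sum(.data$n), .groups = "drop")
  attribution_trie(counts)
}

#' Attribution probability mass function at a read
#'
#' Empirical posterior over source proteins for an observed fluorosequence:
#' the per-protein counts at the read's node, normalized by the node total.
#' An unobserved read returns `NULL` (a distinct "unobserved" signal, not an
#' error); the empty read is never attributable and is an error.
#'
#' @param trie An `attribution_trie`.
#' @param fs Canonical read string or `fluoroseq`.
#' @return An `attribution_pmf` tibble (`protein_id`, `count`,
#'   `probability`), sorted by decreasing probability, with attributes
#'   `fs` and `total`; or `NULL` if the read was never observed.
#' @export
pmf_at <- function(trie, fs) {
  stopifnot(inherits(trie, "attribution_trie"))
  key <- if (inherits(fs, "fluoroseq")) fs_string(fs) else fs
  if (!nzchar(key)) abort("The empty read is never attributable.")
  node <- trie$counts[trie$counts$fs == key, , drop = FALSE]
  if (nrow(node) == 0L) return(NULL)
  out <- arrange(
    tibble(protein_id = node$protein_id, count = node$n,
           probability = node$n / sum(node$n)),
    dplyr::desc(.data$probability), .data$protein_id
  )
  structure(out, class = c("attribution_pmf", class(out)),
            fs = key, total = sum(node$n))
}

#' Uniquely attributed fluorosequences
#'
#' A read is uniquely attributed to its most frequent source protein iff
#' (a) that protein produced the read at least `min_count` times, and
#' (b) all rival proteins combined account for less than `rival_fraction`
#' of the read's observations. The defaults (10 observations out of a
#' 10,000-copy simulation depth; rivals under 10%) are the thresholds used
#' for full-depth runs; [run_monte_carlo()] rescales `min_count`
#' proportionally at other depths. Ties for most frequent are broken
#' alphabetically (they can only be attributed when `rival_fraction > 0.5`).
#'
#' @param trie An `attribution_trie`.
#' @param min_count Minimum count for the primary source (>= 1).
#' @param rival_fraction Maximum combined rival share, in (0, 1].
#' @return A tibble (`fs`, `protein_id`, `count`, `total`, `rival_share`),
#'   one row per uniquely attributed read.
#' @export
#' @examples
#' tr <- trie_from_reads(rep(c("(K,2)", "(K,3)"), c(95, 50)),
#'                       rep(c("A", "B"), c(95, 50)))
#' unique_attributions(tr)
unique_attributions <- function(trie, min_count = 10L, rival_fraction = 0.10) {
  stopifnot(inherits(trie, "attribution_trie"))
  if (min_count < 1) abort("`min_count` must be >= 1.")
  if (rival_fraction <= 0 || rival_fraction > 1) {
    abort("`rival_fraction` must be in (0, 1].")
  }
  counts <- filter(trie$counts, .data$fs != "")
  if (nrow(counts) == 0L) {
    return(tibble(fs = character(), protein_id = character(),
                  count = integer(), total = integer(), rival_share = double()))
  }
  nodes <- summarise(
    group_by(counts, .data$fs),
    protein_id = .data$protein_id[order(-.data$n, .data$protein_id)][1],
    count = max(.data$n),
    total = sum(.data$n),
    .groups = "drop"
  )
  nodes <- mutate(nodes, rival_share = (.data$total - .data$count) / .data$total)
  arrange(
    filter(nodes, .data$count >= min_count, .data$rival_share < rival_fraction),
    .data$fs
  )
}

#' Proteome coverage from an attribution trie
#'
#' A protein is identified when at least one fluorosequence is uniquely
#' attributed to it; coverage is the identified fraction of *all* proteins
#' in the input proteome (including proteins none of whose peptides carried
#' an anchor).
#'
#' @param trie An `attribution_trie` built over `proteome`.
#' @param proteome The proteome table the simulation used.
#' @param min_count,rival_fraction Attribution thresholds, as
#'   [unique_attributions()].
#' @return A `coverage_summary` object: `$identified` (character vector),
#'   `$n_proteins`, `$fraction`.
#' @export
proteome_coverage <- function(trie, proteome, min_count = 10L, rival_fraction = 0.10) {
  check_proteome(proteome)
  if (nrow(proteome) == 0L) abort("`proteome` must be non-empty.")
  att <- unique_attributions(trie, min_count, rival_fraction)
  identified <- sort(unique(att$protein_id))
  structure(
    list(identified = identified, n_proteins = nrow(proteome),
         fraction = length(identified) / nrow(proteome)),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d / %d proteins identified (%.1f%%)\n",
              length(x$identified), x$n_proteins, 100 * x$fraction))
  invisible(x)
}

#' Serialize / load an attribution trie
#'
#' Newline-delimited text format, one record per (node, source protein):
#' `fs<TAB>protein_id<TAB>count`, with the empty tally as an empty `fs`
#' field. The format is merge-friendly and diffable; a `.gz` path is
#' compressed transparently.
#'
#' @param trie An `attribution_trie`.
#' @param path Output (input) path; `.gz` suffix enables gzip.
#' @return `write_trie()`: `path` invisibly. `read_trie()`: the trie.
#' @export
write_trie <- function(trie, path) {
  stopifnot(inherits(trie, "attribution_trie"))
  readr::write_tsv(arrange(trie$counts, .data$fs, .data$protein_id), path,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_trie
#' @export
read_trie <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    fs = readr::col_character(), protein_id = readr::col_character(),
    n = readr::col_integer()))
  counts$fs[is.na(counts$fs)] <- ""
  attribution_trie(counts)
}

#' Attribution table as TSV
#'
#' Writes the [unique_attributions()] table (read, protein, count, total,
#' rival share) as TSV.
#'
#' @param trie An `attribution_trie`.
#' @param path Output path.
#' @param ... Passed to [unique_attributions()].
#' @return `path`, invisibly.
#' @export
write_attributions_tsv <- function(trie, path, ...) {
  readr::write_tsv(unique_attributions(trie, ...), path)
  invisible(path)
}
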