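#' Fluorosequence objects
#'
#' A fluorosequence is the observable read of a peptide: an ordered set of
#' (channel, cycle) luminosity-drop events, sorted by cycle and then channel,
#' with no duplicate pairs (a drop is a binary per-channel, per-cycle
#' observation). The canonical text rendering is comma-joined tuples, e.g.
#' `"(K,2),(K,4)"`; the empty read renders as `""`.
#'
#' @param channel Character vector of channel identifiers.
#' @param cycle Integer vector of 1-based cycle indices (same length).
#' @param cycles Optional cycle budget the read was produced under.
#' @return A `fluoroseq` object (a tibble of `channel`, `cycle` with class
#'   `fluoroseq`).
#' @export
#' @examples
#' fluoroseq(c("K", "K"), c(2, 4))
fluoroseq <- function(channel = character(), cycle = integer(), cycles = NA_integer_) {
  if (length(channel) != length(cycle)) {
    abort("`channel` and `cycle` must have the same length.")
  }
  cycle <- as.integer(cycle)
  if (any(cycle < 1L)) abort("Drop cycles must be >= 1.")
  ord <- order(cycle, channel)
  channel <- channel[ord]
  cycle <- cycle[ord]
  if (anyDuplicated(paste(channel, cycle))) {
    abort("Duplicate (channel, cycle) drops are not allowed.")
  }
  drops <- tibble(channel = as.character(channel), cycle = cycle)
  structure(drops, class = c("fluoroseq", class(drops)), cycles = cycles)
}

#' @export
print.fluoroseq <- function(x, ...) {
  cat("<fluoroseq>", if (nrow(x) == 0L) "(empty)" else fs_string(x), "\n")
  if (nrow(x) > 0L) cat(" pattern:", fs_pattern(x), "\n")
  invisible(x)
}

#' Canonical string rendering of a fluorosequence
#'
#' @param fs A `fluoroseq` object (or tibble with `channel`, `cycle`).
#' @return A string like `"(K,2),(K,4)"`; `""` for an empty read.
#' @export
fs_string <- function(fs) {
  if (nrow(fs) == 0L) return("")
  paste(sprintf("(%s,%d)", fs$channel, fs$cycle), collapse = ",")
}

#' Parse a canonical fluorosequence string
#'
#' Inverse of [fs_string()]. Errors on non-canonical input (drops out of
#' (cycle, channel) order, duplicates, cycles < 1).
#'
#' @param string A canonical fluorosequence string; `""` parses to the empty
#'   read.
#' @param cycles Optional cycle budget to record.
#' @return A `fluoroseq` object.
#' @export
as_fluoroseq <- function(string, cycles = NA_integer_) {
  if (inherits(string, "fluoroseq")) return(string)
  stopifnot(is.character(string), length(string) == 1L)
  if (!nzchar(string)) return(fluoroseq(cycles = cycles))
  m <- regmatches(string, gregexpr("\\(([^,()]+),(\\d+)\\)", string))[[1]]
  flat <- gsub("[()]", "", m)
  parts <- strsplit(flat, ",", fixed = TRUE)
  if (length(m) == 0L ||
      paste(m, collapse = ",") != string ||
      any(lengths(parts) != 2L)) {
    abort(sprintf("Not a canonical fluorosequence string: '%s'", string))
  }
  channel <- vapply(parts, `[[`, "", 1L)
  cycle <- as.integer(vapply(parts, `[[`, "", 2L))
  if (is.unsorted(order(cycle, channel)) ||
      any(order(cycle, channel) != seq_along(cycle))) {
    abort(sprintf("Fluorosequence drops out of canonical (cycle, channel) order: '%s'", string))
  }
  fluoroseq(channel, cycle, cycles = cycles)
}

# TRUE if a canonical-format string is validly ordered; used by trie insert.
is_canonical_fs <- function(string) {
  ok <- tryCatch({
    as_fluoroseq(string)
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Per-cycle pattern rendering of a fluorosequence
#'
#' Human-readable rendering with one character per experimental cycle: the
#' channel letter where exactly one channel dropped, `"x"` where none did,
#' and the collision marker `"*"` where two or more channels dropped in the
#' same cycle.
#'
#' @param fs A `fluoroseq` object.
#' @param cycles Number of cycles to render; defaults to the read's recorded
#'   budget, else its last drop cycle.
#' @return A single string, e.g. `"xKxxK"`.
#' @export
#' @examples
#' fs_pattern(fluoroseq(c("K", "K"), c(2, 5)))  # "xKxxK"
fs_pattern <- function(fs, cycles = NULL) {
  cycles <- cycles %||% attr(fs, "cycles")
  if (is.null(cycles) || is.na(cycles)) {
    cycles <- if (nrow(fs) > 0L) max(fs$cycle) else 0L
  }
  if (cycles == 0L) return("")
  out <- rep("x", cycles)
  if (nrow(fs) > 0L) {
    keep <- fs$cycle <= cycles
    tab <- table(fs$cycle[keep])
    cyc <- as.integer(names(tab))
    single <- cyc[tab == 1L]
    multi <- cyc[tab > 1L]
    out[single] <- fs$channel[keep][match(single, fs$cycle[keep])]
    out[multi] <- "*"
  }
  paste(out, collapse = "")
}
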