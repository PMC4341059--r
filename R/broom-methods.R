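#' Tidy a Monte Carlo result
#'
#' Returns the unique-attribution table: one row per fluorosequence uniquely
#' attributed to a protein, with its count, node total, and rival share.
#'
#' @param x A `fluorosim_result`.
#' @param ... Ignored.
#' @return A tibble (`fs`, `protein_id`, `count`, `total`, `rival_share`).
#' @export
tidy.fluorosim_result <- function(x, ...) {
  x$attributions
}

#' One-row summary of a Monte Carlo result
#'
#' @param x A `fluorosim_result`.
#' @param ... Ignored.
#' @return A one-row tibble: proteome size, peptide count, depth, cycles,
#'   error parameters, identified count and coverage fraction, seed,
#'   runtime.
#' @export
glance.fluorosim_result <- function(x, ...) {
  tibble(
    n_proteins = x$coverage$n_proteins,
    n_peptides = x$n_peptides,
    depth = x$config$depth,
    cycles = x$config$cycles,
    dye_failure = x$config$params$u,
    edman_efficiency = x$config$params$p,
    half_life_cycles = x$config$params$half_life_cycles,
    identified = length(x$coverage$identified),
    coverage = x$coverage$fraction,
    scaled_down = x$scaled_down,
    seed = x$config$seed,
    runtime_seconds = x$runtime_seconds
  )
}

#' Tidy a coverage summary
#'
#' @param x A `coverage_summary`.
#' @param ... Ignored.
#' @return A tibble with one row per identified protein.
#' @export
tidy.coverage_summary <- function(x, ...) {
  tibble(protein_id = x$identified)
}

#' One-row summary of a coverage summary
#'
#' @param x A `coverage_summary`.
#' @param ... Ignored.
#' @return A one-row tibble: `identified`, `n_proteins`, `fraction`.
#' @export
glance.coverage_summary <- function(x, ...) {
  tibble(identified = length(x$identified), n_proteins = x$n_proteins,
         fraction = x$fraction)
}
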