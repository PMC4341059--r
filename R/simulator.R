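#' Simulation configuration
#'
#' Validates and bundles everything a Monte Carlo run needs. Validation
#' failures are reported collectively.
#'
#' @param proteome A proteome table or a FASTA path.
#' @param protease A [protease()] rule or preset name.
#' @param anchor `"cysteine"` or `"c_terminus"`.
#' @param scheme A [labeling_scheme()] or preset name.
#' @param cycles Cycle budget (default 30; undigested full-protein runs
#'   typically use 200).
#' @param depth Simulated copies per peptide (default 10,000; desk-scale
#'   examples use 100-500 and are labeled scaled-down in the result).
#' @param params An [error_params()] object.
#' @param seed Master seed; per-protein substreams are derived from it via
#'   [derive_seed()], so sharding and execution order cannot change results.
#' @param min_count Unique-attribution count threshold, or `NULL` (default)
#'   to scale the full-depth threshold of 10 per 10,000 proportionally with
#'   `depth` (keeping the implied 0.1% rate; never below 1). The scaling is
#'   logged.
#' @param rival_fraction Maximum combined rival share (default 0.10).
#' @param shards Number of proteome shards to process and merge (default 1);
#'   results are shard-invariant.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(proteome, protease = "gluc", anchor = "cysteine",
                              scheme = "K", cycles = 30L, depth = 10000L,
                              params = error_params(), seed = 1L,
                              min_count = NULL, rival_fraction = 0.10,
                              shards = 1L) {
  problems <- character()
  if (is.character(proteome) && length(proteome) == 1L) {
    proteome <- read_fasta(proteome)
  }
  if (!is.data.frame(proteome) ||
      !all(c("protein_id", "sequence") %in% names(proteome))) {
    problems <- c(problems, "`proteome` must be a proteome table or FASTA path.")
  }
  protease <- tryCatch(protease(protease), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  anchor <- if (is.character(anchor) && length(anchor) == 1L &&
                anchor %in% c("cysteine", "c_terminus")) {
    anchor
  } else {
    problems <- c(problems, "`anchor` must be 'cysteine' or 'c_terminus'."); NULL
  }
  scheme <- tryCatch(labeling_scheme(scheme), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })
  if (!is.null(scheme) && !is.null(anchor)) {
    tryCatch(check_scheme_anchor(scheme, anchor), error = function(e) {
      problems <<- c(problems, conditionMessage(e))
    })
  }
  if (!is.numeric(cycles) || cycles < 1) problems <- c(problems, "`cycles` must be >= 1.")
  if (!is.numeric(depth) || depth < 1) problems <- c(problems, "`depth` must be >= 1.")
  if (!inherits(params, "error_params")) problems <- c(problems, "`params` must be an error_params object.")
  if (!is.numeric(seed) || length(seed) != 1L) problems <- c(problems, "`seed` must be a single integer.")
  if (!is.numeric(shards) || shards < 1) problems <- c(problems, "`shards` must be >= 1.")
  if (length(problems) > 0L) {
    abort(paste(c("Invalid simulation configuration:", paste("-", problems)),
                collapse = "\n"))
  }
  if (is.null(min_count)) {
    min_count <- max(1L, as.integer(round(10 * depth / 10000)))
    if (depth != 10000L) {
      message(sprintf(
        "min_count scaled to %d for depth %d (10 per 10,000 copies).",
        min_count, as.integer(depth)))
    }
  }
  structure(
    list(proteome = as_tibble(proteome), protease = protease, anchor = anchor,
         scheme = scheme, cycles = as.integer(cycles), depth = as.integer(depth),
         params = params, seed = as.integer(seed), min_count = as.integer(min_count),
         rival_fraction = rival_fraction, shards = as.integer(shards)),
    class = "simulation_config"
  )
}

#' Ideal-condition proteome coverage curve
#'
#' Error-free identification is deterministic, so the curve is computed
#' analytically rather than by sampling: at cycle budget `n` a protein is
#' identified iff one of its anchored peptides' ideal reads, truncated to
#' `n` cycles, is non-empty and produced by no other protein's peptide.
#' Coverage is non-decreasing in `n`.
#'
#' @param proteome A proteome table.
#' @param protease,anchor,scheme As in [simulation_config()].
#' @param max_cycles Largest cycle budget to evaluate.
#' @return A `coverage_curve` tibble: `cycles` (0..max), `identified`,
#'   `fraction`.
#' @export
#' @examples
#' prot <- tibble::tibble(protein_id = c("P1", "P2"),
#'                        sequence = c("GKEGC", "GGEGC"))
#' ideal_coverage_curve(prot, "none", "cysteine", "K", max_cycles = 5)
ideal_coverage_curve <- function(proteome, protease, anchor, scheme,
                                 max_cycles = 30L) {
  check_proteome(proteome)
  anchor <- match.arg(anchor, c("cysteine", "c_terminus"))
  scheme <- labeling_scheme(scheme)
  check_scheme_anchor(scheme, anchor)
  peptides <- filter_by_anchor(digest(proteome, protease), anchor)
  residues <- names(scheme$channel_of)

  # Labeled positions of every peptide, long form.
  if (nrow(peptides) > 0L) {
    pat <- sprintf("[%s]", paste(residues, collapse = ""))
    hits <- gregexpr(pat, peptides$peptide)
    n_hit <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), integer(1))
    pos <- unlist(lapply(hits, function(h) if (h[1] == -1L) integer(0) else as.integer(h)),
                  use.names = FALSE)
    row <- rep(seq_len(nrow(peptides)), n_hit)
    ok <- pos <= peptides$anchor_index[row]
    row <- row[ok]; pos <- pos[ok]
    res <- substring(peptides$peptide[row], pos, pos)
    chn <- unname(scheme$channel_of[res])
    drops <- tibble(row = row, protein_id = peptides$protein_id[row],
                    pos = pos, channel = chn)
  } else {
    drops <- tibble(row = integer(), protein_id = character(),
                    pos = integer(), channel = character())
  }

  out <- vector("list", max_cycles + 1L)
  out[[1]] <- tibble(cycles = 0L, identified = 0L, fraction = 0)
  for (n in seq_len(max_cycles)) {
    d <- drops[drops$pos <= n, , drop = FALSE]
    if (nrow(d) == 0L) {
      out[[n + 1L]] <- tibble(cycles = n, identified = 0L, fraction = 0)
      next
    }
    ord <- order(d$row, d$pos, d$channel)
    tok <- sprintf("(%s,%d)", d$channel[ord], d$pos[ord])
    reads <- vapply(split(tok, d$row[ord]), paste, "", collapse = ",")
    prot <- d$protein_id[ord][!duplicated(d$row[ord])]
    uniq <- distinct(tibble(read = reads, protein_id = prot))
    solo <- summarise(group_by(uniq, .data$read),
                      n_prot = dplyr::n_distinct(.data$protein_id),
                      protein_id = .data$protein_id[1], .groups = "drop")
    ident <- unique(solo$protein_id[solo$n_prot == 1L])
    out[[n + 1L]] <- tibble(cycles = n, identified = length(ident),
                            fraction = length(ident) / nrow(proteome))
  }
  curve <- bind_rows(out)
  structure(curve, class = c("coverage_curve", class(curve)),
            anchor = anchor, scheme = scheme$name)
}

#' Run a Monte Carlo fluorosequencing simulation
#'
#' Digests and anchor-filters the proteome, simulates `depth` copies of each
#' retained peptide under the error model, collates the reads into an
#' attribution trie, and derives unique attributions and proteome coverage.
#' Each protein gets its own RNG substream derived from the master seed and
#' its identifier, so results are independent of protein order and of the
#' number of shards.
#'
#' @param config A [simulation_config()].
#' @return A `fluorosim_result`: `$trie`, `$attributions`, `$coverage`,
#'   `$config`, `$n_peptides`, `$runtime_seconds`, `$scaled_down` (TRUE when
#'   depth < 10,000).
#' @export
#' @examples
#' prot <- tibble::tibble(protein_id = c("X", "Y"),
#'                        sequence = c("GKEGC", "GKGKEC"))
#' cfg <- simulation_config(prot, "none", "cysteine", "K",
#'                          cycles = 30, depth = 500, seed = 7)
#' run_monte_carlo(cfg)
run_monte_carlo <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  t0 <- proc.time()[["elapsed"]]
  peptides <- filter_by_anchor(digest(config$proteome, config$protease),
                               config$anchor)
  shard_of <- rep(seq_len(config$shards),
                  length.out = nrow(config$proteome))
  shard_tries <- vector("list", config$shards)
  for (s in seq_len(config$shards)) {
    ids <- config$proteome$protein_id[shard_of == s]
    shard_tries[[s]] <- simulate_shard(
      peptides[peptides$protein_id %in% ids, , drop = FALSE], config)
  }
  trie <- Reduce(merge, shard_tries, attribution_trie())
  att <- unique_attributions(trie, config$min_count, config$rival_fraction)
  cov <- proteome_coverage(trie, config$proteome, config$min_count,
                           config$rival_fraction)
  structure(
    list(trie = trie, attributions = att, coverage = cov, config = config,
         n_peptides = nrow(peptides),
         runtime_seconds = proc.time()[["elapsed"]] - t0,
         scaled_down = config$depth < 10000L),
    class = "fluorosim_result"
  )
}

# Simulate all peptides of one proteome shard into a trie.
simulate_shard <- function(peptides, config) {
  if (nrow(peptides) == 0L) return(attribution_trie())
  by_prot <- split(seq_len(nrow(peptides)), peptides$protein_id)
  fs_all <- vector("list", length(by_prot))
  id_all <- vector("list", length(by_prot))
  for (k in seq_along(by_prot)) {
    pid <- names(by_prot)[k]
    rows <- by_prot[[k]]
    withr::with_seed(derive_seed(config$seed, pid), {
      reads <- lapply(rows, function(i) {
        simulate_reads(peptides$peptide[i], config$scheme, config$params,
                       cycles = config$cycles, depth = config$depth,
                       anchor_index = peptides$anchor_index[i])
      })
    })
    fs_all[[k]] <- unlist(reads, use.names = FALSE)
    id_all[[k]] <- rep(pid, length(rows) * config$depth)
  }
  trie_from_reads(unlist(fs_all, use.names = FALSE),
                  unlist(id_all, use.names = FALSE))
}

#' @export
print.fluorosim_result <- function(x, ...) {
  cat(sprintf(
    "<fluorosim_result> %s + %s + %s, %d cycles, depth %d%s, seed %d\n",
    x$config$protease$name, x$config$anchor, x$config$scheme$name,
    x$config$cycles, x$config$depth,
    if (x$scaled_down) " (scaled-down)" else "", x$config$seed))
  cat(sprintf("  %d peptides simulated; %d reads; coverage %.1f%% (%d/%d proteins)\n",
              x$n_peptides, trie_total(x$trie), 100 * x$coverage$fraction,
              length(x$coverage$identified), x$coverage$n_proteins))
  invisible(x)
}

#' Sweep the three error parameters
#'
#' Runs one Monte Carlo simulation per combination of dye-failure rate,
#' Edman efficiency, and photobleaching half-life, each with a seed derived
#' from the master seed and the combination index (rows are independent and
#' order-insensitive). The default axes are six values each: dye failure
#' evenly spaced over 0-25%, Edman efficiency evenly spaced over 90-100%,
#' and photobleaching half-lives from 210 cycles to no photobleaching.
#'
#' @param config A [simulation_config()]; its `params` are overridden
#'   combination by combination.
#' @param dye_failure,edman_efficiency,half_life_cycles Numeric axes; the
#'   full grid is their Cartesian product (must be non-empty).
#' @return A `sweep_result` tibble: `dye_failure`, `edman_efficiency`,
#'   `half_life_cycles`, `coverage`, `identified`, `runtime_seconds`.
#' @export
parameter_sweep <- function(config,
                            dye_failure = seq(0, 0.25, length.out = 6),
                            edman_efficiency = seq(0.90, 1.00, length.out = 6),
                            half_life_cycles = c(210, 450, 900, 1800, 5400, Inf)) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(dye_failure) == 0L || length(edman_efficiency) == 0L ||
      length(half_life_cycles) == 0L) {
    abort("Sweep axes must be non-empty.")
  }
  grid <- tidyr::expand_grid(
    dye_failure = dye_failure,
    edman_efficiency = edman_efficiency,
    half_life_cycles = half_life_cycles
  )
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$params <- error_params(
      dye_failure = grid$dye_failure[i],
      edman_efficiency = grid$edman_efficiency[i],
      half_life_cycles = grid$half_life_cycles[i],
      exposure_seconds = config$params$exposure_seconds
    )
    cfg$seed <- derive_seed(config$seed, "sweep", i)
    res <- run_monte_carlo(cfg)
    rows[[i]] <- mutate(grid[i, , drop = FALSE],
                        coverage = res$coverage$fraction,
                        identified = length(res$coverage$identified),
                        runtime_seconds = res$runtime_seconds)
  }
  out <- bind_rows(rows)
  structure(out, class = c("sweep_result", class(out)))
}
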