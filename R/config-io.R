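#' Read a simulation configuration file
#'
#' Flat YAML key-value file mirroring [simulation_config()]. Recognized
#' keys: `proteome` (FASTA path) or `synthetic_n` / `synthetic_length` /
#' `synthetic_composition` (`"uniform"` or `"human"`), `protease`, `anchor`,
#' `scheme`, `cycles`, `depth`, `seed`, `min_count`, `rival_fraction`,
#' `shards`, and the error keys `dye_failure`, `edman_efficiency`, and
#' either `photobleach_half_life_cycles` or `photobleach_half_life_minutes`
#' with `exposure_seconds`.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config` object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  get <- function(key, default) cfg[[key]] %||% default
  proteome <- if (!is.null(cfg$proteome)) {
    read_fasta(cfg$proteome)
  } else if (!is.null(cfg$synthetic_n)) {
    comp <- switch(get("synthetic_composition", "uniform"),
                   uniform = composition_uniform(),
                   human = composition_human(),
                   abort("`synthetic_composition` must be 'uniform' or 'human'."))
    generate_synthetic_proteome(
      cfg$synthetic_n,
      length_sampler = if (!is.null(cfg$synthetic_length)) cfg$synthetic_length
                       else length_sampler_lognormal(),
      composition = comp,
      seed = get("seed", 1L)
    )
  } else {
    abort("Config must set `proteome` (FASTA path) or `synthetic_n`.")
  }
  hl_cycles <- cfg$photobleach_half_life_cycles
  if (!is.null(hl_cycles) && identical(hl_cycles, "Inf")) hl_cycles <- Inf
  params <- error_params(
    dye_failure = get("dye_failure", 0),
    edman_efficiency = get("edman_efficiency", 1),
    half_life_cycles = hl_cycles %||% Inf,
    half_life_minutes = cfg$photobleach_half_life_minutes,
    exposure_seconds = get("exposure_seconds", 1)
  )
  simulation_config(
    proteome = proteome,
    protease = get("protease", "gluc"),
    anchor = get("anchor", "cysteine"),
    scheme = get("scheme", "K"),
    cycles = get("cycles", 30L),
    depth = get("depth", 10000L),
    params = params,
    seed = get("seed", 1L),
    min_count = cfg$min_count,
    rival_fraction = get("rival_fraction", 0.10),
    shards = get("shards", 1L)
  )
}

#' Write a coverage curve as TSV
#'
#' @param curve A `coverage_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(curve, path) {
  readr::write_tsv(as_tibble(curve), path)
  invisible(path)
}
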