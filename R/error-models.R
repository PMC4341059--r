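#' Error-model parameters
#'
#' Bundles the three stochastic error processes of the simulation:
#' \describe{
#'   \item{dye failure `u`}{each label independently never fluoresces with
#'     probability `u` (failed attachment or a dark fluorophore), causing an
#'     apparent substitution.}
#'   \item{Edman efficiency `p`}{each cycle's removal attempt succeeds with
#'     probability `p` (failure `q = 1 - p`); failures dilate the inter-label
#'     intervals, an interval of `d` residues taking `d + e` cycles with
#'     negative-binomial `e` (see [dilation_pmf()]).}
#'   \item{photobleaching `b`}{each fluorophore survives `k` cycles with
#'     probability `exp(-b * k)`; a bleach before removal shifts the drop to
#'     an earlier cycle (an apparent residue swap). `b = 0` means no
#'     photobleaching. Specify either the decay constant implicitly via
#'     `half_life_cycles` (`b = ln 2 / half-life`) or via
#'     `half_life_minutes`, converted with `exposure_seconds` of laser
#'     exposure per cycle (additive-exposure property of bleaching).}
#' }
#'
#' @param dye_failure Probability in `[0, 1]`. Default 0.
#' @param edman_efficiency Probability in `(0, 1]`. Default 1.
#' @param half_life_cycles Fluorophore half-life in experimental cycles
#'   (`Inf` = no photobleaching). Default `Inf`.
#' @param half_life_minutes Optional half-life in minutes; overrides
#'   `half_life_cycles` via `minutes * 60 / exposure_seconds`.
#' @param exposure_seconds Laser exposure per cycle, seconds (default 1).
#' @return An `error_params` object with fields `u`, `p`, `b`,
#'   `half_life_cycles`, `exposure_seconds`.
#' @export
#' @examples
#' error_params(dye_failure = 0.2, edman_efficiency = 0.9, half_life_cycles = 20)
#' error_params(half_life_minutes = 30)  # 1800 cycles at 1 s exposure
error_params <- function(dye_failure = 0, edman_efficiency = 1,
                         half_life_cycles = Inf, half_life_minutes = NULL,
                         exposure_seconds = 1) {
  if (!is.numeric(dye_failure) || dye_failure < 0 || dye_failure > 1) {
    abort("`dye_failure` must be a probability in [0, 1].")
  }
  if (!is.numeric(edman_efficiency) || edman_efficiency <= 0 || edman_efficiency > 1) {
    abort("`edman_efficiency` must be a probability in (0, 1].")
  }
  if (!is.null(half_life_minutes)) {
    if (exposure_seconds <= 0) abort("`exposure_seconds` must be positive.")
    half_life_cycles <- half_life_minutes * 60 / exposure_seconds
  }
  b <- halflife_to_decay_constant(half_life_cycles)
  structure(
    list(u = dye_failure, p = edman_efficiency, b = b,
         half_life_cycles = half_life_cycles,
         exposure_seconds = exposure_seconds),
    class = "error_params"
  )
}

#' @export
print.error_params <- function(x, ...) {
  cat(sprintf(
    "<error_params> dye failure u = %g, Edman efficiency p = %g, photobleach half-life = %g cycles (b = %g)\n",
    x$u, x$p, x$half_life_cycles, x$b))
  invisible(x)
}

#' Photobleaching half-life to exponential decay constant
#'
#' Survival over `k` cycles is `exp(-b * k)`; at `k` equal to the half-life
#' it is exactly 1/2, so `b = ln(2) / half_life`. An infinite half-life maps
#' to `b = 0` (no photobleaching).
#'
#' @param half_life_cycles Positive half-life in cycles, or `Inf`.
#' @return The decay constant `b >= 0` (per cycle).
#' @export
halflife_to_decay_constant <- function(half_life_cycles) {
  if (!is.numeric(half_life_cycles) || length(half_life_cycles) != 1L ||
      is.na(half_life_cycles) || half_life_cycles <= 0) {
    abort("`half_life_cycles` must be a positive number or Inf.")
  }
  if (is.infinite(half_life_cycles)) 0 else log(2) / half_life_cycles
}

#' Interval-dilation probability mass function
#'
#' Probability that an inter-label interval of `d` residues requires `d + e`
#' experimental cycles before the downstream label is removed, under
#' independent per-cycle Edman success probability `p`:
#' `choose(d - 1 + e, e) * p^d * q^e` with `q = 1 - p` -- the negative
#' binomial law of `e` failures interleaved before the `d`-th success, the
#' final trial being a success.
#'
#' @param d Interval length in residues (>= 1).
#' @param e Number of extra cycles (>= 0); vectorized.
#' @param p Per-cycle Edman success probability in (0, 1].
#' @return `P(extra cycles = e)`, same length as `e`.
#' @export
#' @examples
#' dilation_pmf(1, 0:3, 0.5)      # geometric wait: 0.5, 0.25, ...
#' dilation_pmf(2, 1, 0.9)        # 2 * 0.81 * 0.1 = 0.162
dilation_pmf <- function(d, e, p) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != floor(d)) {
    abort("`d` must be a single integer >= 1.")
  }
  if (any(e < 0) || any(e != floor(e))) abort("`e` must be non-negative integers.")
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].")
  dnbinom(e, size = d, prob = p)
}

#' Dye failure: delete labels that never fluoresce
#'
#' Each label is independently deleted with probability `u`; order is
#' preserved. With `u = 0` this is the identity, with `u = 1` all labels are
#' lost.
#'
#' @param labels A label table from [label_positions()] (`position`,
#'   `channel`).
#' @param u Dye failure probability in `[0, 1]`.
#' @param fail Optional logical vector (one per label) fixing which labels
#'   fail, for reproducing specific single-event scenarios; when `NULL`
#'   (default) failures are drawn from the current RNG stream.
#' @return The surviving subset of `labels`.
#' @export
apply_dye_failure <- function(labels, u, fail = NULL) {
  if (!is.numeric(u) || u < 0 || u > 1) abort("`u` must be in [0, 1].")
  n <- nrow(labels)
  if (is.null(fail)) fail <- runif(n) < u
  stopifnot(length(fail) == n)
  labels[!fail, , drop = FALSE]
}

#' Edman dilation: assign removal cycles to surviving labels
#'
#' For surviving labeled positions `i1 < i2 < ...` (up to the anchor), the
#' inter-label intervals are `d1 = i1`, `dj = ij - i(j-1)`. Each interval
#' independently takes `dj + ej` cycles with `ej` drawn from
#' [dilation_pmf()], so the removal cycle of the j-th label is the running
#' sum of `dt + et`. Labels strictly beyond the anchor position are never
#' removed (`removal_cycle = Inf`): Edman chemistry cannot proceed past the
#' residue attached to the surface.
#'
#' @param labels A label table (`position`, `channel`) with strictly
#'   increasing positions.
#' @param p Per-cycle Edman success probability.
#' @param anchor_index Anchor position; positions `> anchor_index` get
#'   `removal_cycle = Inf`.
#' @param dilation Optional integer vector of fixed `e` values (one per
#'   removable label), for deterministic scenarios.
#' @return `labels` with a `removal_cycle` column appended.
#' @export
apply_edman_dilation <- function(labels, p, anchor_index, dilation = NULL) {
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].")
  pos <- labels$position
  if (is.unsorted(pos, strictly = TRUE)) {
    abort("Label positions must be strictly increasing.")
  }
  removable <- pos <= anchor_index
  d <- diff(c(0L, pos[removable]))
  if (is.null(dilation)) {
    dilation <- if (length(d) > 0L) rnbinom(length(d), size = d, prob = p) else integer(0)
  }
  stopifnot(length(dilation) == length(d))
  removal <- rep(Inf, nrow(labels))
  removal[removable] <- cumsum(d + dilation)
  labels$removal_cycle <- removal
  labels
}

#' Photobleaching: observed drop cycles and final read
#'
#' Each fluorophore draws a continuous bleach time `T ~ Exponential(b)` in
#' cycle units (`T = Inf` when `b = 0`); a bleach during cycle `t`
#' contributes a drop at cycle `ceiling(t)` (the imaging after that cycle).
#' The observed drop is whichever comes first, removal or bleach:
#' `min(removal_cycle, ceiling(T))`. Drops past the budget are discarded;
#' coincident drops in the same channel and cycle collapse to a single event
#' (only a per-channel luminosity decrease is observable, not how many
#' fluorophores were lost).
#'
#' @param labels A label table with `removal_cycle` (from
#'   [apply_edman_dilation()]).
#' @param b Decay constant per cycle (>= 0).
#' @param cycles Cycle budget.
#' @param bleach_cycles Optional integer vector of fixed bleach cycles (one
#'   per label; `Inf` = never bleaches), for deterministic scenarios.
#' @return A `fluoroseq` object.
#' @export
apply_photobleaching <- function(labels, b, cycles, bleach_cycles = NULL) {
  if (!is.numeric(b) || b < 0) abort("`b` must be >= 0.")
  n <- nrow(labels)
  if (is.null(bleach_cycles)) {
    bleach_cycles <- if (b == 0) rep(Inf, n) else ceiling(rexp(n, rate = b))
  }
  stopifnot(length(bleach_cycles) == n)
  obs <- pmin(labels$removal_cycle, bleach_cycles)
  keep <- is.finite(obs) & obs <= cycles
  chn <- labels$channel[keep]
  cyc <- as.integer(obs[keep])
  dup <- duplicated(paste(chn, cyc))
  fluoroseq(chn[!dup], cyc[!dup], cycles = as.integer(cycles))
}

#' Simulate one observed fluorosequence
#'
#' Composes the full per-molecule observation model in the order the errors
#' act physically: label the peptide, delete never-fluorescing labels
#' ([apply_dye_failure()]), dilate removal cycles by Edman failures
#' ([apply_edman_dilation()]), then overlay photobleaching and truncate to
#' the cycle budget ([apply_photobleaching()]). With `u = 0`, `p = 1`,
#' `b = 0` the result equals [encode_ideal()]. Uses the current RNG stream;
#' call `set.seed()` first for reproducibility.
#'
#' @param sequence Peptide sequence string.
#' @param scheme A [labeling_scheme()].
#' @param params An [error_params()] object.
#' @param cycles Cycle budget.
#' @param anchor_index Anchor position (default: peptide length).
#' @return A `fluoroseq` object.
#' @export
#' @examples
#' set.seed(1)
#' simulate_observed_fluorosequence("GKEGK", "K",
#'   error_params(dye_failure = 0.2, edman_efficiency = 0.9,
#'                half_life_cycles = 20), cycles = 6)
simulate_observed_fluorosequence <- function(sequence, scheme, params,
                                             cycles = 30L,
                                             anchor_index = nchar(sequence)) {
  stopifnot(inherits(params, "error_params"))
  labels <- label_positions(sequence, scheme)
  labels <- apply_dye_failure(labels, params$u)
  labels <- apply_edman_dilation(labels, params$p, anchor_index)
  apply_photobleaching(labels, params$b, cycles)
}

#' Simulate many reads of one peptide (vectorized)
#'
#' Monte Carlo engine used by [run_monte_carlo()]: simulates `depth`
#' independent copies of a peptide under the full error model and returns
#' canonical read strings. Statistically identical to `depth` calls of
#' [simulate_observed_fluorosequence()] (the Edman process is drawn as
#' per-position geometric failure counts, whose running sums have exactly
#' the negative-binomial interval law).
#'
#' @param sequence Peptide sequence string.
#' @param scheme A [labeling_scheme()].
#' @param params An [error_params()] object.
#' @param cycles Cycle budget.
#' @param depth Number of copies to simulate.
#' @param anchor_index Anchor position (default: peptide length).
#' @return A character vector of `depth` canonical read strings (`""` for
#'   empty reads).
#' @export
simulate_reads <- function(sequence, scheme, params, cycles = 30L, depth = 1L,
                           anchor_index = nchar(sequence)) {
  stopifnot(inherits(params, "error_params"), depth >= 1, cycles >= 0)
  labels <- label_positions(sequence, scheme)
  m <- nrow(labels)
  if (m == 0L || cycles == 0L) return(rep("", depth))
  pos <- labels$position
  chn <- labels$channel

  # Dye failure: m x depth survival mask.
  survive <- matrix(runif(m * depth) >= params$u, nrow = m)

  # Edman removal cycles. Only positions <= anchor_index are removable, and
  # removal cycles beyond the budget are never observed, so per-copy
  # cumulative failure counts are needed only up to position P*.
  Pstar <- min(anchor_index, cycles, max(pos))
  removal <- matrix(Inf, nrow = m, ncol = depth)
  if (Pstar >= 1L && params$p < 1) {
    g <- matrix(rgeom(Pstar * depth, prob = params$p), nrow = Pstar)
    tot <- cumsum(as.double(g))
    base <- rep(c(0, tot[Pstar * seq_len(depth - 1L)]), each = Pstar)
    cumfail <- matrix(tot - base, nrow = Pstar)
    idx <- which(pos <= Pstar)
    removal[idx, ] <- pos[idx] + cumfail[pos[idx], , drop = FALSE]
  } else if (Pstar >= 1L) {
    idx <- which(pos <= Pstar)
    removal[idx, ] <- pos[idx]
  }

  # Photobleaching: m x depth bleach cycles.
  bleach <- if (params$b == 0) {
    matrix(Inf, nrow = m, ncol = depth)
  } else {
    matrix(ceiling(rexp(m * depth, rate = params$b)), nrow = m)
  }

  obs <- pmin(removal, bleach)
  keep <- survive & is.finite(obs) & obs <= cycles
  hit <- which(keep)
  if (length(hit) == 0L) return(rep("", depth))
  copy <- (hit - 1L) %/% m + 1L
  lab <- (hit - 1L) %% m + 1L
  cyc <- as.integer(obs[hit])
  ch <- chn[lab]

  ord <- order(copy, cyc, ch)
  copy <- copy[ord]; cyc <- cyc[ord]; ch <- ch[ord]
  dup <- c(FALSE, copy[-1] == copy[-length(copy)] &
             cyc[-1] == cyc[-length(cyc)] &
             ch[-1] == ch[-length(ch)])
  copy <- copy[!dup]; cyc <- cyc[!dup]; ch <- ch[!dup]

  out <- rep("", depth)
  tok <- sprintf("(%s,%d)", ch, cyc)
  grp <- split(tok, copy)
  vals <- vapply(grp, paste, "", collapse = ",")
  out[as.integer(names(vals))] <- vals
  out
}
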