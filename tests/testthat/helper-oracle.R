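# Independent oracle: exact outcome distribution of the per-molecule
# observation model by exhaustive enumeration over (dye-failure patterns x
# bounded dilation vectors x discretized bleach cycles). Written separately
# from the package's sampling code paths; removal cycles that exceed the
# budget are lumped (they are observationally equivalent to "never removed").
#
# Returns a named numeric vector: canonical read string -> probability.
enumerate_read_distribution <- function(sequence, channel_of, u, p, b, n,
                                        anchor_index = nchar(sequence)) {
  chars <- strsplit(sequence, "")[[1]]
  pos <- which(chars %in% names(channel_of))
  chn <- unname(channel_of[chars[pos]])
  m <- length(pos)
  out <- new.env(parent = emptyenv())
  add <- function(key, pr) {
    key <- paste0("k:", key)  # env names must be non-empty
    cur <- if (is.null(out[[key]])) 0 else out[[key]]
    out[[key]] <- cur + pr
  }

  # bleach-cycle categories and probabilities for one fluor
  bleach_cats <- if (b == 0) {
    list(cycles = Inf, probs = 1)
  } else {
    k <- seq_len(n)
    list(cycles = c(k, Inf),
         probs = c(exp(-b * (k - 1)) - exp(-b * k), exp(-b * n)))
  }

  # enumerate removal-cycle vectors for surviving removable positions
  removal_branches <- function(d_vec) {
    branches <- list(list(removal = numeric(0), prob = 1, done = FALSE))
    for (d in d_vec) {
      nxt <- list()
      for (br in branches) {
        if (br$done || (length(br$removal) > 0 && utils::tail(br$removal, 1) > n)) {
          # already past budget: all later removals unobservable
          nxt[[length(nxt) + 1]] <- list(removal = c(br$removal, Inf),
                                         prob = br$prob, done = TRUE)
          next
        }
        base <- if (length(br$removal) > 0) utils::tail(br$removal, 1) else 0
        for (e in 0:n) {
          nxt[[length(nxt) + 1]] <- list(removal = c(br$removal, base + d + e),
                                         prob = br$prob * dnbinom(e, size = d, prob = p),
                                         done = FALSE)
        }
        tail_pr <- 1 - pnbinom(n, size = d, prob = p)
        if (tail_pr > 0) {
          nxt[[length(nxt) + 1]] <- list(removal = c(br$removal, Inf),
                                         prob = br$prob * tail_pr, done = TRUE)
        }
      }
      branches <- nxt
    }
    branches
  }

  canonical <- function(channel, cycle) {
    if (length(cycle) == 0) return("")
    ord <- order(cycle, channel)
    channel <- channel[ord]; cycle <- cycle[ord]
    dup <- duplicated(paste(channel, cycle))
    paste(sprintf("(%s,%d)", channel[!dup], as.integer(cycle[!dup])),
          collapse = ",")
  }

  masks <- if (m == 0) list(logical(0)) else
    lapply(0:(2^m - 1), function(x) as.logical(bitwAnd(x, 2^(seq_len(m) - 1))))
  for (surv in masks) {
    pr_dye <- prod(ifelse(surv, 1 - u, u))
    if (pr_dye == 0) next
    sp <- pos[surv]; sc <- chn[surv]
    removable <- sp <= anchor_index
    d_vec <- diff(c(0, sp[removable]))
    for (br in removal_branches(d_vec)) {
      removal <- rep(Inf, length(sp))
      removal[removable] <- br$removal
      # bleach categories per surviving label
      k_lab <- length(sp)
      grids <- rep(list(seq_along(bleach_cats$cycles)), k_lab)
      combos <- if (k_lab == 0) matrix(nrow = 1, ncol = 0) else
        as.matrix(expand.grid(grids))
      for (r in seq_len(nrow(combos))) {
        idx <- combos[r, ]
        pr_bleach <- prod(bleach_cats$probs[idx])
        obs <- pmin(removal, bleach_cats$cycles[idx])
        keep <- is.finite(obs) & obs <= n
        add(canonical(sc[keep], obs[keep]), pr_dye * br$prob * pr_bleach)
      }
    }
  }
  probs <- unlist(as.list(out))
  names(probs) <- sub("^k:", "", names(probs))
  probs
}

# Brute-force dilation pmf: enumerate Bernoulli trial strings of length
# d + e ending in a success and containing exactly d successes, summing
# their probabilities term by term (independent of any closed form).
brute_force_dilation_pmf <- function(d, e, p) {
  len <- d + e
  if (d < 1) stop("d >= 1")
  total <- 0
  # last trial fixed as success; choose positions of the remaining d - 1
  # successes among the first len - 1 trials
  slots <- seq_len(len - 1)
  choosers <- if (d - 1 == 0) list(integer(0)) else
    if (length(slots) == 0) list() else
      asplit(utils::combn(slots, d - 1), 2)
  for (succ in choosers) {
    trial <- rep(FALSE, len)
    trial[c(succ, len)] <- TRUE
    total <- total + prod(ifelse(trial, p, 1 - p))
  }
  total
}

# Small random proteome of clean sequences for property tests.
random_proteome <- function(n = 10, len = 40, seed = 1) {
  generate_synthetic_proteome(n, length_sampler = len,
                              composition = composition_uniform(), seed = seed)
}
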