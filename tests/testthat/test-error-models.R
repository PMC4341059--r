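test_that("dilation pmf matches hand-derived values and validates inputs", {
  # p = 1: no failures possible
  expect_equal(dilation_pmf(3, 0, 1), 1)
  expect_equal(dilation_pmf(3, 2, 1), 0)
  # d = 1: geometric wait
  expect_equal(dilation_pmf(1, 0:2, 0.5), c(0.5, 0.25, 0.125))
  # d = 2, p = 0.9, e = 1: two arrangements of one failure
  expect_equal(dilation_pmf(2, 1, 0.9), 0.162)
  expect_error(dilation_pmf(0, 1, 0.5), "d")
  expect_error(dilation_pmf(2, -1, 0.5), "e")
})

test_that("dilation pmf sums to one with negligible tail mass", {
  for (d in c(1, 3, 7)) {
    for (p in c(0.5, 0.9, 0.99)) {
      e_max <- 2000
      expect_lt(abs(1 - sum(dilation_pmf(d, 0:e_max, p))), 1e-9)
    }
  }
})

test_that("sampled dilations have the negative-binomial mean d*q/p", {
  set.seed(101)
  labels <- tibble::tibble(position = 4L, channel = "K")
  p <- 0.8
  draws <- replicate(1e5, {
    apply_edman_dilation(labels, p, anchor_index = 10)$removal_cycle - 4
  })
  expected <- 4 * (1 - p) / p
  se <- sqrt(4 * (1 - p) / p^2 / 1e5)
  expect_lt(abs(mean(draws) - expected), 4 * se)
})

test_that("fluor survival is exponential in the cycle count", {
  set.seed(202)
  b <- halflife_to_decay_constant(20)
  n_draw <- 1e5
  t_bleach <- ceiling(rexp(n_draw, rate = b))
  for (k in c(1, 5, 20, 50)) {
    surv_hat <- mean(t_bleach > k)
    surv_exp <- exp(-b * k)
    se <- sqrt(surv_exp * (1 - surv_exp) / n_draw)
    expect_lt(abs(surv_hat - surv_exp), 5 * se)
  }
  # half-life definition: survival at k = h is exactly 1/2
  expect_equal(exp(-halflife_to_decay_constant(35) * 35), 0.5)
  expect_equal(halflife_to_decay_constant(Inf), 0)
  # minutes-to-cycles conversion: 30 min at 1 s/cycle = 1800 cycles
  expect_equal(error_params(half_life_minutes = 30)$half_life_cycles, 1800)
})

test_that("dye failure deletes labels independently, preserving order", {
  labels <- label_positions("GKEGK", "K")
  expect_equal(apply_dye_failure(labels, 0), labels)
  expect_equal(nrow(apply_dye_failure(labels, 1)), 0L)
  expect_error(apply_dye_failure(labels, 1.5), "\\[0, 1\\]")
  # deterministic single-event case: losing the first label turns the ideal
  # xKxxK read of GK*EGK* into xxxxK
  lost <- apply_dye_failure(labels, 0.5, fail = c(TRUE, FALSE))
  lost <- apply_edman_dilation(lost, 1, anchor_index = 5, dilation = 0L)
  fs <- apply_photobleaching(lost, 0, cycles = 6)
  expect_equal(fs_pattern(fs, 5), "xxxxK")
})

test_that("Edman dilation shifts removal cycles by interval sums", {
  labels <- label_positions("KEGK", "K")   # positions 1 and 4
  # zero dilation: removal cycle equals position
  ideal <- apply_edman_dilation(labels, 1, anchor_index = 4)
  expect_equal(ideal$removal_cycle, c(1, 4))
  # one failure before the first removal delays every later drop: xKxxK
  delayed <- apply_edman_dilation(labels, 0.9, anchor_index = 4,
                                  dilation = c(1L, 0L))
  expect_equal(delayed$removal_cycle, c(2, 5))
  fs <- apply_photobleaching(delayed, 0, cycles = 6)
  expect_equal(fs_pattern(fs, 5), "xKxxK")
  # labels beyond the anchor are never removed
  past <- apply_edman_dilation(label_positions("KCGK", "K"), 0.9,
                               anchor_index = 2, dilation = 0L)
  expect_equal(past$removal_cycle, c(1, Inf))
  expect_error(
    apply_edman_dilation(tibble::tibble(position = c(3L, 2L), channel = "K"),
                         0.9, 5),
    "strictly increasing")
})

test_that("removal cycles are strictly increasing before the anchor", {
  set.seed(7)
  labels <- label_positions("KAKAKAKAK", "K")
  for (i in 1:50) {
    rc <- apply_edman_dilation(labels, 0.7, anchor_index = 9)$removal_cycle
    expect_true(all(diff(rc) > 0))
    expect_true(all(rc >= labels$position))
  }
})

test_that("photobleaching shifts drops upstream and truncates at the budget", {
  labels <- apply_edman_dilation(label_positions("GKEGK", "K"), 1,
                                 anchor_index = 5)
  expect_equal(labels$removal_cycle, c(2, 5))
  # b = 0: drops exactly at the removal cycles
  expect_equal(fs_string(apply_photobleaching(labels, 0, 30)), "(K,2),(K,5)")
  # dye on the position-5 lysine bleaching in imaging cycle 3: xKKxx
  fs <- apply_photobleaching(labels, 0.1, 30, bleach_cycles = c(Inf, 3))
  expect_equal(fs_string(fs), "(K,2),(K,3)")
  expect_equal(fs_pattern(fs, 5), "xKKxx")
  # budget truncation
  fs2 <- apply_photobleaching(labels, 0.1, 2, bleach_cycles = c(Inf, 3))
  expect_equal(fs_string(fs2), "(K,2)")
  expect_error(apply_photobleaching(labels, -1, 30), ">= 0")
})

test_that("a label at or beyond the anchor can still bleach into a drop", {
  labels <- apply_edman_dilation(label_positions("KCAK", "K"), 1,
                                 anchor_index = 2, dilation = 0L)
  expect_equal(labels$removal_cycle, c(1, Inf))
  fs <- apply_photobleaching(labels, 0.05, 30, bleach_cycles = c(Inf, 4))
  expect_equal(fs_string(fs), "(K,1),(K,4)")
})

test_that("the zero-error pipeline reproduces ideal encodings exactly", {
  prot <- random_proteome(n = 10, len = 40, seed = 31)
  peps <- filter_by_anchor(digest(prot, "trypsin"), "cysteine")
  params0 <- error_params()
  for (i in seq_len(nrow(peps))) {
    set.seed(i)
    obs <- simulate_observed_fluorosequence(
      peps$peptide[i], "K+Y+W+DE", params0, cycles = 30,
      anchor_index = peps$anchor_index[i])
    ideal <- encode_ideal(peps$peptide[i], "K+Y+W+DE", 30,
                          anchor_index = peps$anchor_index[i])
    expect_equal(fs_string(obs), fs_string(ideal))
    set.seed(i)
    expect_equal(
      simulate_reads(peps$peptide[i], labeling_scheme("K+Y+W+DE"), params0,
                     30, depth = 4, anchor_index = peps$anchor_index[i]),
      rep(fs_string(ideal), 4))
  }
})

test_that("observed drops never occur later than the zero-photobleach removal", {
  set.seed(55)
  params <- error_params(dye_failure = 0, edman_efficiency = 0.85,
                         half_life_cycles = 15)
  labels <- label_positions("GKEGK", "K")
  for (i in 1:200) {
    dil <- apply_edman_dilation(labels, params$p, anchor_index = 5)
    fs <- apply_photobleaching(dil, params$b, cycles = 30)
    # every drop stems from a label whose (possibly infinite) removal cycle
    # is no earlier: min(removal, bleach) can only move drops upstream
    for (j in seq_len(nrow(fs))) {
      expect_true(any(dil$channel == fs$channel[j] &
                        dil$removal_cycle >= fs$cycle[j]))
    }
    expect_true(all(fs$cycle <= 30))
  }
})

test_that("simulation is deterministic for a fixed seed", {
  params <- error_params(0.2, 0.9, 20)
  set.seed(99)
  a <- simulate_reads("GKEGKAYWK", labeling_scheme("K+Y"), params, 30, 200)
  set.seed(99)
  b <- simulate_reads("GKEGKAYWK", labeling_scheme("K+Y"), params, 30, 200)
  expect_identical(a, b)
  set.seed(99)
  c1 <- simulate_observed_fluorosequence("GKEGKAYWK", "K+Y", params, 30)
  set.seed(99)
  c2 <- simulate_observed_fluorosequence("GKEGKAYWK", "K+Y", params, 30)
  expect_identical(fs_string(c1), fs_string(c2))
})

test_that("the single-molecule composition path matches exhaustive enumeration", {
  # modest-depth distributional check of the three-stage composition
  # (the bulk engine is checked at full depth in the acceptance suite)
  u <- 0.2; p <- 0.9; hl <- 20; n <- 6
  b <- halflife_to_decay_constant(hl)
  oracle <- enumerate_read_distribution("GKEGK", c(K = "K"), u, p, b, n)
  expect_lt(abs(1 - sum(oracle)), 1e-9)
  params <- error_params(u, p, hl)
  set.seed(17)
  n_rep <- 2e4
  reads <- vapply(seq_len(n_rep), function(i) {
    fs_string(simulate_observed_fluorosequence("GKEGK", "K", params, n))
  }, "")
  freq <- table(reads) / n_rep
  for (key in names(oracle)[oracle >= 0.005]) {
    p_true <- unname(oracle[match(key, names(oracle))])
    p_hat <- if (key %in% names(freq)) as.numeric(freq[match(key, names(freq))]) else 0
    tol <- 3.29 * sqrt(p_true * (1 - p_true) / n_rep) + 1 / n_rep
    expect_lt(abs(p_hat - p_true), tol)
  }
})
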