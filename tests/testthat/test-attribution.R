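toy_trie <- function() {
  tr <- attribution_trie()
  tr <- trie_insert(tr, "(K,2)", "X")
  tr <- trie_insert(tr, "(K,2),(K,4)", "Y")
  tr
}

test_that("insert creates nodes, counts repeats, and rejects disorder", {
  tr <- toy_trie()
  expect_equal(trie_total(tr), 2L)
  expect_equal(sort(unique(tr$counts$fs)), c("(K,2)", "(K,2),(K,4)"))

  # repeat insertion increments the count without new structure
  tr2 <- trie_insert(trie_insert(tr, "(K,2)", "X"), "(K,2)", "X")
  expect_equal(tr2$counts$n[tr2$counts$fs == "(K,2)"], 3L)
  expect_equal(nrow(tr2$counts), nrow(tr$counts))

  expect_error(trie_insert(tr, "(K,4),(K,2)", "X"), "canonical")

  # empty reads accumulate in the empty tally and are never attributable
  tr3 <- trie_insert(tr, "", "X")
  expect_equal(trie_total(tr3), 3L)
  expect_error(pmf_at(tr3, ""), "never attributable")
  expect_false("" %in% unique_attributions(tr3, 1, 0.5)$fs)
})

test_that("merge adds counts with the empty trie as identity", {
  a <- toy_trie()
  b <- trie_insert(trie_insert(attribution_trie(), "(K,2)", "Z"), "(K,3)", "Z")
  expect_equal(merge(a, attribution_trie())$counts, a$counts)
  ab <- merge(a, b)
  ba <- merge(b, a)
  expect_equal(dplyr::arrange(ab$counts, fs, protein_id),
               dplyr::arrange(ba$counts, fs, protein_id))
  expect_equal(trie_total(ab), trie_total(a) + trie_total(b))
  expect_equal(ab$counts$n[ab$counts$fs == "(K,2)" & ab$counts$protein_id == "Z"], 1L)
})

test_that("attribution pmfs normalize node counts", {
  tr <- attribution_trie(tibble::tibble(
    fs = c("(K,2)", "(K,2)"), protein_id = c("A", "B"), n = c(300L, 100L)))
  pmf <- pmf_at(tr, "(K,2)")
  expect_equal(pmf$probability, c(0.75, 0.25))
  expect_equal(pmf$protein_id, c("A", "B"))
  expect_equal(sum(pmf$probability), 1)
  expect_equal(attr(pmf, "total"), 400L)

  single <- pmf_at(attribution_trie(tibble::tibble(
    fs = "(K,2)", protein_id = "A", n = 100L)), "(K,2)")
  expect_equal(single$probability, 1)

  # unobserved read: a distinct signal, not an error
  expect_null(pmf_at(tr, "(Y,9)"))
})

test_that("unique attribution applies both thresholds", {
  tr <- attribution_trie(tibble::tibble(
    fs = c("(K,1)", "(K,1)", "(K,2)", "(K,2)", "(K,3)"),
    protein_id = c("A", "B", "A", "B", "A"),
    n = c(95L, 5L, 50L, 50L, 9L)))
  att <- unique_attributions(tr, min_count = 10, rival_fraction = 0.10)
  expect_equal(att$fs, "(K,1)")
  expect_equal(att$protein_id, "A")
  expect_equal(att$rival_share, 0.05)
  expect_error(unique_attributions(tr, 0, 0.1), "min_count")
  expect_error(unique_attributions(tr, 10, 0), "rival_fraction")
})

test_that("unique attributions are invariant to merge order", {
  set.seed(12)
  reads <- sprintf("(K,%d)", sample(1:5, 200, replace = TRUE))
  prots <- sample(c("A", "B", "C"), 200, replace = TRUE)
  whole <- fluorosim:::trie_from_reads(reads, prots)
  half1 <- fluorosim:::trie_from_reads(reads[1:100], prots[1:100])
  half2 <- fluorosim:::trie_from_reads(reads[101:200], prots[101:200])
  expect_equal(unique_attributions(merge(half1, half2), 1, 0.9),
               unique_attributions(merge(half2, half1), 1, 0.9))
  expect_equal(unique_attributions(merge(half1, half2), 1, 0.9),
               unique_attributions(whole, 1, 0.9))
})

test_that("zero-error simulation of the two-peptide mixture identifies both", {
  prot <- tibble::tibble(protein_id = c("X", "Y"),
                         sequence = c("GKEGC", "GKGKEC"))
  cfg <- simulation_config(prot, "none", "cysteine", "K",
                           cycles = 30, depth = 500, seed = 4,
                           min_count = 10)
  res <- run_monte_carlo(cfg)
  # exhaustive zero-error enumeration: X always reads (K,2), Y always
  # (K,2),(K,4); the shorter read is terminal only for X, so both are unique
  expect_equal(
    dplyr::arrange(res$trie$counts, fs),
    tibble::tibble(fs = c("(K,2)", "(K,2),(K,4)"),
                   protein_id = c("X", "Y"), n = c(500L, 500L)))
  expect_equal(res$coverage$fraction, 1.0)
  expect_equal(trie_total(res$trie), 2L * 500L)
})

test_that("indistinguishable paralogs are never identified", {
  prot <- tibble::tibble(protein_id = c("A", "B"),
                         sequence = c("GKEGC", "GKEGC"))
  cfg <- simulation_config(prot, "none", "cysteine", "K",
                           cycles = 30, depth = 100, seed = 1, min_count = 1)
  res <- run_monte_carlo(cfg)
  expect_equal(res$coverage$fraction, 0)

  solo <- simulation_config(prot[1, ], "none", "cysteine", "K",
                            cycles = 30, depth = 100, seed = 1, min_count = 1)
  expect_equal(run_monte_carlo(solo)$coverage$fraction, 1.0)
})

test_that("count conservation holds: total observations = depth * peptides", {
  prot <- random_proteome(n = 4, len = 30, seed = 8)
  cfg <- simulation_config(prot, "gluc", "c_terminus", "K+Y",
                           cycles = 10, depth = 50, seed = 2, min_count = 1,
                           params = error_params(0.3, 0.9, 10))
  res <- run_monte_carlo(cfg)
  expect_equal(trie_total(res$trie), res$n_peptides * 50L)
})

test_that("coverage requires a non-empty proteome", {
  expect_error(
    proteome_coverage(attribution_trie(),
                      tibble::tibble(protein_id = character(),
                                     sequence = character())),
    "non-empty")
})

test_that("trie serialization round-trips through the text format", {
  tr <- trie_insert(toy_trie(), "", "X", n = 3L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_trie(tr, tf)
  back <- read_trie(tf)
  expect_equal(dplyr::arrange(back$counts, fs, protein_id),
               dplyr::arrange(tr$counts, fs, protein_id))
  expect_equal(trie_total(back), trie_total(tr))
  # gzip variant
  tgz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_trie(tr, tgz)
  expect_equal(trie_total(read_trie(tgz)), trie_total(tr))
})
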