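make_cm <- function(input, output, other = NULL) {
  ids <- rownames(input)
  reps <- colnames(input)
  arr <- array(0, dim = c(nrow(input), ncol(input), 2L),
               dimnames = list(ids, reps, c("input", "output")))
  arr[, , "input"] <- input
  arr[, , "output"] <- output
  count_matrix(arr, other)
}

test_that("frequencies divide by the channel total including the lumped bin", {
  input <- matrix(c(50, 30, 50, 30), 2L, dimnames = list(c("wt", "3A>C"),
                                                         c("rep1", "rep2")))
  output <- input
  other <- matrix(20, 2L, 2L, dimnames = list(c("rep1", "rep2"),
                                              c("input", "output")))
  ft <- frequencies(make_cm(input, output, other))
  expect_equal(unname(ft$freq["wt", "rep1", "input"]), 0.5)
  expect_equal(unname(ft$freq["3A>C", "rep1", "input"]), 0.3)
  # conservation: retained variants plus the lumped bin sum to exactly 1
  expect_equal(sum(ft$freq[, "rep1", "input"]) + 20 / 100, 1)
  # absent variant has frequency zero
  input2 <- rbind(input, "5C>T" = c(0, 0))
  ft2 <- frequencies(make_cm(input2, rbind(output, "5C>T" = c(1, 1))))
  expect_equal(unname(ft2$freq["5C>T", "rep1", "input"]), 0)
  expect_error(frequencies(make_cm(input * 0, output)), "empty channel")
})

test_that("wild type scores exactly zero and ratio doubling scores one", {
  input <- matrix(100, 2L, 3L,
                  dimnames = list(c("wt", "2G>A"), paste0("rep", 1:3)))
  output <- matrix(c(100, 200), 2L, 3L, dimnames = dimnames(input))
  sc <- enrichment_scores(frequencies(make_cm(input, output)),
                          min_input_reads = 1)
  expect_equal(sc["wt", "es"], 0)
  expect_equal(sc["2G>A", "es"], 1)
  expect_equal(unname(rep_es_matrix(sc)["2G>A", ]), rep(1, 3L))
})

test_that("the score is the ratio of median frequencies, not the median ratio", {
  # frequencies chosen so the two orders of operations disagree
  input <- matrix(c(100, 100, 100, 10, 40, 90), 2L, 3L, byrow = TRUE,
                  dimnames = list(c("wt", "4T>G"), paste0("rep", 1:3)))
  output <- matrix(c(100, 100, 100, 80, 20, 45), 2L, 3L, byrow = TRUE,
                   dimnames = dimnames(input))
  cm <- make_cm(input, output)
  ft <- frequencies(cm)
  sc <- enrichment_scores(ft, min_input_reads = 1)
  fi_med <- median(ft$freq["4T>G", , "input"])
  fo_med <- median(ft$freq["4T>G", , "output"])
  wt_term <- log2(median(ft$freq["wt", , "output"]) /
                    median(ft$freq["wt", , "input"]))
  expect_equal(sc["4T>G", "es"], log2(fo_med / fi_med) - wt_term)
  med_ratio <- median(ft$freq["4T>G", , "output"] / ft$freq["4T>G", , "input"])
  expect_false(isTRUE(all.equal(sc["4T>G", "es"],
                                log2(med_ratio) - wt_term)))
})

test_that("scaling any channel's counts leaves every score unchanged", {
  cfg <- small_config(seed = 3L)
  truth <- build_truth(cfg)
  cm <- simulate_counts(truth)
  sc0 <- enrichment_scores(frequencies(cm), min_input_reads = 0)
  scaled <- cm
  scaled$counts[, , "input"] <- scaled$counts[, , "input"] * 7
  scaled$other[, "input"] <- scaled$other[, "input"] * 7
  sc1 <- enrichment_scores(frequencies(scaled), min_input_reads = 0)
  expect_equal(sc1$es, sc0$es)
  # single-replicate rescaling too
  scaled2 <- cm
  scaled2$counts[, 2L, "output"] <- scaled2$counts[, 2L, "output"] * 3
  scaled2$other[2L, "output"] <- scaled2$other[2L, "output"] * 3
  sc2 <- enrichment_scores(frequencies(scaled2), min_input_reads = 0)
  expect_equal(sc2$es, sc0$es)
})

test_that("scores are invariant to replicate permutation", {
  cfg <- small_config(seed = 6L)
  cm <- simulate_counts(build_truth(cfg))
  sc0 <- enrichment_scores(frequencies(cm))
  perm <- cm
  perm$counts <- perm$counts[, c(3L, 1L, 2L), ]
  perm$other <- perm$other[c(3L, 1L, 2L), ]
  sc1 <- enrichment_scores(frequencies(perm))
  expect_equal(sc1$es, sc0$es)
})

test_that("zero frequencies and low coverage flag variants unquantified", {
  input <- matrix(c(100, 100, 100, 20, 20, 20, 2, 3, 2), 3L, 3L, byrow = TRUE,
                  dimnames = list(c("wt", "1G>T", "2G>A"), paste0("rep", 1:3)))
  output <- matrix(c(100, 100, 100, 0, 0, 0, 5, 5, 5), 3L, 3L, byrow = TRUE,
                   dimnames = dimnames(input))
  sc <- enrichment_scores(frequencies(make_cm(input, output)),
                          min_input_reads = 10)
  expect_false(sc["1G>T", "quantified"])  # zero output frequency
  expect_true(is.na(sc["1G>T", "es"]))
  expect_false(sc["2G>A", "quantified"])  # median input 2 < 10
  # a pseudocount rescues the zero-output variant
  sc_pc <- enrichment_scores(frequencies(make_cm(input, output)),
                             min_input_reads = 1, pseudocount = 0.5)
  expect_true(sc_pc["1G>T", "quantified"])
  expect_true(is.finite(sc_pc["1G>T", "es"]))
})

test_that("an unquantifiable wild type is fatal", {
  input <- matrix(c(100, 100, 100, 50, 50, 50), 2L, 3L, byrow = TRUE,
                  dimnames = list(c("wt", "1G>T"), paste0("rep", 1:3)))
  output <- matrix(c(0, 100, 100, 50, 50, 50), 2L, 3L, byrow = TRUE,
                   dimnames = dimnames(input))
  expect_error(enrichment_scores(frequencies(make_cm(input, output))),
               "wild type unquantifiable")
})

test_that("noiseless expected counts reproduce the PSI oracle to 1e-9", {
  cfg <- small_config(L = 8L, neutral_fraction = 0.25, n_epistatic = 5L,
                      eps_magnitude = 0.8, seed = 12L)
  truth <- build_truth(cfg)
  sc <- noiseless_scores(truth, min_input_reads = 0)
  oracle <- log2(truth$psi / truth$psi[["wt"]])
  expect_lt(max(abs(sc$es - oracle[sc$variant_id])), 1e-9)
})

test_that("score tables round-trip through TSV", {
  cfg <- small_config(seed = 2L)
  sc <- enrichment_scores(frequencies(simulate_counts(build_truth(cfg))))
  path <- tempfile(fileext = ".tsv")
  write_scores(sc, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(sc))
  expect_equal(back$es, sc$es, tolerance = 1e-12)
  unlink(path)
})
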