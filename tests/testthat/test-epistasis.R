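make_classes <- function(ids, classes) {
  structure(data.frame(variant_id = ids, class = classes),
            class = c("classified_variants", "data.frame"))
}

test_that("additive data fit with slope 1, intercept 0, R2 = 1 and zero residuals", {
  cfg <- small_config(L = 8L, neutral_fraction = 0.3, effect_mean = -0.4,
                      effect_sd = 0.3, seed = 23L)
  truth <- build_truth(cfg)
  sc <- noiseless_scores(truth, min_input_reads = 0)
  fit <- fit_linear_expectation(sc)
  expect_equal(fit$coefs$slope, rep(1, 3L), tolerance = 1e-9)
  expect_equal(fit$coefs$intercept, rep(0, 3L), tolerance = 1e-9)
  expect_equal(fit$coefs$r2, rep(1, 3L), tolerance = 1e-9)
  expect_equal(fit$pooled_r2, 1, tolerance = 1e-9)
  epi <- epistasis_scores(fit)
  expect_lt(max(abs(epi$E)), 1e-9)
})

test_that("an exactly planted line is recovered to machine precision", {
  cfg <- small_config(L = 8L, neutral_fraction = 0, effect_sd = 0.4, seed = 24L)
  sc <- noiseless_scores(build_truth(cfg), min_input_reads = 0)
  S <- dmsplice:::rep_es_matrix(sc)
  doubles <- sc$variant_id[sc$n_mutations == 2L]
  comp <- strsplit(doubles, ",", fixed = TRUE)
  sums <- S[vapply(comp, `[`, "", 1L), ] + S[vapply(comp, `[`, "", 2L), ]
  planted <- 0.3 + 0.5 * sums
  cols <- grep("^rep_es_", names(sc))
  sc[doubles, cols] <- planted
  sc[doubles, "es"] <- rowMeans(planted)
  fit <- fit_linear_expectation(sc)
  expect_equal(fit$coefs$slope, rep(0.5, 3L), tolerance = 1e-9)
  expect_equal(fit$coefs$intercept, rep(0.3, 3L), tolerance = 1e-9)
})

test_that("observed always equals predicted plus residual, and E is the row median", {
  cfg <- small_config(L = 6L, seed = 25L, n_input = 2e5, n_output = 2e5)
  sc <- enrichment_scores(frequencies(simulate_counts(build_truth(cfg))),
                          min_input_reads = 5)
  fit <- fit_linear_expectation(sc)
  epi <- epistasis_scores(fit)
  resid <- attr(epi, "obs") - attr(epi, "pred")
  expect_equal(attr(epi, "obs"), attr(epi, "pred") + resid)
  expect_equal(epi$E, unname(apply(resid, 1L, median, na.rm = TRUE)))
  expect_equal(median(c(-0.2, 0.1, 0.4)), 0.1)  # the E of such residuals
})

test_that("a planted interaction on an additive background is recovered", {
  ref <- make_test_ref(8L)
  v <- enumerate_variants(ref, 2L)
  pair <- v[v$n_mutations == 2L, ][17L, ]
  ida <- mutation_id(pair$pos1, pair$ref1, pair$alt1)
  idb <- mutation_id(pair$pos2, pair$ref2, pair$alt2)
  cfg <- small_config(L = 8L, neutral_fraction = 0.4, effect_mean = -0.6,
                      effect_sd = 0.3, seed = 26L,
                      eps_pairs = data.frame(id_a = ida, id_b = idb, eps = 1.5))
  truth <- build_truth(cfg)
  sc <- noiseless_scores(truth, min_input_reads = 0)
  epi <- epistasis_scores(fit_linear_expectation(sc))
  expect_equal(epi[pair$variant_id, "E"], 1.5, tolerance = 0.05)
  expect_lt(median(abs(epi$E)), 0.02)
})

test_that("variance explained decreases as planted interactions grow", {
  ref <- make_test_ref(8L)
  v <- enumerate_variants(ref, 2L)
  pairs <- v[v$n_mutations == 2L, ][seq(1L, 240L, by = 8L), ]
  r2 <- vapply(c(0.5, 1, 2), function(mag) {
    eps_df <- data.frame(
      id_a = mutation_id(pairs$pos1, pairs$ref1, pairs$alt1),
      id_b = mutation_id(pairs$pos2, pairs$ref2, pairs$alt2),
      eps = rep(c(mag, -mag), length.out = nrow(pairs)))
    cfg <- small_config(L = 8L, neutral_fraction = 0.3, effect_sd = 0.4,
                        seed = 27L, eps_pairs = eps_df)
    fit_linear_expectation(noiseless_scores(build_truth(cfg),
                                            min_input_reads = 0))$pooled_r2
  }, 0)
  expect_true(all(diff(r2) < 0))
  expect_lt(r2[3L], 1)
})

test_that("the paired test matches t.test and handles degenerate residuals", {
  set.seed(31)
  n_pairs <- 12L
  obs <- matrix(rnorm(n_pairs * 3L), n_pairs, 3L)
  pred <- obs + matrix(rnorm(n_pairs * 3L, sd = 0.5), n_pairs, 3L)
  epi <- data.frame(pair_id = sprintf("p%d", 1:n_pairs),
                    single_a = "1A>C", single_b = "2A>C",
                    E = apply(obs - pred, 1L, median), distance = 1L)
  attr(epi, "obs") <- obs
  attr(epi, "pred") <- pred
  class(epi) <- c("epistasis_table", "data.frame")
  tested <- test_epistasis(epi)
  for (i in seq_len(n_pairs)) {
    expect_equal(tested$p_value[i],
                 t.test(obs[i, ], pred[i, ], paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # degenerate rows: zero-variance differences
  obs2 <- rbind(c(1, 1, 1), c(2, 2, 2))
  pred2 <- rbind(c(1, 1, 1), c(1, 1, 1))
  epi2 <- data.frame(pair_id = c("a", "b"), single_a = "1A>C",
                     single_b = "2A>C", E = c(0, 1), distance = 1L)
  attr(epi2, "obs") <- obs2
  attr(epi2, "pred") <- pred2
  class(epi2) <- c("epistasis_table", "data.frame")
  t2 <- test_epistasis(epi2)
  expect_equal(t2$p_value, c(1, 0))
  expect_true(all(t2$degenerate))
  expect_equal(t2$sign_class, c("none", "positive"))
})

test_that("network families partition pairs and FDR is applied per family", {
  cfg <- small_config(L = 8L, neutral_fraction = 0.5, seed = 28L,
                      n_input = 5e5, n_output = 5e5)
  truth <- build_truth(cfg)
  sc <- enrichment_scores(frequencies(simulate_counts(truth)),
                          min_input_reads = 5)
  cl <- classify_variants(sc)
  epi <- test_epistasis(epistasis_scores(fit_linear_expectation(sc)), cl)
  neutral <- cl$variant_id[cl$class == "N"]
  n_in <- (epi$single_a %in% neutral) + (epi$single_b %in% neutral)
  expect_true(all(epi$network_family == c("XxX", "NxX", "NxN")[n_in + 1L]))
  for (f in unique(epi$network_family)) {
    idx <- epi$network_family == f
    expect_equal(epi$fdr[idx], bh_fdr(epi$p_value[idx]))
  }
})

test_that("E is invariant to replicate relabeling", {
  cfg <- small_config(L = 6L, seed = 29L, n_input = 2e5, n_output = 2e5)
  cm <- simulate_counts(build_truth(cfg))
  go <- function(x) {
    sc <- enrichment_scores(frequencies(x), min_input_reads = 5)
    epistasis_scores(fit_linear_expectation(sc))
  }
  e1 <- go(cm)
  perm <- cm
  perm$counts <- perm$counts[, c(2L, 3L, 1L), ]
  perm$other <- perm$other[c(2L, 3L, 1L), ]
  e2 <- go(perm)
  expect_equal(e2[e1$pair_id, "E"], e1$E)
})

test_that("network metrics find planted hubs and report distances", {
  hub <- "5A>C"
  others <- sprintf("%d%s", c(1:4, 6:16), "G>T")
  epi <- data.frame(pair_id = paste(hub, others, sep = ","),
                    single_a = hub, single_b = others,
                    E = 1, distance = abs(5L - c(1:4, 6:16)),
                    p_value = 0.001, fdr = 0.001,
                    network_family = "NxN",
                    sign_class = "positive", degenerate = FALSE)
  # plus a layer of non-significant pairs among the others
  extra <- data.frame(pair_id = paste(others[1:10], others[2:11], sep = ","),
                      single_a = others[1:10], single_b = others[2:11],
                      E = 0, distance = 1L, p_value = 0.9, fdr = 0.9,
                      network_family = "NxN", sign_class = "none",
                      degenerate = FALSE)
  both <- rbind(epi, extra)
  class(both) <- c("epistasis_table", "data.frame")
  nm <- network_metrics(both)
  deg <- setNames(nm$degrees$degree, nm$degrees$mutation_id)
  expect_equal(unname(deg[hub]), 15L)
  expect_equal(max(deg), deg[[hub]])
  expect_true(hub %in% nm$hubs)
  expect_equal(nm$n_significant, 15L)
  # a pair at positions 10 and 12 is 2 nt apart
  expect_equal(both$distance[both$pair_id == paste(hub, "7G>T", sep = ",")], 2L)

  none <- extra
  class(none) <- c("epistasis_table", "data.frame")
  nm0 <- network_metrics(none)
  expect_true(all(nm0$degrees$degree == 0L))
  expect_length(nm0$hubs, 0L)
})
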