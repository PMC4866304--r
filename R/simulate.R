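#' Configuration for the doped-library simulator
#'
#' Defaults reproduce the FAS exon 6 study conditions: 1.2\% doping per
#' alternative base per position over a 63-nt exon, three biological
#' replicates, an input channel deep enough to give a median single-mutant
#' coverage around 16,000 reads, an output (spliced) channel of 4.2 million
#' reads, and wild-type inclusion of 50\%. The fraction of exactly-neutral
#' single effects defaults to 73/189 and the remaining effects are drawn from
#' a normal distribution with negative mean, so the simulated landscape is
#' skewed towards increased skipping.
#'
#' @param ref An `exon_reference` (default the FAS exon 6 design).
#' @param doping_rate Doping rate `d` per alternative base per position.
#' @param replicates Number of biological replicates (>= 2).
#' @param n_input,n_output Total reads per replicate in each channel.
#' @param psi_wt Wild-type percent spliced in (0-100).
#' @param psi_min Floor applied to simulated PSI values, in percent; keeps
#'   output-channel probabilities positive so log-ratios stay defined.
#' @param psi_other PSI assigned to the lumped >2-mutation bin (default
#'   `psi_wt`).
#' @param neutral_fraction Fraction of single mutations with a true effect of
#'   exactly zero.
#' @param effect_mean,effect_sd Normal distribution of the non-zero single
#'   effects, in log2 inclusion-ratio units.
#' @param n_epistatic Number of variant pairs given a non-zero interaction.
#' @param eps_magnitude Interaction sizes: a single positive number (each
#'   planted pair gets that magnitude with random sign) or a vector of signed
#'   values recycled across the planted pairs.
#' @param eps_pairs Optional explicit data.frame (`id_a`, `id_b`, `eps`) of
#'   interactions; overrides `n_epistatic`/`eps_magnitude`.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(ref = fas_reference(),
                              doping_rate = 0.012,
                              replicates = 3L,
                              n_input = 1.3e7,
                              n_output = 4.2e6,
                              psi_wt = 50,
                              psi_min = 0.1,
                              psi_other = psi_wt,
                              neutral_fraction = 73 / 189,
                              effect_mean = -0.5,
                              effect_sd = 0.75,
                              n_epistatic = 0L,
                              eps_magnitude = 1,
                              eps_pairs = NULL,
                              seed = 1L) {
  stopifnot(inherits(ref, "exon_reference"),
            doping_rate > 0, 3 * doping_rate < 1,
            replicates >= 2, n_input >= 1, n_output >= 1,
            psi_wt > 0, psi_wt <= 100, psi_min > 0, psi_min < psi_wt,
            psi_other > 0, psi_other <= 100,
            neutral_fraction >= 0, neutral_fraction <= 1,
            effect_sd >= 0, n_epistatic >= 0, length(seed) == 1L)
  if (!is.null(eps_pairs)) {
    stopifnot(is.data.frame(eps_pairs),
              all(c("id_a", "id_b", "eps") %in% names(eps_pairs)))
  }
  structure(list(ref = ref, doping_rate = doping_rate,
                 replicates = as.integer(replicates),
                 n_input = n_input, n_output = n_output,
                 psi_wt = psi_wt, psi_min = psi_min, psi_other = psi_other,
                 neutral_fraction = neutral_fraction,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 n_epistatic = as.integer(n_epistatic),
                 eps_magnitude = eps_magnitude, eps_pairs = eps_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

clip_psi <- function(psi, psi_min) pmin(pmax(psi, psi_min), 100)

#' Generate a ground-truth splicing landscape
#'
#' Draws latent single-mutation effects (a configurable fraction exactly
#' zero, the rest normal with negative mean) and sparse pairwise
#' interactions, then assigns every variant v the inclusion level
#' `PSI(v) = clip(psi_wt * 2^(sum of single effects + pair interaction),
#' psi_min, 100)`. Interactions are planted only on pairs whose resulting
#' PSI stays strictly inside the dynamic range, since a clipped PSI cannot
#' express the interaction.
#'
#' @param config A `sim_config`.
#' @return An object of class `landscape_truth` with the variant table,
#'   `single_effects` (named by mutation id), the interaction table `eps`,
#'   and `psi` (named by variant id, in percent).
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  variants <- enumerate_variants(config$ref, 2L)
  singles <- variants[variants$n_mutations == 1L, ]
  n_s <- nrow(singles)
  effects <- stats::setNames(numeric(n_s), singles$variant_id)
  n_neutral <- round(config$neutral_fraction * n_s)
  nonzero <- setdiff(seq_len(n_s), sample.int(n_s, n_neutral))
  effects[nonzero] <- stats::rnorm(length(nonzero), config$effect_mean,
                                   config$effect_sd)

  doubles <- variants[variants$n_mutations == 2L, ]
  id1 <- mutation_id(doubles$pos1, doubles$ref1, doubles$alt1)
  id2 <- mutation_id(doubles$pos2, doubles$ref2, doubles$alt2)
  base2 <- effects[id1] + effects[id2]

  eps_tab <- data.frame(variant_id = character(), id_a = character(),
                        id_b = character(), eps = numeric())
  if (!is.null(config$eps_pairs)) {
    ep <- config$eps_pairs
    pid <- vapply(seq_len(nrow(ep)), function(i) {
      ma <- parse_variant_id(ep$id_a[i]); mb <- parse_variant_id(ep$id_b[i])
      variant_id_from_mutations(c(ma$pos, mb$pos), c(ma$ref, mb$ref),
                                c(ma$alt, mb$alt))
    }, "")
    if (!all(pid %in% doubles$variant_id)) stop("eps_pairs contains unknown pairs")
    eps_tab <- data.frame(variant_id = pid, id_a = ep$id_a, id_b = ep$id_b,
                          eps = ep$eps)
  } else if (config$n_epistatic > 0L) {
    vals <- rep_len(config$eps_magnitude, config$n_epistatic)
    if (length(config$eps_magnitude) == 1L) {
      vals <- vals * sample(c(-1, 1), config$n_epistatic, replace = TRUE)
    }
    chosen <- integer(0)
    for (v in vals) {
      lat <- config$psi_wt * 2^(base2 + v)
      ok <- which(lat > config$psi_min & lat < 100)
      ok <- setdiff(ok, chosen)
      if (!length(ok)) {
        stop("config error: requested epistatic pairs exceed the pairs available ",
             "within the PSI dynamic range")
      }
      chosen <- c(chosen, if (length(ok) == 1L) ok else sample(ok, 1L))
    }
    eps_tab <- data.frame(variant_id = doubles$variant_id[chosen],
                          id_a = id1[chosen], id_b = id2[chosen], eps = vals)
  }

  eps_full <- stats::setNames(numeric(nrow(doubles)), doubles$variant_id)
  eps_full[eps_tab$variant_id] <- eps_tab$eps
  e_total <- c(stats::setNames(0, "wt"), effects, base2 + eps_full)
  names(e_total) <- variants$variant_id
  psi <- clip_psi(config$psi_wt * 2^e_total, config$psi_min)

  structure(list(ref = config$ref, variants = variants,
                 psi_wt = config$psi_wt, single_effects = effects,
                 eps = eps_tab, psi = psi, config = config),
            class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat(sprintf("landscape_truth: %d variants, psi_wt = %g%%\n",
              nrow(x$variants), x$psi_wt))
  cat(sprintf("  %d/%d single effects exactly zero; %d epistatic pairs\n",
              sum(x$single_effects == 0), length(x$single_effects), nrow(x$eps)))
  invisible(x)
}

sim_class_probs <- function(truth) {
  config <- truth$config
  L <- nchar(truth$ref$exon)
  comp <- doping_composition(config$doping_rate, L)
  nm <- truth$variants$n_mutations
  p <- numeric(nrow(truth$variants))
  p[nm == 0L] <- comp[["p_wt"]]
  p[nm == 1L] <- comp[["p_single"]] / sum(nm == 1L)
  p[nm == 2L] <- comp[["p_double"]] / sum(nm == 2L)
  list(variant = stats::setNames(p, truth$variants$variant_id),
       other = 1 - sum(comp))
}

sim_output_probs <- function(truth, p_in) {
  w <- p_in$variant * truth$psi[names(p_in$variant)]
  w_other <- p_in$other * truth$config$psi_other
  z <- sum(w) + w_other
  list(variant = w / z, other = w_other / z)
}

#' Simulate sequencing counts from a landscape
#'
#' Input-channel counts per replicate are multinomial over the variant
#' universe with class probabilities from [doping_composition()] spread
#' uniformly within each mutation class, plus a lumped bin for >2-mutation
#' molecules. Output-channel probabilities are proportional to input
#' frequency times PSI: the assay sequences the inclusion band, so a
#' variant's representation there scales with its inclusion level.
#'
#' @param truth A `landscape_truth`.
#' @param seed Integer seed (default the config seed).
#' @return A `count_matrix`.
#' @export
simulate_counts <- function(truth, seed = truth$config$seed) {
  stopifnot(inherits(truth, "landscape_truth"))
  config <- truth$config
  set.seed(seed)
  p_in <- sim_class_probs(truth)
  p_out <- sim_output_probs(truth, p_in)
  ids <- truth$variants$variant_id
  reps <- paste0("rep", seq_len(config$replicates))
  arr <- array(0, dim = c(length(ids), length(reps), 2L),
               dimnames = list(ids, reps, c("input", "output")))
  other <- matrix(0, length(reps), 2L,
                  dimnames = list(reps, c("input", "output")))
  for (r in seq_along(reps)) {
    d_in <- stats::rmultinom(1L, config$n_input, c(p_in$variant, p_in$other))
    d_out <- stats::rmultinom(1L, config$n_output, c(p_out$variant, p_out$other))
    n <- length(ids)
    arr[, r, "input"] <- d_in[seq_len(n), 1L]
    arr[, r, "output"] <- d_out[seq_len(n), 1L]
    other[r, ] <- c(d_in[n + 1L, 1L], d_out[n + 1L, 1L])
  }
  count_matrix(arr, other)
}

#' Expected (noise-free) counts under the selection model
#'
#' Returns the exact expected counts rather than a multinomial draw, identical
#' across replicates. On these counts the enrichment pipeline recovers
#' `ES(v) = log2(PSI(v) / PSI(wt))` exactly, which is the closed-form oracle
#' used to validate the scoring stages.
#'
#' @param truth A `landscape_truth`.
#' @return A `count_matrix` with non-integer expected counts.
#' @export
expected_counts <- function(truth) {
  stopifnot(inherits(truth, "landscape_truth"))
  config <- truth$config
  p_in <- sim_class_probs(truth)
  p_out <- sim_output_probs(truth, p_in)
  ids <- truth$variants$variant_id
  reps <- paste0("rep", seq_len(config$replicates))
  arr <- array(0, dim = c(length(ids), length(reps), 2L),
               dimnames = list(ids, reps, c("input", "output")))
  other <- matrix(0, length(reps), 2L,
                  dimnames = list(reps, c("input", "output")))
  for (r in seq_along(reps)) {
    arr[, r, "input"] <- config$n_input * p_in$variant
    arr[, r, "output"] <- config$n_output * p_out$variant
    other[r, ] <- c(config$n_input * p_in$other, config$n_output * p_out$other)
  }
  count_matrix(arr, other)
}

other_bin_sequence <- function(ref) {
  # deterministic carrier for the >2-mutation bin: first three exon positions
  # substituted by the next base in A->C->G->T->A order
  exon <- strsplit(ref$exon, "")[[1L]]
  alt <- DNA_BASES[match(exon[1:3], DNA_BASES) %% 4L + 1L]
  paste0(ref$flank5, apply_mutations(ref, 1:3, alt), ref$flank3)
}

#' Write simulated counts as FASTQ reads
#'
#' Emits each variant's full amplicon (5' flank + mutated exon + 3' flank)
#' count-many times with uniform Phred quality, one FASTQ per (replicate,
#' channel). Reads in the >2-mutation bin are emitted as a fixed triple
#' mutant so that re-counting the files reproduces the `count_matrix`
#' exactly, lumped bin included.
#'
#' @param counts A `count_matrix` with whole-number counts.
#' @param ref The `exon_reference` the counts were simulated from.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a sample sheet data.frame (`path`, `replicate`,
#'   `channel`) suitable for [count_reads()].
#' @export
write_reads <- function(counts, ref, dir, prefix = "sim") {
  stopifnot(inherits(counts, "count_matrix"), inherits(ref, "exon_reference"))
  if (any(counts$counts != round(counts$counts)) || any(counts$other != round(counts$other))) {
    stop("write_reads needs whole-number counts")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- dimnames(counts$counts)[[1L]]
  seqs <- vapply(ids, function(id) {
    m <- parse_variant_id(id)
    paste0(ref$flank5, apply_mutations(ref, m$pos, m$alt), ref$flank3)
  }, "")
  other_seq <- other_bin_sequence(ref)
  sheet <- expand.grid(replicate = dimnames(counts$counts)[[2L]],
                       channel = c("input", "output"),
                       stringsAsFactors = FALSE)
  sheet$path <- file.path(dir, sprintf("%s_%s_%s.fastq", prefix,
                                       sheet$replicate, sheet$channel))
  for (i in seq_len(nrow(sheet))) {
    n <- counts$counts[, sheet$replicate[i], sheet$channel[i]]
    reads <- c(rep(seqs, n),
               rep(other_seq, counts$other[sheet$replicate[i], sheet$channel[i]]))
    dna <- Biostrings::DNAStringSet(reads)
    if (length(dna)) {
      names(dna) <- sprintf("r%06d", seq_along(dna))
      qual <- Biostrings::PhredQuality(
        vapply(Biostrings::width(dna), function(w) strrep("I", w), ""))
    } else {
      names(dna) <- character(0)
      qual <- Biostrings::PhredQuality(character(0))
    }
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(dna, qual), sheet$path[i])
  }
  invisible(sheet[, c("path", "replicate", "channel")])
}
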