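#' Variant frequencies per replicate and channel
#'
#' Frequencies are counts divided by the channel total of all accepted reads,
#' including the lumped >2-mutation bin — molecules with many substitutions
#' are never scored but do dilute everything else, so they belong in the
#' denominator.
#'
#' @param counts A `count_matrix`.
#' @return An object of class `frequency_table` holding the frequency array
#'   (`variants x replicates x channel`), the originating counts and the
#'   channel totals.
#' @export
frequencies <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  tot <- channel_totals(counts)
  if (any(tot <= 0)) stop("empty channel: every (replicate, channel) needs reads")
  freq <- counts$counts
  for (ch in c("input", "output")) {
    m <- matrix(counts$counts[, , ch], ncol = dim(counts$counts)[2L])
    freq[, , ch] <- sweep(m, 2L, tot[, ch], "/")
  }
  structure(list(freq = freq, counts = counts, totals = tot),
            class = "frequency_table")
}

#' Wild-type-normalised enrichment scores
#'
#' For each variant the median frequency across replicates is taken in the
#' input and output channels; the enrichment score is
#' `ES(v) = log2(median fo / median fi) - log2(median fo(wt) / median fi(wt))`,
#' so the wild type scores exactly 0. Per-replicate non-normalised
#' enrichments `log2(fo/fi)` and their wild-type-normalised counterparts are
#' retained for the replicate-level statistics; the reported `variance` is
#' the sample variance of the per-replicate normalised scores.
#'
#' Variants whose median input coverage falls below `min_input_reads`, or for
#' which any frequency entering the score is zero, are reported with
#' `quantified = FALSE` and an `NA` score — no pseudocounts are added unless
#' requested.
#'
#' @param ft A `frequency_table` (or a `count_matrix`, converted internally).
#' @param min_input_reads Minimum median input reads to score a variant.
#' @param pseudocount Added to every per-variant count before frequencies are
#'   formed (default 0; a sensitivity-analysis knob, not part of the scoring
#'   definition).
#' @return A data.frame of class `enrichment_table` with one row per variant:
#'   `variant_id`, `n_mutations`, `es`, per-replicate `rep_es_*` and
#'   `rep_enr_*` columns, `variance`, `median_input`, `quantified`.
#' @export
enrichment_scores <- function(ft, min_input_reads = 10, pseudocount = 0) {
  if (inherits(ft, "count_matrix")) ft <- frequencies(ft)
  stopifnot(inherits(ft, "frequency_table"))
  cm <- ft$counts
  freq <- ft$freq
  if (pseudocount > 0) {
    for (ch in c("input", "output")) {
      m <- matrix(cm$counts[, , ch], ncol = dim(cm$counts)[2L]) + pseudocount
      freq[, , ch] <- sweep(m, 2L, ft$totals[, ch], "/")
    }
  }
  ids <- dimnames(freq)[[1L]]
  if (!"wt" %in% ids) stop("wild type absent from the count matrix")
  reps <- dimnames(freq)[[2L]]
  fi <- matrix(freq[, , "input"], ncol = length(reps), dimnames = list(ids, reps))
  fo <- matrix(freq[, , "output"], ncol = length(reps), dimnames = list(ids, reps))
  fi_med <- apply(fi, 1L, stats::median)
  fo_med <- apply(fo, 1L, stats::median)
  if (fi_med[["wt"]] <= 0 || fo_med[["wt"]] <= 0 ||
      any(fi["wt", ] <= 0) || any(fo["wt", ] <= 0)) {
    stop("wild type unquantifiable: normalization impossible")
  }
  wt_raw <- log2(fo_med[["wt"]] / fi_med[["wt"]])
  es <- log2(fo_med / fi_med) - wt_raw

  rep_enr <- log2(fo / fi)
  rep_enr[!is.finite(rep_enr)] <- NA_real_
  rep_es <- sweep(rep_enr, 2L, rep_enr["wt", ], "-")

  counts_in <- matrix(cm$counts[, , "input"], ncol = length(reps))
  med_in <- apply(counts_in, 1L, stats::median)
  quantified <- med_in >= min_input_reads & fi_med > 0 & fo_med > 0
  es[!quantified] <- NA_real_
  variance <- apply(rep_es, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::var(v)
  })

  out <- data.frame(
    variant_id = ids,
    n_mutations = ifelse(ids == "wt", 0L, lengths(strsplit(ids, ",", fixed = TRUE))),
    es = es, row.names = NULL
  )
  colnames(rep_es) <- paste0("rep_es_", seq_along(reps))
  colnames(rep_enr) <- paste0("rep_enr_", seq_along(reps))
  out <- cbind(out, as.data.frame(rep_es, row.names = NULL),
               as.data.frame(rep_enr, row.names = NULL))
  out$variance <- variance
  out$median_input <- med_in
  out$quantified <- quantified
  rownames(out) <- ids
  attr(out, "replicates") <- reps
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# per-replicate wt-normalised score matrix from an enrichment_table
rep_es_matrix <- function(scores) {
  cols <- grep("^rep_es_", names(scores), value = TRUE)
  m <- as.matrix(scores[, cols, drop = FALSE])
  rownames(m) <- scores$variant_id
  m
}

# per-replicate non-normalised enrichment matrix
rep_enr_matrix <- function(scores) {
  cols <- grep("^rep_enr_", names(scores), value = TRUE)
  m <- as.matrix(scores[, cols, drop = FALSE])
  rownames(m) <- scores$variant_id
  m
}

#' Write an enrichment table as TSV
#'
#' @param scores An `enrichment_table`.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
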