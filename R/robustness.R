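#' Mutation effects in non-wild-type backgrounds
#'
#' The effect of single mutation A in the background of single mutation B is
#' `ES(A -> B) = ES(AB) - ES(B)`, defined whenever the double AB was
#' quantified. Effects in the wild-type background (`ES(A -> wt) = ES(A)`)
#' are included with `background_id = "wt"`, so the wild type can be compared
#' to its neighbours on the same footing.
#'
#' @param scores An `enrichment_table` covering singles and doubles.
#' @param backgrounds Character vector of single-mutation ids to use as
#'   backgrounds (typically the near-neutral class from
#'   [classify_variants()]).
#' @return Data.frame with `background_id`, `mutation_id`, `double_id`,
#'   `effect`.
#' @export
background_effects <- function(scores, backgrounds) {
  stopifnot(inherits(scores, "enrichment_table"))
  q <- scores[scores$quantified & !is.na(scores$es), ]
  singles <- q[q$n_mutations == 1L, ]
  doubles <- q[q$n_mutations == 2L, ]
  es <- stats::setNames(q$es, q$variant_id)
  backgrounds <- intersect(backgrounds, singles$variant_id)

  out <- list(data.frame(background_id = "wt", mutation_id = singles$variant_id,
                         double_id = singles$variant_id, effect = singles$es))
  if (nrow(doubles) && length(backgrounds)) {
    comp <- strsplit(doubles$variant_id, ",", fixed = TRUE)
    a <- vapply(comp, `[`, "", 1L)
    b <- vapply(comp, `[`, "", 2L)
    for (ori in list(c("a", "b"), c("b", "a"))) {
      bg <- if (ori[1L] == "a") a else b
      mu <- if (ori[1L] == "a") b else a
      keep <- bg %in% backgrounds & mu %in% singles$variant_id
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          background_id = bg[keep], mutation_id = mu[keep],
          double_id = doubles$variant_id[keep],
          effect = doubles$es[keep] - es[bg[keep]])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Coverage-matched read resampling
#'
#' Draws `target_total` reads over a variant set with probabilities equal to
#' each variant's median frequency in the output (selection) channel, then
#' recomputes enrichment scores from the resampled counts against the
#' original input frequencies. This puts deeply covered variants (single
#' mutants) on the same sampling-noise footing as shallowly covered ones
#' (double mutants).
#'
#' @param counts A `count_matrix`.
#' @param variant_set Character vector of variant ids to resample.
#' @param target_total Total reads to draw.
#' @param seed Integer seed.
#' @return List with `counts` (named resampled counts) and `es` (named
#'   resampled wild-type-normalised scores; `NA` where the resampled count
#'   is zero).
#' @export
subsample_reads <- function(counts, variant_set, target_total, seed = 1L) {
  stopifnot(inherits(counts, "count_matrix"), length(variant_set) >= 1L,
            target_total >= 1)
  ft <- frequencies(counts)
  reps <- dimnames(ft$freq)[[2L]]
  fo <- matrix(ft$freq[, , "output"], ncol = length(reps),
               dimnames = list(dimnames(ft$freq)[[1L]], reps))
  fi <- matrix(ft$freq[, , "input"], ncol = length(reps),
               dimnames = dimnames(fo))
  miss <- setdiff(variant_set, rownames(fo))
  if (length(miss)) stop("variants absent from counts: ", miss[1L])
  fo_med <- apply(fo[variant_set, , drop = FALSE], 1L, stats::median)
  fi_med <- apply(fi[variant_set, , drop = FALSE], 1L, stats::median)
  if (all(fo_med == 0)) stop("variant set has no output reads to resample")
  wt_raw <- log2(stats::median(fo["wt", ]) / stats::median(fi["wt", ]))
  set.seed(seed)
  drawn <- stats::rmultinom(1L, target_total, fo_med)[, 1L]
  f_res <- drawn / target_total
  es <- ifelse(drawn > 0 & fi_med > 0, log2(f_res / fi_med) - wt_raw, NA_real_)
  list(counts = drawn, es = stats::setNames(es, variant_set))
}

#' Compare wild-type mutational robustness to near-neutral backgrounds
#'
#' Summarises, per background, the spread of single-mutation effects (median
#' absolute effect and interquartile range). Because the wild type is covered
#' orders of magnitude more deeply than double mutants, its effect
#' distribution is re-estimated `n_wt_resamples` times (default: once per
#' background, 73 in the original design) from read subsamples whose average
#' per-variant depth matches the double mutants'. The set of wild-type
#' resample IQRs is compared to the set of background IQRs with a two-sided
#' Mann-Whitney U test.
#'
#' @param effects Output of [background_effects()].
#' @param counts The `count_matrix` the scores came from.
#' @param n_wt_resamples Number of coverage-matched wild-type resamples
#'   (default: the number of retained backgrounds).
#' @param seed Integer seed.
#' @param min_effects Backgrounds with fewer quantified effects are dropped
#'   (IQRs of tiny samples are unstable).
#' @param match Match the doubles' `"mean"` (default) or `"median"`
#'   per-variant output coverage.
#' @return An object of class `robustness_summary`: `per_background` table,
#'   `wt_iqrs`, `wt_median_abs`, `p_value` (Mann-Whitney), and
#'   `wt_is_most_robust` (is the wild type's median absolute effect below
#'   every background's?).
#' @export
compare_robustness <- function(effects, counts, n_wt_resamples = NULL,
                               seed = 1L, min_effects = 20L,
                               match = c("mean", "median")) {
  match <- match.arg(match)
  bg_rows <- effects[effects$background_id != "wt", ]
  n_per <- table(bg_rows$background_id)
  bgs <- names(n_per)[n_per >= min_effects]
  if (length(bgs) < 2L) stop("insufficient backgrounds with >= ", min_effects,
                             " quantified effects")
  per_bg <- do.call(rbind, lapply(bgs, function(b) {
    e <- bg_rows$effect[bg_rows$background_id == b]
    data.frame(background_id = b, n = length(e),
               median_abs_effect = stats::median(abs(e)),
               iqr = stats::IQR(e))
  }))

  wt_rows <- effects[effects$background_id == "wt", ]
  wt_set <- wt_rows$double_id
  reps <- dimnames(counts$counts)[[2L]]
  dbl <- unique(bg_rows$double_id)
  out_med <- apply(matrix(counts$counts[dbl, , "output"], ncol = length(reps)),
                   1L, stats::median)
  per_variant <- if (match == "mean") mean(out_med) else stats::median(out_med)
  target_total <- max(1L, round(per_variant * length(wt_set)))
  if (is.null(n_wt_resamples)) n_wt_resamples <- length(bgs)
  wt_iqrs <- vapply(seq_len(n_wt_resamples), function(i) {
    es <- subsample_reads(counts, wt_set, target_total, seed = seed + i)$es
    stats::IQR(es, na.rm = TRUE)
  }, 0)
  mw <- stats::wilcox.test(wt_iqrs, per_bg$iqr, alternative = "two.sided",
                           exact = NULL)
  wt_median_abs <- stats::median(abs(wt_rows$effect))
  structure(list(per_background = per_bg, wt_iqrs = wt_iqrs,
                 wt_median_abs = wt_median_abs,
                 wt_is_most_robust = wt_median_abs < min(per_bg$median_abs_effect),
                 p_value = mw$p.value, target_total = target_total,
                 n_wt_resamples = n_wt_resamples, seed = seed),
            class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat(sprintf("robustness_summary: %d backgrounds, %d wt resamples of %d reads\n",
              nrow(x$per_background), x$n_wt_resamples, x$target_total))
  cat(sprintf("  wt median |effect| %.3f vs background min %.3f (wt most robust: %s)\n",
              x$wt_median_abs, min(x$per_background$median_abs_effect),
              x$wt_is_most_robust))
  cat(sprintf("  Mann-Whitney (wt resample IQRs vs background IQRs): p = %.3g\n",
              x$p_value))
  invisible(x)
}
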