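#' Welch's unequal-variances t-test on per-replicate enrichments
#'
#' Wraps [stats::t.test()] (two-sided, `var.equal = FALSE`) with explicit
#' handling of the degenerate cases a three-replicate design can produce:
#' when both sides have zero variance the test statistic is undefined, so
#' equal means give `p = 1` and unequal means give `p = 0` with a
#' `degenerate` flag.
#'
#' @param a,b Numeric vectors (variant and wild-type per-replicate
#'   non-normalised enrichments); `NA`s are dropped.
#' @return A list with `t`, `df`, `p` and `degenerate`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient replicates: need at least 2 values on each side")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values via [stats::p.adjust()], with input validation.
#' `NA` p-values propagate to `NA` q-values and do not count towards the
#' family size.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("invalid p-value outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify single-mutation splicing effects against the wild type
#'
#' Each quantified single mutant's per-replicate non-normalised enrichments
#' are compared to the wild type's by Welch's test; p-values are BH-adjusted
#' over the family of tested singles (189 at full coverage). Labels:
#' `I` (increased inclusion: FDR < alpha and ES > 0), `S` (increased
#' skipping: FDR < alpha and ES < 0), `N` (near-neutral: FDR >= alpha and
#' replicate variance <= var_threshold), `X` (not classified: FDR >= alpha
#' but variance above the threshold). The variance is the sample variance of
#' the per-replicate wild-type-normalised scores.
#'
#' @param scores An `enrichment_table`.
#' @param alpha FDR threshold (default 0.05).
#' @param var_threshold Replicate-variance ceiling for the near-neutral
#'   label (default 0.15).
#' @return A data.frame of class `classified_variants`: one row per tested
#'   single with `variant_id`, `es`, `p_value`, `fdr`, `variance`, `class`,
#'   `rank` (by increasing ES).
#' @export
classify_variants <- function(scores, alpha = 0.05, var_threshold = 0.15) {
  stopifnot(inherits(scores, "enrichment_table"))
  enr <- rep_enr_matrix(scores)
  wt <- enr["wt", ]
  singles <- scores[scores$n_mutations == 1L & scores$quantified, , drop = FALSE]
  testable <- vapply(singles$variant_id, function(id) {
    sum(!is.na(enr[id, ])) >= 2L
  }, TRUE)
  singles <- singles[testable, , drop = FALSE]
  if (!nrow(singles)) stop("no testable single mutants")
  p <- vapply(singles$variant_id, function(id) welch_test(enr[id, ], wt)$p,
              0)
  fdr <- bh_fdr(p)
  cls <- ifelse(fdr < alpha & singles$es > 0, "I",
         ifelse(fdr < alpha & singles$es < 0, "S",
         ifelse(singles$variance <= var_threshold, "N", "X")))
  out <- data.frame(variant_id = singles$variant_id, es = singles$es,
                    p_value = unname(p), fdr = unname(fdr),
                    variance = singles$variance, class = cls,
                    rank = rank(singles$es, ties.method = "first"),
                    row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "var_threshold") <- var_threshold
  class(out) <- c("classified_variants", "data.frame")
  out
}

#' @export
print.classified_variants <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("I", "S", "N", "X")))
  cat(sprintf("classified_variants: %d tested singles (FDR < %g)\n",
              nrow(x), attr(x, "alpha")))
  cat(sprintf("  I (inclusion up): %d, S (skipping up): %d, N (near-neutral): %d, X (unclassified): %d\n",
              tab[["I"]], tab[["S"]], tab[["N"]], tab[["X"]]))
  invisible(x)
}
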