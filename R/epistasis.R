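single_position <- function(id) as.integer(sub("^([0-9]+).*$", "\\1", id))

# median across the rows of a matrix, NA-tolerant, fast for few columns
row_medians <- function(m) {
  apply(m, 1L, stats::median, na.rm = TRUE)
}

#' Fit the linear no-interaction expectation for double mutants
#'
#' Regresses each double mutant's enrichment score on the sum of its two
#' constituent single-mutant scores, by ordinary least squares with
#' intercept, separately within every replicate. The residual from this
#' expectation is the replicate-level epistasis signal; the variance
#' explained by the no-interaction model (pooled over replicates) measures
#' how additive the landscape is.
#'
#' @param scores An `enrichment_table` covering quantified singles and
#'   doubles.
#' @param min_pairs Minimum usable pairs per replicate.
#' @return An object of class `epistasis_fit`: per-replicate coefficients
#'   (`intercept`, `slope`, `r2`, `n`), `pooled_r2`, and the observed /
#'   expected-sum / predicted score matrices for the retained pairs.
#' @export
fit_linear_expectation <- function(scores, min_pairs = 10L) {
  stopifnot(inherits(scores, "enrichment_table"))
  S <- rep_es_matrix(scores)
  q <- scores$quantified & !is.na(scores$es)
  singles <- scores$variant_id[scores$n_mutations == 1L & q]
  doubles <- scores$variant_id[scores$n_mutations == 2L & q]
  if (!length(doubles)) stop("no quantified double mutants")
  comp <- strsplit(doubles, ",", fixed = TRUE)
  a <- vapply(comp, `[`, "", 1L)
  b <- vapply(comp, `[`, "", 2L)
  keep <- a %in% singles & b %in% singles
  doubles <- doubles[keep]; a <- a[keep]; b <- b[keep]
  if (!length(doubles)) stop("no double mutant has both singles quantified")
  obs <- S[doubles, , drop = FALSE]
  ssum <- S[a, , drop = FALSE] + S[b, , drop = FALSE]
  nrep <- ncol(S)
  coefs <- data.frame(replicate = colnames(S) %||% paste0("rep", seq_len(nrep)),
                      intercept = NA_real_, slope = NA_real_,
                      r2 = NA_real_, n = NA_integer_)
  pred <- obs * NA_real_
  for (r in seq_len(nrep)) {
    ok <- is.finite(obs[, r]) & is.finite(ssum[, r])
    if (sum(ok) < min_pairs) {
      stop("insufficient pairs in replicate ", r, ": ", sum(ok), " < ", min_pairs)
    }
    fit <- stats::lm(obs[ok, r] ~ ssum[ok, r])
    cf <- stats::coef(fit)
    coefs$intercept[r] <- unname(cf[1L])
    coefs$slope[r] <- unname(cf[2L])
    coefs$n[r] <- sum(ok)
    pred[, r] <- cf[1L] + cf[2L] * ssum[, r]
    coefs$r2[r] <- 1 - sum(stats::residuals(fit)^2) /
      sum((obs[ok, r] - mean(obs[ok, r]))^2)
  }
  ok_all <- is.finite(obs) & is.finite(pred)
  pooled_r2 <- 1 - sum((obs[ok_all] - pred[ok_all])^2) /
    sum((obs[ok_all] - mean(obs[ok_all]))^2)
  structure(list(coefs = coefs, pooled_r2 = pooled_r2,
                 pairs = data.frame(pair_id = doubles, single_a = a,
                                    single_b = b),
                 obs = obs, ssum = ssum, pred = pred),
            class = "epistasis_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf("epistasis_fit: %d pairs, %d replicates\n",
              nrow(x$pairs), nrow(x$coefs)))
  print(x$coefs, row.names = FALSE)
  cat(sprintf("  variance explained by the no-interaction model: %.1f%%\n",
              100 * x$pooled_r2))
  invisible(x)
}

#' Empirical epistasis scores
#'
#' The replicate-level epistasis score of a pair is the residual of the
#' observed double-mutant score from the replicate's linear expectation; the
#' empirical score E is the median of those residuals across replicates.
#'
#' @param fit An `epistasis_fit`.
#' @return A data.frame of class `epistasis_table`: `pair_id`, `single_a`,
#'   `single_b`, per-replicate `resid_*` columns, `E`, and `distance`
#'   (nucleotides between the two mutated positions). The observed and
#'   predicted matrices travel along as attributes for testing.
#' @export
epistasis_scores <- function(fit) {
  stopifnot(inherits(fit, "epistasis_fit"))
  resid <- fit$obs - fit$pred
  out <- fit$pairs
  colnames(resid) <- paste0("resid_", seq_len(ncol(resid)))
  out <- cbind(out, as.data.frame(resid, row.names = NULL))
  out$E <- row_medians(resid)
  out$distance <- abs(single_position(out$single_a) -
                        single_position(out$single_b))
  rownames(out) <- out$pair_id
  attr(out, "obs") <- fit$obs
  attr(out, "pred") <- fit$pred
  class(out) <- c("epistasis_table", "data.frame")
  out
}

#' Test and classify pairwise epistasis
#'
#' Per pair, a paired t-test between the replicate-wise observed and
#' predicted double-mutant scores (equivalently, a one-sample t-test of the
#' residuals against zero). BH FDR is applied separately within network
#' families defined by the single-mutant classes: `NxN` (both near-neutral),
#' `NxX` (one near-neutral), `XxX` (neither). Pairs with FDR < alpha are
#' classified `positive` or `negative` by the sign of E, otherwise `none`.
#' Zero-variance residual vectors make the t statistic undefined: such pairs
#' get p = 0 when the common residual is non-zero (to tolerance 1e-9) and
#' p = 1 otherwise, and are flagged `degenerate`.
#'
#' @param epi An `epistasis_table`.
#' @param classes Optional `classified_variants` table used to assign
#'   network families; without it every pair is `XxX`.
#' @param alpha FDR threshold (default 0.05).
#' @return The `epistasis_table` augmented with `p_value`, `fdr`,
#'   `network_family`, `sign_class`, `degenerate`.
#' @export
test_epistasis <- function(epi, classes = NULL, alpha = 0.05) {
  stopifnot(inherits(epi, "epistasis_table"))
  d <- attr(epi, "obs") - attr(epi, "pred")
  n_ok <- rowSums(is.finite(d))
  md <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums(d^2, na.rm = TRUE)
  sd2 <- pmax(ss - n_ok * md^2, 0) / pmax(n_ok - 1L, 1L)
  p <- rep(NA_real_, nrow(epi))
  degenerate <- rep(FALSE, nrow(epi))
  usable <- n_ok >= 2L
  zerovar <- usable & sd2 < 1e-18
  degenerate[zerovar] <- TRUE
  p[zerovar] <- ifelse(abs(md[zerovar]) > 1e-9, 0, 1)
  reg <- usable & !zerovar
  tstat <- md[reg] / sqrt(sd2[reg] / n_ok[reg])
  p[reg] <- 2 * stats::pt(-abs(tstat), df = n_ok[reg] - 1L)

  if (!is.null(classes)) {
    neutral <- classes$variant_id[classes$class == "N"]
    inN <- cbind(epi$single_a %in% neutral, epi$single_b %in% neutral)
    fam <- c("XxX", "NxX", "NxN")[rowSums(inN) + 1L]
  } else {
    fam <- rep("XxX", nrow(epi))
  }
  fdr <- rep(NA_real_, nrow(epi))
  for (f in unique(fam)) {
    idx <- fam == f
    fdr[idx] <- bh_fdr(p[idx])
  }
  epi$p_value <- p
  epi$fdr <- fdr
  epi$network_family <- fam
  epi$sign_class <- ifelse(!is.na(fdr) & fdr < alpha & epi$E > 0, "positive",
                    ifelse(!is.na(fdr) & fdr < alpha & epi$E < 0, "negative",
                           "none"))
  epi$degenerate <- degenerate
  attr(epi, "alpha") <- alpha
  epi
}

#' Epistasis network summaries
#'
#' Interaction degree per single mutation (overall and within each network
#' family), hub detection by a degree quantile, and a comparison of the
#' linear (nucleotide) distance separating epistatically versus
#' non-epistatically interacting pairs.
#'
#' @param epi A tested `epistasis_table` (see [test_epistasis()]).
#' @param hub_quantile Mutations with degree strictly above this quantile of
#'   the positive-degree distribution are reported as hubs (default 0.95).
#' @return An object of class `epistasis_networks`: `degrees` (per mutation,
#'   overall and per family), `hubs`, `distance_p` (two-sided Mann-Whitney),
#'   and summary counts.
#' @export
network_metrics <- function(epi, hub_quantile = 0.95) {
  stopifnot(inherits(epi, "epistasis_table"), "sign_class" %in% names(epi))
  muts <- sort(unique(c(epi$single_a, epi$single_b)))
  sig <- epi$sign_class != "none"
  deg_of <- function(rows) {
    t1 <- table(factor(epi$single_a[rows], levels = muts)) +
      table(factor(epi$single_b[rows], levels = muts))
    as.integer(t1)
  }
  degrees <- data.frame(mutation_id = muts, degree = deg_of(sig))
  for (f in sort(unique(epi$network_family))) {
    degrees[[paste0("degree_", f)]] <- deg_of(sig & epi$network_family == f)
  }
  pos_deg <- degrees$degree[degrees$degree > 0]
  hubs <- character(0)
  if (length(pos_deg)) {
    cut <- stats::quantile(degrees$degree, hub_quantile, names = FALSE)
    hubs <- degrees$mutation_id[degrees$degree > cut & degrees$degree > 0]
  }
  distance_p <- NA_real_
  if (any(sig) && any(!sig)) {
    # distances are integers: ties are routine, use the approximate test
    distance_p <- suppressWarnings(
      stats::wilcox.test(epi$distance[sig], epi$distance[!sig],
                         alternative = "two.sided")$p.value)
  }
  structure(list(
    degrees = degrees, hubs = hubs, distance_p = distance_p,
    n_pairs = nrow(epi), n_significant = sum(sig),
    n_positive = sum(epi$sign_class == "positive"),
    n_negative = sum(epi$sign_class == "negative"),
    n_mutations_with_interaction = sum(degrees$degree > 0),
    hub_quantile = hub_quantile),
    class = "epistasis_networks")
}

#' @export
print.epistasis_networks <- function(x, ...) {
  cat(sprintf("epistasis_networks: %d pairs, %d significant (%d positive, %d negative)\n",
              x$n_pairs, x$n_significant, x$n_positive, x$n_negative))
  cat(sprintf("  %d mutations with >= 1 interaction; hubs (degree > q%.2f): %s\n",
              x$n_mutations_with_interaction, x$hub_quantile,
              if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none"))
  if (!is.na(x$distance_p)) {
    cat(sprintf("  linear-distance comparison (epistatic vs not): MW p = %.3g\n",
                x$distance_p))
  }
  invisible(x)
}

#' Write a tested epistasis table as TSV
#'
#' @param epi An `epistasis_table`.
#' @param path File path.
#' @export
write_epistasis <- function(epi, path) {
  utils::write.table(as.data.frame(epi), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
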