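#' Variant count matrices
#'
#' A `count_matrix` holds read counts per variant, replicate and channel
#' (`input` = plasmid library, `output` = exon-inclusion RT-PCR product),
#' plus a lumped bin for molecules carrying more than two substitutions.
#' Those molecules are excluded from per-variant analysis but contribute to
#' the channel totals that all frequencies are computed against.
#'
#' @param counts Numeric array `variants x replicates x 2` with dimnames
#'   (variant ids, replicate names, `c("input", "output")`). Expected
#'   (non-integer) counts are allowed: the noiseless limit of the simulator
#'   uses them.
#' @param other Matrix `replicates x 2` of reads with >2 mutations
#'   (default all zero).
#' @param rejected Optional data.frame of rejected-read tallies
#'   (`path`, `reason`, `count`) produced by read counting.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, other = NULL, rejected = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L, dim(counts)[3L] == 2L,
            !is.null(dimnames(counts)), all(counts >= 0))
  dimnames(counts)[[3L]] <- c("input", "output")
  if (is.null(other)) {
    other <- matrix(0, dim(counts)[2L], 2L,
                    dimnames = list(dimnames(counts)[[2L]], c("input", "output")))
  }
  stopifnot(nrow(other) == dim(counts)[2L], ncol(other) == 2L, all(other >= 0))
  structure(list(counts = counts, other = other, rejected = rejected),
            class = "count_matrix")
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @return `channel_totals`: matrix `replicates x 2` of total accepted reads
#'   (per-variant counts plus the >2-mutation bin).
#' @export
channel_totals <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  apply(x$counts, c(2L, 3L), sum) + x$other
}

#' @export
print.count_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("count_matrix: %d variants x %d replicates x 2 channels\n", d[1L], d[2L]))
  tot <- channel_totals(x)
  for (r in rownames(tot)) {
    cat(sprintf("  %s: input %s reads, output %s reads\n", r,
                format(tot[r, "input"], big.mark = ","),
                format(tot[r, "output"], big.mark = ",")))
  }
  if (!is.null(x$rejected) && nrow(x$rejected)) {
    cat(sprintf("  rejected reads: %d\n", sum(x$rejected$count)))
  }
  invisible(x)
}

#' Read and write count matrices as TSV
#'
#' Long format with columns `variant_id`, `replicate`, `channel`, `count`;
#' the >2-mutation bin is stored under the reserved id `"other"`.
#'
#' @param x A `count_matrix`.
#' @param path File path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  dn <- dimnames(x$counts)
  long <- expand.grid(variant_id = dn[[1L]], replicate = dn[[2L]],
                      channel = dn[[3L]], stringsAsFactors = FALSE)
  long$count <- as.vector(x$counts)
  oth <- expand.grid(variant_id = "other", replicate = dn[[2L]],
                     channel = dn[[3L]], stringsAsFactors = FALSE)
  oth$count <- as.vector(x$other)
  utils::write.table(rbind(long, oth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts`: the reconstructed `count_matrix`.
#' @export
read_counts <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character", "character", "numeric"))
  ids <- setdiff(unique(long$variant_id), "other")
  reps <- unique(long$replicate)
  arr <- array(0, dim = c(length(ids), length(reps), 2L),
               dimnames = list(ids, reps, c("input", "output")))
  main <- long[long$variant_id != "other", ]
  arr[cbind(match(main$variant_id, ids), match(main$replicate, reps),
            match(main$channel, c("input", "output")))] <- main$count
  other <- matrix(0, length(reps), 2L, dimnames = list(reps, c("input", "output")))
  oth <- long[long$variant_id == "other", ]
  other[cbind(match(oth$replicate, reps),
              match(oth$channel, c("input", "output")))] <- oth$count
  count_matrix(arr, other)
}
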