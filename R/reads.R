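#' Trim invariant flanks off an amplicon read
#'
#' A read is accepted when it has exactly the reference amplicon length and
#' each flank matches its invariant reference flank with at most
#' `max_flank_mismatch` mismatches; the central exon-length substring is then
#' returned. Reads of any other length (indel-bearing molecules, truncated
#' amplicons) are rejected with reason `"length_mismatch"`, flank-damaged
#' reads with `"flank_mismatch"`. Rejection is a value, not an error.
#'
#' @param read A single DNA string.
#' @param ref An `exon_reference`.
#' @param max_flank_mismatch Mismatches tolerated per flank (default 0: the
#'   flanks are invariant by design).
#' @return A list with `exon` (the trimmed exon string, or `NA`) and
#'   `reason` (`NA` when accepted).
#' @export
trim_flanks <- function(read, ref, max_flank_mismatch = 0L) {
  stopifnot(is.character(read), length(read) == 1L, nchar(read) > 0L)
  res <- trim_flanks_vec(read, ref, max_flank_mismatch)
  list(exon = res$exon, reason = res$reason)
}

# vectorised core shared with count_reads; reads is a character vector
trim_flanks_vec <- function(reads, ref, max_flank_mismatch = 0L) {
  f5 <- nchar(ref$flank5)
  L <- nchar(ref$exon)
  full_len <- nchar(ref$full_sequence)
  exon <- rep(NA_character_, length(reads))
  reason <- rep(NA_character_, length(reads))
  reads <- toupper(reads)
  len_ok <- nchar(reads) == full_len
  reason[!len_ok] <- "length_mismatch"
  if (any(len_ok)) {
    idx <- which(len_ok)
    m5 <- hamming_vec(substr(reads[idx], 1L, f5), ref$flank5)
    m3 <- hamming_vec(substr(reads[idx], f5 + L + 1L, full_len), ref$flank3)
    bad <- m5 > max_flank_mismatch | m3 > max_flank_mismatch
    reason[idx[bad]] <- "flank_mismatch"
    keep <- idx[!bad]
    exon[keep] <- substr(reads[keep], f5 + 1L, f5 + L)
  }
  list(exon = exon, reason = reason)
}

# Hamming distance of each string in x (all the same length) to string y
hamming_vec <- function(x, y) {
  if (!length(x)) return(integer(0))
  yb <- utf8ToInt(y)
  vapply(x, function(s) sum(utf8ToInt(s) != yb), 0L, USE.NAMES = FALSE)
}

#' Call the substitutions carried by a trimmed exon read
#'
#' Compares an exon-length string to the reference exon position by position.
#' The mutation list is populated only for reads with at most two
#' substitutions; reads with more report their Hamming distance and are
#' destined for the lumped >2-mutation bin.
#'
#' @param exon_seq An exon-length DNA string (A/C/G/T).
#' @param ref An `exon_reference`.
#' @return A list with `variant_id` (`NA` for >2 substitutions),
#'   `n_mutations`, and a `mutations` data.frame (`pos`, `ref`, `alt`; empty
#'   for the wild type and for >2 substitutions).
#' @export
call_variant <- function(exon_seq, ref) {
  stopifnot(is.character(exon_seq), length(exon_seq) == 1L)
  exon_seq <- toupper(exon_seq)
  if (nchar(exon_seq) != nchar(ref$exon)) {
    stop("exon_seq must have the reference exon length (",
         nchar(ref$exon), " nt)")
  }
  if (!grepl("^[ACGT]+$", exon_seq)) stop("invalid alphabet in exon_seq")
  a <- utf8ToInt(exon_seq)
  b <- utf8ToInt(ref$exon)
  pos <- which(a != b)
  n <- length(pos)
  if (n > 2L) {
    return(list(variant_id = NA_character_, n_mutations = n,
                mutations = data.frame(pos = integer(), ref = character(),
                                       alt = character())))
  }
  mut <- data.frame(pos = pos, ref = intToUtf8(b[pos], multiple = TRUE),
                    alt = intToUtf8(a[pos], multiple = TRUE),
                    stringsAsFactors = FALSE)
  if (n == 0L) mut <- data.frame(pos = integer(), ref = character(), alt = character())
  list(variant_id = variant_id_from_mutations(mut$pos, mut$ref, mut$alt),
       n_mutations = n, mutations = mut)
}

#' Count amplicon reads into a variant count matrix
#'
#' Reads each (replicate, channel) FASTQ, trims flanks, calls substitutions
#' against the reference exon, and aggregates counts per variant. Reads with
#' more than two substitutions are tallied in the lumped bin and still count
#' towards channel totals; rejected reads (wrong length or damaged flanks)
#' are tallied per file with their reason.
#'
#' @param sample_sheet Data.frame with columns `path`, `replicate`, `channel`
#'   (`channel` in `"input"`/`"output"`), or the path to such a TSV. Every
#'   replicate must appear with both channels.
#' @param ref An `exon_reference`.
#' @param max_flank_mismatch Passed to the flank trimmer.
#' @param universe Variant table defining the rows of the result (default
#'   `enumerate_variants(ref, 2)`); observed variants outside it are an error.
#' @return A `count_matrix`; the rejection report is in its `rejected` field.
#' @export
count_reads <- function(sample_sheet, ref, max_flank_mismatch = 0L,
                        universe = NULL) {
  if (is.character(sample_sheet)) {
    sample_sheet <- utils::read.table(sample_sheet, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("path", "replicate", "channel") %in% names(sample_sheet)),
            all(sample_sheet$channel %in% c("input", "output")))
  reps <- unique(sample_sheet$replicate)
  for (r in reps) {
    if (!setequal(sample_sheet$channel[sample_sheet$replicate == r],
                  c("input", "output"))) {
      stop("replicate ", r, " must have both an input and an output channel")
    }
  }
  if (is.null(universe)) universe <- enumerate_variants(ref, 2L)
  ids <- universe$variant_id
  arr <- array(0, dim = c(length(ids), length(reps), 2L),
               dimnames = list(ids, reps, c("input", "output")))
  other <- matrix(0, length(reps), 2L,
                  dimnames = list(reps, c("input", "output")))
  rej <- list()
  for (i in seq_len(nrow(sample_sheet))) {
    path <- sample_sheet$path[i]
    if (!file.exists(path)) stop("missing read file: ", path)
    reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
    tab <- table(reads)
    uniq <- names(tab)
    n_per <- as.vector(tab)
    tr <- trim_flanks_vec(uniq, ref, max_flank_mismatch)
    if (any(!is.na(tr$reason))) {
      bad <- !is.na(tr$reason)
      rtab <- tapply(n_per[bad], tr$reason[bad], sum)
      rej[[length(rej) + 1L]] <- data.frame(path = path, reason = names(rtab),
                                            count = as.vector(rtab))
    }
    ok <- which(is.na(tr$reason))
    if (!length(ok)) next
    calls <- lapply(tr$exon[ok], call_variant, ref = ref)
    vid <- vapply(calls, `[[`, "", "variant_id")
    r <- sample_sheet$replicate[i]
    ch <- sample_sheet$channel[i]
    multi <- is.na(vid)
    other[r, ch] <- other[r, ch] + sum(n_per[ok][multi])
    if (any(!multi)) {
      hit <- match(vid[!multi], ids)
      if (anyNA(hit)) stop("observed variant outside the supplied universe: ",
                           vid[!multi][which(is.na(hit))[1L]])
      add <- tapply(n_per[ok][!multi], hit, sum)
      idx <- cbind(as.integer(names(add)), match(r, reps),
                   match(ch, c("input", "output")))
      arr[idx] <- arr[idx] + as.vector(add)
    }
  }
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(path = character(), reason = character(), count = numeric())
  count_matrix(arr, other, rejected = rejected)
}
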