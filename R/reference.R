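#' Parse a doped-library reference oligonucleotide
#'
#' The reference for a doped-library splicing assay is a single
#' oligonucleotide in which the mutagenised exon is written in lowercase and
#' the invariant intronic flanks in uppercase. For the FAS/CD95 exon 6 design
#' this is a 135-mer: 22 nt of the 3' end of intron 5, the 63-nt exon, and
#' 50 nt of the 5' end of intron 6.
#'
#' @param x Either a mixed-case DNA string, or the path to a single-record
#'   FASTA file containing such a string (case is preserved on read).
#' @return An object of class `exon_reference` with fields `full_sequence`
#'   (upper-cased), `flank5`, `exon` and `flank3`. Exon coordinates used
#'   throughout the package are 1-based positions along `exon`.
#' @examples
#' ref <- load_reference("AAccAA")
#' ref$exon     # "CC"
#' fas <- fas_reference()
#' nchar(fas$exon)  # 63
#' @export
load_reference <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (grepl("[/\\\\]|\\.fa(sta)?$", x) || file.exists(x)) {
    if (!file.exists(x)) stop("reference FASTA not found: ", x)
    recs <- seqinr::read.fasta(x, as.string = TRUE, forceDNAtolower = FALSE)
    if (length(recs) != 1L) stop("reference FASTA must contain exactly one record")
    x <- as.character(recs[[1L]])
  }
  if (!grepl("^[ACGTacgt]+$", x)) {
    stop("invalid alphabet: reference may contain only A/C/G/T (either case)")
  }
  runs <- gregexpr("[acgt]+", x)[[1L]]
  if (runs[1L] == -1L || length(runs) != 1L) {
    stop("malformed reference: expected exactly one lowercase (exon) run, found ",
         if (runs[1L] == -1L) 0L else length(runs))
  }
  start <- as.integer(runs)
  len <- attr(runs, "match.length")
  ref <- list(
    full_sequence = toupper(x),
    flank5 = toupper(substr(x, 1L, start - 1L)),
    exon = toupper(substr(x, start, start + len - 1L)),
    flank3 = toupper(substr(x, start + len, nchar(x)))
  )
  class(ref) <- "exon_reference"
  ref
}

#' @export
print.exon_reference <- function(x, ...) {
  cat(sprintf("exon_reference: %d nt = %d (5' flank) + %d (exon) + %d (3' flank)\n",
              nchar(x$full_sequence), nchar(x$flank5), nchar(x$exon), nchar(x$flank3)))
  cat("exon:", x$exon, "\n")
  invisible(x)
}

#' The FAS/CD95 exon 6 doped-library reference
#'
#' Loads the 135-nt oligonucleotide of the FAS exon 6 doped-library design
#' shipped with the package (22-nt intron 5 flank, 63-nt exon, 50-nt intron 6
#' flank).
#'
#' @return An `exon_reference`.
#' @export
fas_reference <- function() {
  load_reference(system.file("extdata", "fas_exon6_oligo.fa", package = "dmsplice",
                             mustWork = TRUE))
}

DNA_BASES <- c("A", "C", "G", "T")

#' Canonical mutation and variant identifiers
#'
#' Single substitutions are written `"<pos><ref>><alt>"` (e.g. `"5C>T"`) with
#' 1-based exon coordinates; a variant identifier joins its mutations in
#' ascending position order with `","`, and the unmutated exon is `"wt"`.
#'
#' @param pos,ref,alt Parallel vectors of positions, reference bases and
#'   alternative bases.
#' @return `mutation_id`: a character vector of mutation identifiers.
#' @export
mutation_id <- function(pos, ref, alt) sprintf("%d%s>%s", as.integer(pos), ref, alt)

#' @rdname mutation_id
#' @param variant_id A variant identifier (`"wt"`, one mutation, or several
#'   joined by commas).
#' @return `parse_variant_id`: a data.frame with columns `pos`, `ref`, `alt`
#'   (zero rows for `"wt"`).
#' @export
parse_variant_id <- function(variant_id) {
  stopifnot(length(variant_id) == 1L)
  if (variant_id == "wt") {
    return(data.frame(pos = integer(), ref = character(), alt = character()))
  }
  parts <- strsplit(variant_id, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)([ACGT])>([ACGT])$", parts))
  if (any(lengths(m) != 4L)) stop("unparseable variant id: ", variant_id)
  data.frame(
    pos = as.integer(vapply(m, `[`, "", 2L)),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L)
  )
}

#' @rdname mutation_id
#' @return `variant_id_from_mutations`: a single identifier with mutations
#'   sorted by position.
#' @export
variant_id_from_mutations <- function(pos, ref, alt) {
  if (length(pos) == 0L) return("wt")
  if (anyDuplicated(pos)) stop("mutation positions must be distinct")
  o <- order(pos)
  paste(mutation_id(pos[o], ref[o], alt[o]), collapse = ",")
}

#' Apply substitutions to the reference exon
#'
#' @param ref An `exon_reference`.
#' @param pos,alt Positions (1-based along the exon) and alternative bases.
#' @return The mutated exon string.
#' @export
apply_mutations <- function(ref, pos, alt) {
  exon <- strsplit(ref$exon, "")[[1L]]
  if (length(pos)) {
    stopifnot(all(pos >= 1L), all(pos <= length(exon)))
    if (any(exon[pos] == alt)) stop("alt base equals the reference base")
    exon[pos] <- alt
  }
  paste(exon, collapse = "")
}

#' Enumerate the analysed variant universe
#'
#' Lists the wild type, every single substitution (3L for an exon of length
#' L), and optionally every double substitution (9 L(L-1)/2). For the 63-nt
#' FAS exon this is 189 singles and 17,577 doubles.
#'
#' @param ref An `exon_reference`.
#' @param max_mutations 1 or 2.
#' @return A data.frame with columns `variant_id`, `n_mutations`, `pos1`,
#'   `ref1`, `alt1`, `pos2`, `ref2`, `alt2` (the pos2/ref2/alt2 triplet is NA
#'   for the wild type and singles). Row order: wt, singles, doubles.
#' @examples
#' nrow(enumerate_variants(fas_reference(), 1)) - 1  # 189 singles
#' @export
enumerate_variants <- function(ref, max_mutations = 2L) {
  stopifnot(inherits(ref, "exon_reference"), max_mutations %in% c(1L, 2L))
  exon <- strsplit(ref$exon, "")[[1L]]
  L <- length(exon)
  singles <- do.call(rbind, lapply(seq_len(L), function(p) {
    data.frame(pos = p, ref = exon[p], alt = setdiff(DNA_BASES, exon[p]))
  }))
  out <- data.frame(
    variant_id = c("wt", mutation_id(singles$pos, singles$ref, singles$alt)),
    n_mutations = c(0L, rep(1L, nrow(singles))),
    pos1 = c(NA_integer_, singles$pos),
    ref1 = c(NA_character_, singles$ref),
    alt1 = c(NA_character_, singles$alt),
    pos2 = NA_integer_, ref2 = NA_character_, alt2 = NA_character_
  )
  if (max_mutations == 2L) {
    n <- nrow(singles)
    grid <- expand.grid(i = seq_len(n), j = seq_len(n))
    grid <- grid[singles$pos[grid$i] < singles$pos[grid$j], , drop = FALSE]
    if (nrow(grid) == 0L) {
      rownames(out) <- out$variant_id
      return(out)
    }
    a <- singles[grid$i, ]
    b <- singles[grid$j, ]
    doubles <- data.frame(
      variant_id = paste(mutation_id(a$pos, a$ref, a$alt),
                         mutation_id(b$pos, b$ref, b$alt), sep = ","),
      n_mutations = 2L,
      pos1 = a$pos, ref1 = a$ref, alt1 = a$alt,
      pos2 = b$pos, ref2 = b$ref, alt2 = b$alt
    )
    doubles <- doubles[order(doubles$pos1, doubles$alt1, doubles$pos2, doubles$alt2), ]
    out <- rbind(out, doubles)
  }
  rownames(out) <- out$variant_id
  out
}

#' Analytic composition of a doped oligonucleotide library
#'
#' Under independent per-position doping at rate `d` for each of the three
#' non-reference bases, the number of substitutions per molecule is
#' Binomial(L, 3d): the wild-type fraction is (1-3d)^L, singles
#' L * 3d * (1-3d)^(L-1), doubles C(L,2) * (3d)^2 * (1-3d)^(L-2). At the FAS
#' design values (d = 1.2\%, L = 63) this predicts roughly 10\% wt, 23\%
#' single and 27\% double mutants.
#'
#' @param d Doping rate per alternative base per position.
#' @param L Exon length in nucleotides.
#' @return Named numeric vector `c(p_wt, p_single, p_double)`.
#' @examples
#' round(doping_composition(0.012, 63), 2)  # 0.10 0.23 0.27
#' @export
doping_composition <- function(d, L) {
  stopifnot(length(d) == 1L, length(L) == 1L, L >= 1)
  if (!is.finite(d) || d <= 0 || 3 * d >= 1) {
    stop("invalid rate: need 0 < 3d < 1")
  }
  q <- 3 * d
  c(p_wt = (1 - q)^L,
    p_single = L * q * (1 - q)^(L - 1),
    p_double = choose(L, 2) * q^2 * (1 - q)^(L - 2))
}
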