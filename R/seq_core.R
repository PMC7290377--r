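## Sequence primitives: FASTA I/O, composition, strand handling and pairwise
## alignment. Coordinates are 0-based half-open everywhere inside the package;
## 1-based inclusive only at the GFF3 boundary.

#' Read nucleotide sequences from a FASTA file
#'
#' Residues are upper-cased on read. IUPAC ambiguity codes other than N are
#' mapped to N with a warning; any other character is an error. Record order
#' is preserved.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @return A named character vector of sequences (names are record ids, the
#'   token before the first whitespace of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  ambig <- grepl("[RYSWKMBDHV]", seqs)
  if (any(ambig)) {
    warning("IUPAC ambiguity codes mapped to N in ",
            sum(ambig), " record(s)")
    seqs <- gsub("[RYSWKMBDHV]", "N", seqs)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop("empty record in FASTA file")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' GC content of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N is excluded from both numerator and
#' denominator.
#'
#' @param seq A sequence string.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  check_residues(seq)
  ch <- s2c(seq)
  acgt <- sum(ch != "N")
  if (acgt == 0L) stop("GC content undefined for an all-N sequence")
  sum(ch == "G" | ch == "C") / acgt
}

#' Reverse complement
#'
#' @param seq A sequence string over {A,C,G,T,N}.
#' @return The reverse complement (N maps to N).
#' @export
reverse_complement <- function(seq) {
  check_residues(seq)
  c2s(rev(s2c(chartr("ACGT", "TGCA", seq))))
}

#' Alignment identity from two gapped strings
#'
#' Identity = matching non-gap columns / total alignment columns, so gap
#' columns count against identity. N matches nothing.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return Fraction in \[0, 1\].
#' @export
alignment_identity <- function(aligned_a, aligned_b) {
  ca <- s2c(aligned_a); cb <- s2c(aligned_b)
  stopifnot(length(ca) == length(cb))
  mean(ca == cb & ca != "-" & ca != "N")
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Linear gap penalty; traceback ties are broken diagonal, then up, then left,
#' so results are deterministic.
#'
#' @param a,b Sequence strings.
#' @param match,mismatch,gap Scoring parameters (mismatch and gap are
#'   penalties, i.e. typically negative).
#' @return A list of class `alignment_result` with `aligned_a`, `aligned_b`,
#'   `score` and `identity`.
#' @export
global_align <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  check_residues(a, "a"); check_residues(b, "b")
  res <- nw_align_cpp(a, b, match, mismatch, gap)
  res$identity <- alignment_identity(res$aligned_a, res$aligned_b)
  class(res) <- "alignment_result"
  res
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' @inheritParams global_align
#' @return A list of class `alignment_result` with the gapped strings, score,
#'   identity of the matched region, and 0-based half-open matched intervals
#'   `a_start`/`a_end` and `b_start`/`b_end` on each input.
#' @export
local_align <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  check_residues(a, "a"); check_residues(b, "b")
  res <- sw_align_cpp(a, b, match, mismatch, gap)
  res$identity <- if (nchar(res$aligned_a) > 0)
    alignment_identity(res$aligned_a, res$aligned_b) else 0
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("pairwise alignment: score", x$score,
      sprintf("identity %.3f\n", x$identity))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

## Annotation record containers and format writers ---------------------------

#' Build an annotation record table
#'
#' The internal tabular form of located, stranded, identity-scored matches.
#' Coordinates are 0-based half-open.
#' @param seqid,start,end,strand,family,identity Equal-length vectors.
#' @return A data.frame with those columns.
#' @export
annotation_records <- function(seqid, start, end, strand, family, identity) {
  stopifnot(all(start >= 0), all(end > start),
            all(strand %in% c("+", "-")))
  data.frame(seqid = as.character(seqid), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             family = as.character(family), identity = as.numeric(identity),
             stringsAsFactors = FALSE)
}

records_to_granges <- function(records, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = records$seqid,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = records$strand)
  if (!is.null(records$family)) gr$family <- records$family
  if (!is.null(records$identity)) gr$identity <- records$identity
  if (!is.null(seqlengths))
    GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Write annotation records as GFF3
#'
#' GFF3 uses 1-based inclusive coordinates; attributes carry family name and
#' identity.
#' @param records A data.frame from [annotation_records()].
#' @param path Output path.
#' @param source,type GFF3 source and type columns.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path, source = "satkit",
                       type = "satellite_DNA") {
  gr <- records_to_granges(records)
  gr$source <- source
  gr$type <- type
  gr$ID <- sprintf("%s_%06d", records$family, seq_len(nrow(records)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write annotation records as BED6
#'
#' BED is 0-based half-open; the score field carries identity scaled to
#' 0-1000.
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  gr <- records_to_granges(records)
  gr$name <- records$family
  gr$score <- round(records$identity * 1000)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
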