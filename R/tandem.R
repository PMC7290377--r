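## Tandem periodicity, dotplots, monomer extraction and consensus building.

#' Mismatch-tolerant word-match dotplot segments
#'
#' Reports every maximal run of diagonal positions in which each k-length
#' window has at most `max_mismatch` mismatches, optionally on both strands.
#' Coordinates are 0-based half-open on the original inputs; minus-strand
#' segments are reported against `b`'s plus-strand frame with strand `"-"`.
#'
#' @param a,b Sequence strings.
#' @param word_size Window length k (>= 4).
#' @param max_mismatch Allowed mismatches per window (0 <= S < k).
#' @param both_strands Also scan `a` against the reverse complement of `b`.
#' @return data.frame: a_start, a_end, b_start, b_end, strand, mismatches.
#' @export
wordmatch_segments <- function(a, b, word_size = 10L, max_mismatch = 2L,
                               both_strands = FALSE) {
  check_residues(a, "a"); check_residues(b, "b")
  stopifnot(word_size >= 4, max_mismatch >= 0, max_mismatch < word_size)
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (word_size > nchar(a) || word_size > nchar(b)) return(empty)
  plus <- as.data.frame(wordmatch_cpp(a, b, word_size, max_mismatch))
  if (nrow(plus) > 0) plus$strand <- "+"
  out <- plus
  if (both_strands) {
    rc <- as.data.frame(wordmatch_cpp(a, reverse_complement(b),
                                      word_size, max_mismatch))
    if (nrow(rc) > 0) {
      L <- nchar(b)
      minus <- data.frame(a_start = rc$a_start, a_end = rc$a_end,
                          b_start = L - rc$b_end, b_end = L - rc$b_start,
                          strand = "-", mismatches = rc$mismatches,
                          stringsAsFactors = FALSE)
      out <- rbind(out, minus)
    }
  }
  if (nrow(out) == 0) return(empty)
  out <- out[, c("a_start", "a_end", "b_start", "b_end", "strand",
                 "mismatches")]
  out <- out[order(out$a_start, out$b_start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Windowed dotplot (dotmatcher-style)
#'
#' A point (i, j) is set iff the `window`-length gapless comparison starting
#' at (i, j) along the diagonal scores at least `threshold` under
#' match/mismatch scoring (+5/-4 by default, so the classic window 14 /
#' threshold 27 setting requires at least 7 matches).
#'
#' @param a,b Sequence strings.
#' @param window Window length in bp.
#' @param threshold Minimum window score.
#' @param match,mismatch Scoring parameters.
#' @return data.frame of set points: `i`, `j` (0-based window starts).
#' @export
windowed_dotplot <- function(a, b, window = 14L, threshold = 27,
                             match = 5, mismatch = -4) {
  check_residues(a, "a"); check_residues(b, "b")
  stopifnot(window >= 1, window <= nchar(a), window <= nchar(b))
  res <- windowed_dotplot_cpp(a, b, window, match, mismatch, threshold)
  out <- data.frame(i = res$i, j = res$j)
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  out
}

#' Estimate tandem period by autocorrelation
#'
#' Support at lag p is the fraction of positions whose base equals the base
#' one period away. The best-supported lag wins; a smaller lag within
#' `submultiple_tol` of the maximum is preferred (sub-multiple resolution).
#' Returns `NULL` when the best support falls below `min_support`.
#'
#' @param seq Sequence string.
#' @param min_period,max_period Search range (min >= 2; max <= length/2).
#' @param min_support Detection threshold on support (default 0.60).
#' @param submultiple_tol Support slack for preferring smaller periods.
#' @return A list of class `period_estimate` with `period`, `support`,
#'   `phase`, or `NULL`.
#' @export
estimate_period <- function(seq, min_period = 2L,
                            max_period = floor(nchar(seq) / 2),
                            min_support = 0.60, submultiple_tol = 0.05) {
  check_residues(seq)
  L <- nchar(seq)
  stopifnot(min_period >= 2, max_period >= min_period,
            max_period <= floor(L / 2))
  ch <- s2c(seq)
  lags <- min_period:max_period
  support <- vapply(lags, function(p) {
    x <- ch[seq_len(L - p)]
    y <- ch[(p + 1):L]
    mean(x == y & x != "N")
  }, numeric(1))
  best <- max(support)
  if (best < min_support) return(NULL)
  p <- lags[which(support >= best - submultiple_tol)[1]]
  sup <- support[match(p, lags)]
  structure(list(period = as.integer(p), support = sup,
                 phase = best_phase(ch, p)),
            class = "period_estimate")
}

## phase = offset in [0, p) maximizing mean identity between consecutive
## period-length blocks (gapless)
best_phase <- function(ch, p) {
  L <- length(ch)
  if (L < 2 * p) return(0L)
  scores <- vapply(0:(p - 1), function(o) {
    n_full <- (L - o) %/% p
    if (n_full < 2) return(-1)
    idx <- o + seq_len((n_full - 1) * p)
    mean(ch[idx] == ch[idx + p])
  }, numeric(1))
  as.integer(which.max(scores) - 1L)
}

#' Extract monomers from an array or multimeric clone
#'
#' In consensus mode the sequence is cut at successive best local alignments
#' of the reference; in period mode it is cut at `phase + n * period`.
#' Fragments longer than half the reference length are monomers; shorter
#' fragments are returned separately as partials.
#'
#' @param seq Array or multimeric clone string.
#' @param reference Either a reference monomer/consensus string, a
#'   `consensus_profile`, or a `period_estimate` from [estimate_period()].
#' @param min_identity Minimum local-alignment identity to accept a cut
#'   (consensus mode).
#' @param match,mismatch,gap Alignment scoring (consensus mode).
#' @return A list with `monomers` (named character vector), `intervals`
#'   (data.frame seq start/end, 0-based half-open), and `partials`.
#' @export
extract_monomers <- function(seq, reference, min_identity = 0.5,
                             match = 2, mismatch = -3, gap = -5) {
  check_residues(seq)
  if (inherits(reference, "period_estimate")) {
    return(extract_by_period(seq, reference$period, reference$phase))
  }
  ref <- if (inherits(reference, "consensus_profile"))
    reference$residues else reference
  check_residues(ref, "reference")
  reflen <- nchar(ref)
  L <- nchar(seq)
  work <- seq
  hits <- list()
  repeat {
    al <- local_align(ref, work, match, mismatch, gap)
    span <- al$b_end - al$b_start
    if (al$score <= 0 || al$identity < min_identity ||
        span < 0.3 * reflen) break
    hits[[length(hits) + 1L]] <- c(start = al$b_start, end = al$b_end)
    # mask the matched region so the next round finds the next copy
    work <- paste0(substr(work, 1, al$b_start),
                   strrep("N", span),
                   substr(work, al$b_end + 1, L))
  }
  if (length(hits) == 0L)
    stop("no alignment of the reference above identity ", min_identity)
  iv <- do.call(rbind, hits)
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  segment_fragments(seq, iv[, "start"], iv[, "end"], reflen)
}

extract_by_period <- function(seq, period, phase = 0L) {
  L <- nchar(seq)
  starts <- seq(from = phase, to = L, by = period)
  cuts <- unique(c(0L, starts, L))
  cuts <- sort(cuts[cuts >= 0 & cuts <= L])
  starts <- head(cuts, -1); ends <- tail(cuts, -1)
  keep <- ends > starts
  segment_fragments(seq, starts[keep], ends[keep], period)
}

## classify fragments: monomer iff length > 50% of the reference length
segment_fragments <- function(seq, starts, ends, reflen) {
  lens <- ends - starts
  frag <- substring(seq, starts + 1, ends)
  is_mono <- lens > 0.5 * reflen
  mono <- frag[is_mono]
  names(mono) <- sprintf("monomer_%03d", seq_along(mono))
  part <- frag[!is_mono]
  if (length(part)) names(part) <- sprintf("partial_%03d", seq_along(part))
  list(monomers = mono,
       intervals = data.frame(start = as.integer(starts[is_mono]),
                              end = as.integer(ends[is_mono])),
       partials = part)
}

#' Majority-rule consensus of a monomer collection
#'
#' Monomers are multiply aligned ([progressive_msa()]); each column's
#' majority base is taken, ties broken in the fixed order A < C < G < T, and
#' columns that are majority-gap are dropped.
#'
#' @param monomers Character vector of monomer sequences (>= 1).
#' @return A list of class `consensus_profile` with `residues`,
#'   `column_support` (agreement fraction per kept column) and `n_monomers`.
#' @export
build_consensus <- function(monomers) {
  stopifnot(length(monomers) >= 1)
  if (length(monomers) == 1L) {
    return(structure(list(residues = unname(monomers[[1]]),
                          column_support = rep(1, nchar(monomers[[1]])),
                          n_monomers = 1L),
                     class = "consensus_profile"))
  }
  aln <- progressive_msa(monomers)
  mat <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(mat)
  keep <- colSums(mat == "-") <= n / 2
  mat <- mat[, keep, drop = FALSE]
  cons <- character(ncol(mat))
  supp <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    counts <- vapply(BASES, function(b) sum(mat[, j] == b), numeric(1))
    cons[j] <- BASES[which.max(counts)]   # which.max honors A<C<G<T order
    supp[j] <- max(counts) / n
  }
  structure(list(residues = c2s(cons), column_support = supp,
                 n_monomers = as.integer(n)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("consensus of", x$n_monomers, "monomers,", nchar(x$residues), "bp,",
      sprintf("mean column support %.3f\n", mean(x$column_support)))
  invisible(x)
}

#' Pairwise identity matrix of monomers
#'
#' Without a mask, identities come from pairwise global alignments (matches /
#' alignment columns). With mask intervals on the reference frame, the
#' monomers are aligned together with the reference and identities are
#' computed over unmasked alignment columns only (columns gapped in both
#' members of a pair are also excluded).
#'
#' @param monomers Named character vector (>= 2).
#' @param mask Optional data.frame of 0-based half-open intervals
#'   (`start`, `end`) on the reference.
#' @param reference Reference/consensus string (required with `mask`).
#' @param match,mismatch,gap Alignment scoring.
#' @return Symmetric numeric matrix of identities in \[0, 1\].
#' @export
identity_matrix <- function(monomers, mask = NULL, reference = NULL,
                            match = 2, mismatch = -3, gap = -5) {
  stopifnot(length(monomers) >= 2)
  ids <- names(monomers)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_along(monomers))
  n <- length(monomers)
  M <- matrix(1, n, n, dimnames = list(ids, ids))
  if (is.null(mask)) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      al <- global_align(monomers[[i]], monomers[[j]], match, mismatch, gap)
      M[i, j] <- M[j, i] <- al$identity
    }
    return(M)
  }
  if (is.null(reference))
    stop("a reference sequence is required to map mask intervals")
  ref <- if (inherits(reference, "consensus_profile"))
    reference$residues else reference
  aln <- progressive_msa(c(.ref = ref, monomers))
  mat <- do.call(rbind, strsplit(aln, ""))
  refrow <- mat[1, ]
  refpos <- cumsum(refrow != "-") - 1L  # reference position per column
  masked <- rep(FALSE, ncol(mat))
  for (k in seq_len(nrow(mask))) {
    masked <- masked | (refrow != "-" & refpos >= mask$start[k] &
                          refpos < mask$end[k])
  }
  if (all(masked)) stop("mask covers all reference columns")
  mm <- mat[-1, !masked, drop = FALSE]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- mm[i, ]; b <- mm[j, ]
    use <- !(a == "-" & b == "-")
    if (!any(use)) stop("no unmasked columns shared by a monomer pair")
    M[i, j] <- M[j, i] <- mean(a[use] == b[use] & a[use] != "-" &
                                 a[use] != "N")
  }
  M
}
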