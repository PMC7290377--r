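## Genome-wide satellite similarity search (seed-and-extend), hit clustering,
## target-site-duplication detection and satellite-TE association calls.

#' Seed-and-extend similarity scan
#'
#' Exact 11-mer seeds anchor candidate regions that are
#' extended by local alignment; hits passing the identity and query-coverage
#' floors are kept, tandem neighbours are recovered by walking outward from
#' accepted hits one query-length at a time, and overlapping same-strand hits
#' are merged keeping the best identity. Both strands are scanned.
#'
#' @param query Query consensus string (shorter than the genome).
#' @param genome Genome/chromosome string.
#' @param min_identity Minimum alignment identity (matches / columns).
#' @param min_coverage Minimum fraction of the query length aligned.
#' @param word Seed length (default 11).
#' @param seqid Label recorded in the output.
#' @param match,mismatch,gap Alignment scoring.
#' @return data.frame: seqid, start, end (0-based half-open), strand,
#'   identity, coverage, score, query.
#' @export
scan_similarity <- function(query, genome, min_identity = 0.8,
                            min_coverage = 0.8, word = 11L, seqid = "seq",
                            match = 2, mismatch = -3, gap = -5) {
  check_residues(query, "query"); check_residues(genome, "genome")
  qlen <- nchar(query)
  if (qlen >= nchar(genome)) stop("query must be shorter than the genome")
  word <- as.integer(min(word, qlen))
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else reverse_complement(query)
    cand <- seed_candidates(q, genome, word, qlen)
    accepted <- list()
    covered <- integer(0)
    try_window <- function(ws, we) {
      ws <- max(0L, as.integer(ws)); we <- min(nchar(genome), as.integer(we))
      if (we - ws < 0.5 * qlen) return(NULL)
      al <- sw_align_cpp(q, substr(genome, ws + 1, we), match, mismatch, gap)
      if (al$score <= 0) return(NULL)
      ident <- alignment_identity(al$aligned_a, al$aligned_b)
      cov <- (al$a_end - al$a_start) / qlen
      if (ident < min_identity || cov < min_coverage) return(NULL)
      list(start = ws + al$b_start, end = ws + al$b_end,
           identity = ident, coverage = cov, score = al$score)
    }
    overlaps_accepted <- function(h) {
      for (a in accepted) {
        ov <- min(h$end, a$end) - max(h$start, a$start)
        if (ov > 0.5 * min(h$end - h$start, a$end - a$start)) return(TRUE)
      }
      FALSE
    }
    queue <- list()
    for (cd in cand) {
      h <- try_window(cd[1] - 15L, cd[2] + 15L)
      if (!is.null(h) && !overlaps_accepted(h)) {
        accepted[[length(accepted) + 1L]] <- h
        queue[[length(queue) + 1L]] <- h
      }
    }
    # walk outward to recover tandem neighbours missed by seeding
    while (length(queue) > 0) {
      h <- queue[[1]]; queue[[1]] <- NULL
      for (dir in c(1L, -1L)) {
        nb <- if (dir > 0)
          try_window(h$end - 5L, h$end + round(1.3 * qlen))
        else
          try_window(h$start - round(1.3 * qlen), h$start + 5L)
        if (!is.null(nb) && !overlaps_accepted(nb)) {
          accepted[[length(accepted) + 1L]] <- nb
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
    if (length(accepted)) {
      df <- do.call(rbind, lapply(accepted, as.data.frame))
      df$strand <- strand
      hits[[strand]] <- df
    }
  }
  if (length(hits) == 0)
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      score = numeric(), query = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- merge_hits(out)
  out$seqid <- seqid
  out$query <- if (!is.null(names(query))) names(query) else "query"
  rownames(out) <- NULL
  out[, c("seqid", "start", "end", "strand", "identity", "coverage",
          "score", "query")]
}

## cluster exact-seed diagonals into candidate genome windows; the genome
## k-mer index is a plain substring vector matched by hash against the
## query's k-mer set (fast at the Mb scale used here)
seed_candidates <- function(q, genome, word, qlen) {
  nq <- nchar(q)
  starts <- 1:(nq - word + 1)
  kmers <- substring(q, starts, starts + word - 1)
  keep <- !grepl("N", kmers, fixed = TRUE)
  if (!any(keep)) return(list())
  kmers <- kmers[keep]; qoff <- starts[keep] - 1L
  ng <- nchar(genome)
  gk <- substring(genome, 1:(ng - word + 1), word:ng)
  hit <- match(gk, kmers)
  gpos <- which(!is.na(hit))
  if (length(gpos) == 0) return(list())
  offs_list <- split(qoff, kmers)[kmers[hit[gpos]]]
  diags <- rep(gpos - 1L, lengths(offs_list)) - unlist(offs_list,
                                                       use.names = FALSE)
  diags <- sort(unique(diags))
  brk <- which(diff(diags) > 0.5 * qlen)
  grp <- rep(seq_len(length(brk) + 1),
             times = diff(c(0, brk, length(diags))))
  lapply(split(diags, grp), function(d) c(min(d), max(d) + qlen))
}

## merge overlapping same-strand hits, keeping the best identity
merge_hits <- function(df) {
  out <- list()
  for (s in unique(df$strand)) {
    d <- df[df$strand == s, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    kept <- list()
    for (r in seq_len(nrow(d))) {
      h <- d[r, ]
      merged <- FALSE
      for (k in seq_along(kept)) {
        a <- kept[[k]]
        ov <- min(h$end, a$end) - max(h$start, a$start)
        if (ov > 0.5 * min(h$end - h$start, a$end - a$start)) {
          if (h$identity > a$identity) kept[[k]] <- h
          merged <- TRUE
          break
        }
      }
      if (!merged) kept[[length(kept) + 1L]] <- h
    }
    out[[s]] <- do.call(rbind, kept)
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Single-linkage clustering of similarity hits (75/75 rule)
#'
#' Two hit sequences link when their local alignment identity reaches
#' `min_identity` over at least `min_length_frac` of the longer sequence.
#' Connected components form clusters; a majority-rule consensus is built
#' per cluster.
#'
#' @param hits data.frame from [scan_similarity()] (may span chromosomes).
#' @param genomes Named character vector of the scanned sequences.
#' @param min_identity,min_length_frac Linkage thresholds (default 0.75).
#' @return A list of class `hit_clusters`: `membership` (integer per hit),
#'   `consensus` (character per cluster), `n_clusters`.
#' @export
cluster_hits <- function(hits, genomes, min_identity = 0.75,
                         min_length_frac = 0.75) {
  if (nrow(hits) < 1) stop("need at least one hit")
  seqs <- vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(genomes[[hits$seqid[i]]], hits$start[i] + 1, hits$end[i])
    if (hits$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      longer <- max(nchar(seqs[i]), nchar(seqs[j]))
      al <- local_align(seqs[i], seqs[j])
      span <- max(al$a_end - al$a_start, al$b_end - al$b_start)
      if (al$identity >= min_identity && span >= min_length_frac * longer) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, sort(unique(roots)))
  cons <- vapply(sort(unique(membership)), function(cl)
    build_consensus(seqs[membership == cl])$residues, character(1))
  structure(list(membership = membership, consensus = cons,
                 n_clusters = length(cons)),
            class = "hit_clusters")
}

#' Detect a target-site duplication around an element
#'
#' Finds the longest exact match (2..`max_len` bp) between the suffix of the
#' left flank and the prefix of the right flank, anchored at the element
#' boundaries.
#'
#' @param genome Chromosome string.
#' @param element_start,element_end 0-based half-open element interval.
#' @param max_len Longest TSD considered (default 12).
#' @return A list with `length` and `seq`, or `NULL` when no anchored match
#'   of >= 2 bp exists (or the element sits at a contig edge, with a
#'   warning).
#' @export
detect_tsd <- function(genome, element_start, element_end, max_len = 12L) {
  n <- nchar(genome)
  if (element_start < max_len || element_end + max_len > n) {
    warning("element too close to a contig edge for TSD detection")
    return(NULL)
  }
  for (m in rev(2:max_len)) {
    left <- substr(genome, element_start - m + 1, element_start)
    right <- substr(genome, element_end + 1, element_end + m)
    if (left == right) return(list(length = m, seq = left))
  }
  NULL
}

#' Classify a satellite-TE association
#'
#' `tandem_in_te`: at least two hits inside the element with inter-hit gaps
#' at most `gap_frac` of the query length. `dispersed_in_te`: at least one
#' inside hit not meeting the tandem rule. `standalone_array`: no element and
#' at least two adjacent hits. Otherwise `none`.
#'
#' @param sat_hits data.frame from [scan_similarity()] (one chromosome).
#' @param element Optional c(start, end) 0-based half-open element interval.
#' @param query_length Query monomer length in bp.
#' @param gap_frac Tandem gap tolerance as a fraction of the query length.
#' @return A list of class `te_association`: `arrangement`, `n_inside`,
#'   `element`, `hits`.
#' @export
classify_association <- function(sat_hits, element = NULL, query_length,
                                 gap_frac = 0.25) {
  h <- sat_hits[order(sat_hits$start), , drop = FALSE]
  arrangement <- "none"
  n_inside <- 0L
  if (!is.null(element)) {
    inside <- h$start >= element[1] & h$end <= element[2]
    n_inside <- sum(inside)
    if (n_inside >= 2) {
      hi <- h[inside, ]
      gaps <- hi$start[-1] - head(hi$end, -1)
      arrangement <- if (all(gaps <= gap_frac * query_length))
        "tandem_in_te" else "dispersed_in_te"
    } else if (n_inside == 1) {
      arrangement <- "dispersed_in_te"
    }
  } else if (nrow(h) >= 2) {
    gaps <- h$start[-1] - head(h$end, -1)
    if (any(gaps <= gap_frac * query_length)) arrangement <- "standalone_array"
  }
  structure(list(arrangement = arrangement, n_inside = n_inside,
                 element = element, hits = h),
            class = "te_association")
}

#' @export
print.te_association <- function(x, ...) {
  cat("satellite-TE association:", x$arrangement,
      sprintf("(%d hit(s) inside element)\n", x$n_inside))
  invisible(x)
}
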