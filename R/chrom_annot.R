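## Annotation of satellite monomers along pseudochromosomes and
## classification of per-chromosome distribution patterns.

#' Annotate chromosomes with a satellite family consensus
#'
#' Runs the seed-and-extend scan on every chromosome and strand at the given
#' identity and query-coverage floors (the 80%/80% operationalization of
#' annotation "at 80% similarity").
#'
#' @param chroms Named character vector of chromosome sequences.
#' @param family A list with `name` and `consensus` (or a
#'   `consensus_profile` plus `name`).
#' @param min_identity,min_coverage Floors (default 0.80 both).
#' @param word Seed length for the scan.
#' @return Annotation records data.frame (see [annotation_records()]) sorted
#'   by (chromosome, start), with identity and coverage columns.
#' @export
annotate_chromosomes <- function(chroms, family, min_identity = 0.80,
                                 min_coverage = 0.80, word = 11L) {
  stopifnot(!is.null(names(chroms)))
  cons <- if (inherits(family, "consensus_profile"))
    family$residues else family$consensus
  fname <- if (!is.null(family$name)) family$name else "satellite"
  recs <- list()
  for (cn in names(chroms)) {
    h <- scan_similarity(cons, chroms[[cn]], min_identity = min_identity,
                         min_coverage = min_coverage, word = word,
                         seqid = cn)
    if (nrow(h) > 0) {
      h$family <- fname
      recs[[cn]] <- h
    }
  }
  if (length(recs) == 0)
    return(annotation_records(character(), integer(), integer(),
                              character(), character(), numeric()))
  out <- do.call(rbind, recs)
  out <- out[order(out$seqid, out$start), ]
  rownames(out) <- NULL
  out[, c("seqid", "start", "end", "strand", "family", "identity",
          "coverage")]
}

#' Per-chromosome record counts and presence count
#'
#' @param records Annotation records.
#' @param chrom_names Full chromosome inventory (absences are zero-filled).
#' @return A list with `counts` (named integer vector over the inventory)
#'   and `presence` (number of chromosomes with at least one record).
#' @export
count_per_chromosome <- function(records, chrom_names) {
  unknown <- setdiff(unique(records$seqid), chrom_names)
  if (length(unknown) > 0)
    stop("records reference unknown chromosomes: ",
         paste(unknown, collapse = ", "))
  counts <- setNames(integer(length(chrom_names)), chrom_names)
  if (nrow(records) > 0) {
    tab <- table(records$seqid)
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, presence = sum(counts > 0))
}

#' Classify the distribution pattern of a family along chromosomes
#'
#' Records on one chromosome are chained into runs (inter-record gap at most
#' `run_gap`). Per chromosome: `absent` (no records); `central` (>= 80% of
#' records within the middle third and at most 2 runs); `dispersed` (records
#' span >= 80% of the chromosome, runs are mostly isolated monomers - at
#' least `max(3, records/2)` runs - and no run holds more than 30% of the
#' records); `multisite` otherwise (>= 3 clustered runs, or off-center
#' placement). The family pattern is the modal per-chromosome pattern among
#' chromosomes carrying records.
#'
#' @param records Annotation records for one family.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param run_gap Maximum intra-run gap in bp (default 100 kb).
#' @return A list of class `distribution_call`: `per_chromosome` (data.frame
#'   seqid, n, runs, span_frac, central_frac, pattern) and `pattern` (modal).
#' @export
classify_distribution <- function(records, chrom_lengths, run_gap = 1e5) {
  stopifnot(!is.null(names(chrom_lengths)))
  per <- lapply(names(chrom_lengths), function(cn) {
    r <- records[records$seqid == cn, , drop = FALSE]
    clen <- chrom_lengths[[cn]]
    if (nrow(r) == 0)
      return(data.frame(seqid = cn, n = 0L, runs = 0L, span_frac = 0,
                        central_frac = NA_real_, pattern = "absent",
                        stringsAsFactors = FALSE))
    r <- r[order(r$start), ]
    gaps <- r$start[-1] - head(r$end, -1)
    run_id <- cumsum(c(1L, as.integer(gaps > run_gap)))
    run_sizes <- as.integer(table(run_id))
    n <- nrow(r)
    span <- (max(r$end) - min(r$start)) / clen
    mid <- r$start >= clen / 3 & r$end <= 2 * clen / 3
    central_frac <- mean(mid)
    pattern <- if (central_frac >= 0.8 && length(run_sizes) <= 2) {
      "central"
    } else if (span >= 0.8 && length(run_sizes) >= max(3, n / 2) &&
               max(run_sizes) <= 0.3 * n) {
      "dispersed"
    } else {
      "multisite"
    }
    data.frame(seqid = cn, n = n, runs = length(run_sizes),
               span_frac = span, central_frac = central_frac,
               pattern = pattern, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  present <- per$pattern[per$pattern != "absent"]
  pattern <- if (length(present) == 0) "absent" else {
    tab <- table(factor(present,
                        levels = c("central", "multisite", "dispersed")))
    names(tab)[which.max(tab)]   # ties resolved central > multisite > disp.
  }
  structure(list(per_chromosome = per, pattern = pattern),
            class = "distribution_call")
}

#' @export
print.distribution_call <- function(x, ...) {
  cat("family distribution pattern:", x$pattern, "\n")
  print(table(x$per_chromosome$pattern))
  invisible(x)
}
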