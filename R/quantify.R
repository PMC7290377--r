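## Copy-number estimation from read-cluster genome proportions, amplicon
## ladder prediction for outward-facing primers, and family reports.

#' Copy number from genome proportion
#'
#' copy number = floor(genome size x genome proportion / monomer length).
#' Truncation (not rounding) is used; it uniquely reproduces published
#' read-cluster copy numbers with fractional quotients.
#'
#' @param genome_size Genome size in bp (> 0).
#' @param proportion Genome proportion as a fraction (> 0).
#' @param monomer_length Monomer length in bp (> 0).
#' @return Integer copy number.
#' @export
copy_number <- function(genome_size, proportion, monomer_length) {
  if (any(c(genome_size, proportion, monomer_length) <= 0))
    stop("genome_size, proportion and monomer_length must all be positive")
  as.integer(floor(genome_size * proportion / monomer_length))
}

#' Satellite family descriptors
#'
#' Read-cluster characteristics of the six VaccSat satellite families of
#' highbush blueberry (diploid reference genotype, genome size 470 Mb):
#' monomer length range, GC content, and genome proportion. The
#' `canonical_length` column is the single length used for copy-number
#' arithmetic (range midpoint for VaccSat5; both range bounds of VaccSat7
#' are conventionally reported).
#'
#' @return data.frame: family, length_min, length_max, canonical_length,
#'   gc, proportion.
#' @export
vaccsat_families <- function() {
  data.frame(
    family = c("VaccSat1", "VaccSat2", "VaccSat3", "VaccSat4",
               "VaccSat5", "VaccSat6", "VaccSat7"),
    length_min = c(146L, 238L, 154L, 101L, 36L, 49L, 49L),
    length_max = c(147L, 238L, 154L, 101L, 38L, 49L, 70L),
    canonical_length = c(146L, 238L, 154L, 101L, 37L, 49L, 70L),
    gc = c(0.184, 0.409, 0.211, 0.174, 0.199, 0.224, 0.314),
    proportion = c(0.00999, 0.00124, 0.0036, 0.00050, 0.00015, 0.00015,
                   0.00069),
    stringsAsFactors = FALSE)
}

#' Predict the amplicon ladder of an outward-facing primer pair
#'
#' First band = (monomer length - forward primer start) + reverse primer
#' end; band n = first band + (n - 1) x monomer length. When primer
#' sequences and a consensus are supplied, secondary primer binding sites
#' are enumerated and all cross-products of site pairs are reported as
#' off-ladder sizes.
#'
#' @param primers A [primer_pair()].
#' @param monomer_length Monomer length in bp.
#' @param n_max Largest multimer order.
#' @param consensus Optional consensus monomer string for secondary-site
#'   search.
#' @param max_mismatch Mismatches tolerated when matching primer sequences.
#' @return A list of class `ladder_prediction` with `bands` (length
#'   `n_max`), `off_ladder` (sorted unique sizes not on the main ladder) and
#'   `monomer_length`.
#' @export
predict_amplicon_ladder <- function(primers, monomer_length, n_max = 4L,
                                    consensus = NULL, max_mismatch = 0L) {
  stopifnot(inherits(primers, "primer_pair"), n_max >= 1)
  L <- as.integer(monomer_length)
  if (primers$forward_end > L || primers$reverse_end > L)
    stop("primer coordinates exceed the monomer length")
  first <- (L - primers$forward_start) + primers$reverse_end
  flen <- primers$forward_end - primers$forward_start
  rlen <- primers$reverse_end - primers$reverse_start
  if (first <= flen + rlen)
    stop("primers overlap a monomer junction: first band (", first,
         " bp) does not exceed the combined primer length")
  bands <- first + (seq_len(n_max) - 1L) * L
  off <- integer(0)
  if (!is.null(consensus) && !is.null(primers$forward_seq) &&
      !is.null(primers$reverse_seq)) {
    subj <- Biostrings::DNAString(consensus)
    fm <- Biostrings::matchPattern(primers$forward_seq, subj,
                                   max.mismatch = max_mismatch)
    rm_ <- Biostrings::matchPattern(
      reverse_complement(primers$reverse_seq), subj,
      max.mismatch = max_mismatch)
    fstarts <- Biostrings::start(fm) - 1L
    rends <- Biostrings::end(rm_)
    for (f in fstarts) for (r in rends) for (n in seq_len(n_max)) {
      size <- (L - f) + r + (n - 1L) * L
      if (!size %in% bands && size > 0) off <- c(off, size)
    }
    off <- sort(unique(off))
  }
  structure(list(bands = bands, off_ladder = off, monomer_length = L,
                 first_band = first),
            class = "ladder_prediction")
}

#' @export
print.ladder_prediction <- function(x, ...) {
  cat("amplicon ladder (monomer", x$monomer_length, "bp):",
      paste(x$bands, collapse = ", "), "bp\n")
  if (length(x$off_ladder))
    cat("off-ladder products:", paste(x$off_ladder, collapse = ", "), "bp\n")
  invisible(x)
}

#' Assemble a per-family report
#'
#' Aggregates the outputs of the characterization stages into one
#' machine-readable document.
#'
#' @param family Family descriptor list (`name`, `consensus`, optional
#'   metadata such as `gc`, `proportion`, `monomer_length`).
#' @param monomer_stats Optional list/data.frame of monomer statistics.
#' @param hor Optional `hor_model`.
#' @param specificity Optional `specificity_result`.
#' @param te_calls Optional list of `te_association` calls.
#' @param distribution Optional `distribution_call`.
#' @param copy_number Optional integer from [copy_number()].
#' @return A list of class `family_report`.
#' @export
family_report <- function(family, monomer_stats = NULL, hor = NULL,
                          specificity = NULL, te_calls = NULL,
                          distribution = NULL, copy_number = NULL) {
  if (is.null(monomer_stats) && is.null(hor) && is.null(specificity) &&
      is.null(te_calls) && is.null(distribution) && is.null(copy_number))
    stop("at least one stage output is required")
  rep <- list(
    family = family$name,
    consensus = family$consensus,
    monomer_stats = monomer_stats,
    hor = if (!is.null(hor)) list(
      n_subunits = nrow(hor$subunits),
      subunits = hor$subunits[, c("label", "start", "end")],
      lag = hor$lag, support = hor$support) else NULL,
    specificity = if (!is.null(specificity)) list(
      score = specificity$score, verdict = specificity$verdict,
      monophyletic = specificity$monophyletic_species) else NULL,
    te_associations = if (!is.null(te_calls)) lapply(te_calls, function(x)
      list(arrangement = x$arrangement, n_inside = x$n_inside)) else NULL,
    distribution = if (!is.null(distribution))
      distribution$pattern else "absent",
    copy_number = copy_number)
  structure(rep, class = "family_report")
}

#' Serialize a family report to JSON
#'
#' @param report A `family_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON text (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.family_report <- function(x, ...) {
  cat("== family report:", x$family, "==\n")
  if (!is.null(x$consensus))
    cat("consensus:", nchar(x$consensus), "bp\n")
  if (!is.null(x$hor))
    cat("HOR:", x$hor$n_subunits, "subunit(s), lag",
        ifelse(is.na(x$hor$lag), "-", x$hor$lag), "\n")
  if (!is.null(x$specificity))
    cat(sprintf("specificity score %.1f (%s)\n", x$specificity$score,
                if (isTRUE(x$specificity$verdict)) "species-specific"
                else "not species-specific"))
  if (!is.null(x$te_associations))
    cat("TE associations:",
        paste(vapply(x$te_associations, `[[`, "", "arrangement"),
              collapse = ", "), "\n")
  cat("distribution:", x$distribution, "\n")
  if (!is.null(x$copy_number)) cat("copy number:", x$copy_number, "\n")
  invisible(x)
}
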