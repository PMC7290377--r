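## Synthetic satellite-genome generator with machine-readable planted truth.
## All functions are deterministic under their seed arguments; child seeds are
## derived arithmetically so that nested calls stay reproducible.

#' Mutation model for synthetic sequence divergence
#'
#' Per-site independent substitutions (to a uniformly chosen different base),
#' single-base insertions (after a site) and deletions. All rates must lie in
#' \[0, 0.5).
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-site
#'   probabilities.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `mutation_model`.
#' @export
mutation_model <- function(substitution_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, seed = NULL) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 0.5))
    stop("mutation rates must lie in [0, 0.5)")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 seed = seed),
            class = "mutation_model")
}

#' Random i.i.d. nucleotide sequence
#'
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc Target GC fraction in \[0, 1\].
#' @param seed Integer seed for reproducibility.
#' @return A sequence string.
#' @export
make_random_sequence <- function(length, gc = 0.5, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    c2s(sample(BASES, length, replace = TRUE, prob = p))
  })
}

#' Apply a mutation model to a sequence
#'
#' Substitutions replace a base by a uniformly chosen different base;
#' insertions add one random base after a site; deletions drop the site.
#' Events are drawn independently per site.
#'
#' @param seq Sequence string.
#' @param model A [mutation_model()].
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(seq, model) {
  check_residues(seq)
  stopifnot(inherits(model, "mutation_model"))
  if (model$substitution_rate == 0 && model$insertion_rate == 0 &&
      model$deletion_rate == 0) return(seq)
  with_seed(model$seed, {
    ch <- s2c(seq)
    n <- length(ch)
    sub <- runif(n) < model$substitution_rate
    if (any(sub)) {
      ch[sub] <- vapply(ch[sub], function(b) {
        if (b == "N") "N" else sample(setdiff(BASES, b), 1L)
      }, character(1))
    }
    del <- runif(n) < model$deletion_rate
    ins <- runif(n) < model$insertion_rate
    if (any(del) || any(ins)) {
      pieces <- ifelse(del, "", ch)
      if (any(ins)) {
        newb <- sample(BASES, sum(ins), replace = TRUE)
        pieces[ins] <- paste0(pieces[ins], newb)
      }
      c2s(pieces)
    } else c2s(ch)
  })
}

#' Higher-order-repeat specification
#'
#' Ordered subunits with unique labels. Labels sharing a stem before `-`
#' (e.g. `S1-1`, `S1-2`) are variants of one subunit: the first instance keeps
#' its residues and later instances are re-derived from it by substitution-only
#' mutation at `variant_divergence` when their residues are given as `NA`.
#'
#' @param subunits Named character vector (names = labels, values = residues;
#'   `NA` for a variant to be derived from the first instance of its stem).
#' @param variant_divergence Extra substitution divergence applied between
#'   repeated variants of the same subunit.
#' @return A list of class `hor_spec`.
#' @export
hor_spec <- function(subunits, variant_divergence = 0) {
  stopifnot(length(subunits) >= 1, !is.null(names(subunits)),
            !anyDuplicated(names(subunits)),
            variant_divergence >= 0, variant_divergence < 0.5)
  structure(list(subunits = subunits,
                 variant_divergence = variant_divergence),
            class = "hor_spec")
}

#' Build a monomer from an HOR specification
#'
#' Concatenates the subunits; repeated variants of one subunit (labels with a
#' shared stem, e.g. `S1-1`/`S1-2`) are mutated copies of the first variant at
#' the spec's `variant_divergence` (substitutions only, so planted subunit
#' boundaries stay exact).
#'
#' @param spec An [hor_spec()].
#' @param seed Integer seed used for variant derivation.
#' @return A list with `monomer` (string) and `subunits` (data.frame with
#'   label, start, end; 0-based half-open).
#' @export
build_hor_monomer <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "hor_spec"))
  labels <- names(spec$subunits)
  stems <- sub("-.*$", "", labels)
  residues <- as.character(spec$subunits)
  for (i in seq_along(residues)) {
    if (is.na(residues[i])) {
      first <- match(stems[i], stems)
      if (first == i || is.na(residues[first]))
        stop("variant ", labels[i], " has no seed residues to derive from")
      mm <- mutation_model(substitution_rate = spec$variant_divergence,
                           seed = child_seed(seed, i))
      residues[i] <- apply_mutations(residues[first], mm)
    }
  }
  lens <- nchar(residues)
  ends <- cumsum(lens)
  list(monomer = c2s(residues),
       subunits = data.frame(label = labels,
                             start = as.integer(ends - lens),
                             end = as.integer(ends),
                             stringsAsFactors = FALSE))
}

#' Build a tandem array from a monomer template
#'
#' Head-to-tail copies, each independently mutated from the shared template
#' (star phylogeny).
#'
#' @param monomer Template monomer string.
#' @param copies Number of copies (>= 1).
#' @param model A [mutation_model()] applied independently per copy.
#' @return A list with `array` (string) and `monomers` (data.frame with
#'   copy, start, end; 0-based half-open intervals tiling the array).
#' @export
build_array <- function(monomer, copies, model = mutation_model()) {
  check_residues(monomer)
  stopifnot(copies >= 1)
  seqs <- character(copies)
  for (i in seq_len(copies)) {
    m <- model
    m$seed <- child_seed(model$seed, i)
    seqs[i] <- apply_mutations(monomer, m)
  }
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  list(array = c2s(seqs),
       monomers = data.frame(copy = seq_len(copies),
                             start = as.integer(ends - lens),
                             end = as.integer(ends),
                             stringsAsFactors = FALSE))
}

#' Build a transposable element carrying satellite units
#'
#' `ltr_retro` builds LTR + internal + identical LTR with the satellite
#' unit(s) embedded at the same position inside each LTR (solo-LTR-like
#' capture). `tir_dna` builds terminal inverted repeats flanking an internal
#' region that carries the units, adjacent when `arrangement = "tandem"` or
#' separated by random spacers when `"single"`/dispersed.
#'
#' @param kind `"ltr_retro"` or `"tir_dna"`.
#' @param internal Internal (between-terminal-repeats) sequence.
#' @param sat_units Character vector of satellite unit sequences.
#' @param arrangement `"tandem"` (adjacent units) or `"single"` (units
#'   separated by random spacers; for `ltr_retro`, one unit per LTR).
#' @param tsd_length Target-site-duplication length created at insertion
#'   (0, 3, 8 or 9 by default; other values allowed via `allow_any_tsd`).
#' @param seed Integer seed.
#' @param ltr_length,tir_length Terminal repeat lengths.
#' @param gc Backbone GC for generated terminal repeats / spacers.
#' @param allow_any_tsd Permit TSD lengths outside the default set.
#' @return A list of class `te_element` with `seq`, `features` (element-local
#'   0-based intervals: terminal repeats and sat units), `tsd_length`, `kind`.
#' @export
build_te_with_satellite <- function(kind = c("ltr_retro", "tir_dna"),
                                    internal, sat_units,
                                    arrangement = c("single", "tandem"),
                                    tsd_length = 0, seed = NULL,
                                    ltr_length = 200L, tir_length = 25L,
                                    gc = 0.38, allow_any_tsd = FALSE) {
  kind <- match.arg(kind)
  arrangement <- match.arg(arrangement)
  if (!allow_any_tsd && !tsd_length %in% c(0, 3, 8, 9))
    stop("tsd_length must be one of 0, 3, 8, 9 (or set allow_any_tsd)")
  if (length(sat_units) < 1) stop("sat_units must be non-empty")
  if (arrangement == "tandem" && length(sat_units) < 2)
    stop("tandem arrangement needs at least 2 satellite units")
  check_residues(internal, "internal")
  feat <- function(label, start, end, family = NA_character_)
    data.frame(kind = label, start = as.integer(start), end = as.integer(end),
               family = family, stringsAsFactors = FALSE)
  with_seed(seed, {
    if (kind == "ltr_retro") {
      ltr_core <- make_random_sequence(ltr_length, gc)
      embed_at <- floor(ltr_length / 3)
      unit <- sat_units[[1]]
      ltr <- paste0(substr(ltr_core, 1, embed_at), unit,
                    substr(ltr_core, embed_at + 1, ltr_length))
      llen <- nchar(ltr)
      seqs <- paste0(ltr, internal, ltr)
      off2 <- llen + nchar(internal)
      features <- rbind(
        feat("ltr", 0, llen),
        feat("sat_unit", embed_at, embed_at + nchar(unit)),
        feat("ltr", off2, off2 + llen),
        feat("sat_unit", off2 + embed_at, off2 + embed_at + nchar(unit)))
    } else {
      tir <- make_random_sequence(tir_length, gc)
      pad_l <- make_random_sequence(20L, gc)
      if (arrangement == "tandem") {
        block <- c2s(sat_units)
        lens <- nchar(sat_units)
        ends <- cumsum(lens)
        ustart <- nchar(tir) + nchar(pad_l) + (ends - lens)
        uend <- nchar(tir) + nchar(pad_l) + ends
      } else {
        spacers <- vapply(seq_along(sat_units), function(i)
          make_random_sequence(30L, gc), character(1))
        pieces <- as.vector(rbind(sat_units, spacers))
        block <- c2s(pieces)
        lens <- nchar(sat_units)
        offs <- cumsum(c(0, head(nchar(sat_units) + 30L, -1)))
        ustart <- nchar(tir) + nchar(pad_l) + offs
        uend <- ustart + lens
      }
      pad_r <- make_random_sequence(20L, gc)
      seqs <- paste0(tir, pad_l, block, internal, pad_r,
                     reverse_complement(tir))
      total <- nchar(seqs)
      features <- rbind(
        feat("tir", 0, nchar(tir)),
        feat("sat_unit", ustart, uend),
        feat("tir", total - nchar(tir), total))
    }
    structure(list(seq = seqs, features = features,
                   tsd_length = as.integer(tsd_length), kind = kind,
                   arrangement = arrangement),
              class = "te_element")
  })
}

#' Assemble a chromosome with planted features
#'
#' Splices feature sequences into a random backbone at the given insertion
#' points and lifts all feature coordinates to the chromosome frame. A
#' transposable element with a non-zero `tsd_length` duplicates the backbone
#' k-mer at its insertion site on both sides (the biological TSD mechanism);
#' insertion sites whose flank context would extend the duplication into a
#' longer boundary-anchored match are shifted so the planted TSD length is
#' unambiguous.
#'
#' @param backbone_length Backbone length in bp.
#' @param placements List of placements, each a list with `obj` (either a
#'   `te_element`, a [build_array()] result, or a plain sequence string),
#'   `position` (0-based backbone insertion point), optional `strand`
#'   (`"+"`/`"-"`) and optional `family` label.
#' @param seed Integer seed for the backbone.
#' @param gc Backbone GC content.
#' @return A list with `seq` (chromosome string) and `truth` (data.frame:
#'   kind, family, start, end, strand, attr; 0-based half-open chromosome
#'   coordinates).
#' @export
assemble_chromosome <- function(backbone_length, placements = list(),
                                seed = NULL, gc = 0.38) {
  stopifnot(backbone_length >= 1)
  backbone <- make_random_sequence(backbone_length, gc, seed = seed)
  if (length(placements) == 0L)
    return(list(seq = backbone,
                truth = data.frame(kind = character(), family = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), attr = character(),
                                   stringsAsFactors = FALSE)))
  pos <- vapply(placements, function(p) as.integer(p$position), integer(1))
  if (anyDuplicated(pos)) stop("overlapping placements: duplicated positions")
  if (any(pos < 0) || any(pos > backbone_length))
    stop("placement positions must lie within the backbone")
  ord <- order(pos)
  placements <- placements[ord]
  pos <- pos[ord]

  out_pieces <- character(0)
  truth <- list()
  cursor <- 0L   # consumed backbone prefix
  offset <- 0L   # length of assembled output so far
  for (idx in seq_along(placements)) {
    p <- placements[[idx]]
    strand <- if (is.null(p$strand)) "+" else p$strand
    family <- if (is.null(p$family)) NA_character_ else p$family
    obj <- p$obj
    ins_pos <- pos[idx]

    if (inherits(obj, "te_element") && obj$tsd_length > 0) {
      ins_pos <- resolve_tsd_site(backbone, ins_pos, obj$tsd_length)
    }
    seg <- substr(backbone, cursor + 1, ins_pos)
    out_pieces <- c(out_pieces, seg)
    offset <- offset + nchar(seg)
    cursor <- ins_pos

    if (inherits(obj, "te_element")) {
      feats <- obj$features
      fseq <- obj$seq
      tlen <- obj$tsd_length
      if (strand == "-") {
        L <- nchar(fseq)
        fseq <- reverse_complement(fseq)
        feats <- transform(feats, start2 = L - end, end2 = L - start)
        feats$start <- feats$start2; feats$end <- feats$end2
        feats$start2 <- feats$end2 <- NULL
      }
      if (tlen > 0) {
        tsd <- substr(backbone, cursor + 1, cursor + tlen)
        out_pieces <- c(out_pieces, tsd)
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "tsd", family = family, start = offset,
          end = offset + tlen, strand = strand, attr = tsd,
          stringsAsFactors = FALSE)
        offset <- offset + tlen
      }
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "te", family = family, start = offset,
        end = offset + nchar(fseq), strand = strand,
        attr = obj$kind, stringsAsFactors = FALSE)
      if (nrow(feats) > 0)
        truth[[length(truth) + 1L]] <- data.frame(
          kind = feats$kind, family = family,
          start = offset + feats$start, end = offset + feats$end,
          strand = strand, attr = NA_character_, stringsAsFactors = FALSE)
      out_pieces <- c(out_pieces, fseq)
      offset <- offset + nchar(fseq)
      if (tlen > 0) {
        tsd <- substr(backbone, cursor + 1, cursor + tlen)
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "tsd", family = family, start = offset,
          end = offset + tlen, strand = strand, attr = tsd,
          stringsAsFactors = FALSE)
        # the duplicated k-mer is emitted twice; consume it once from the
        # backbone so flanking sequence continues naturally
        out_pieces <- c(out_pieces, tsd)
        offset <- offset + tlen
        cursor <- cursor + tlen
      }
    } else if (is.list(obj) && !is.null(obj$array)) {
      aseq <- obj$array
      mon <- obj$monomers
      if (strand == "-") {
        L <- nchar(aseq)
        aseq <- reverse_complement(aseq)
        mon <- data.frame(copy = mon$copy, start = L - mon$end,
                          end = L - mon$start)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "array", family = family, start = offset,
        end = offset + nchar(aseq), strand = strand, attr = NA_character_,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "monomer", family = family, start = offset + mon$start,
        end = offset + mon$end, strand = strand, attr = NA_character_,
        stringsAsFactors = FALSE)
      out_pieces <- c(out_pieces, aseq)
      offset <- offset + nchar(aseq)
    } else {
      sq <- if (strand == "-") reverse_complement(obj) else obj
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "monomer", family = family, start = offset,
        end = offset + nchar(sq), strand = strand, attr = NA_character_,
        stringsAsFactors = FALSE)
      out_pieces <- c(out_pieces, sq)
      offset <- offset + nchar(sq)
    }
  }
  out_pieces <- c(out_pieces, substr(backbone, cursor + 1, backbone_length))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(seq = c2s(out_pieces), truth = truth)
}

## shift an insertion site until the duplicated k-mer is the unique longest
## boundary-anchored match (no ambiguous TSD extension)
resolve_tsd_site <- function(backbone, pos, tlen, max_shift = 50L) {
  n <- nchar(backbone)
  for (s in 0:max_shift) {
    p <- pos + s
    if (p + tlen + 1 > n || p < 1) break
    # extension would occur iff backbone has a run of shifted self-matches:
    # left flank char before the site equals char tlen later, or the base
    # just after the duplicated k-mer equals the first k-mer base pattern
    left_ok <- substr(backbone, p, p) != substr(backbone, p + tlen, p + tlen)
    right_ok <- substr(backbone, p + 1, p + 1) !=
      substr(backbone, p + tlen + 1, p + tlen + 1)
    if (left_ok && right_ok) return(p)
  }
  pos
}

#' Simulate a cloned PCR multimer set from outward-facing primers
#'
#' For each multimer order n = 1..`max_multimer`, takes the substring from a
#' forward-primer 5' end across n monomer junctions to the next
#' reverse-primer 5' end and applies light mutation (cloning/sequencing
#' noise). Product lengths follow the amplicon ladder law: first band =
#' (monomer length - forward start) + reverse end, increments of one monomer
#' length.
#'
#' @param array Tandem array string (phase 0 = monomer start).
#' @param primers A [primer_pair()].
#' @param monomer_length Monomer length in bp.
#' @param max_multimer Largest multimer order to clone.
#' @param model Optional [mutation_model()] for per-clone noise.
#' @return Named character vector of clone sequences (`clone_n1`, ...).
#' @export
simulate_clone_set <- function(array, primers, monomer_length, max_multimer,
                               model = mutation_model()) {
  check_residues(array)
  stopifnot(inherits(primers, "primer_pair"), max_multimer >= 1)
  L <- as.integer(monomer_length)
  f <- primers$forward_start
  r <- primers$reverse_end
  alen <- nchar(array)
  copies <- alen %/% L
  clones <- character(0)
  for (n in seq_len(max_multimer)) {
    start <- f            # 0-based on the array (first monomer)
    end <- n * L + r      # 0-based half-open
    if (end > alen)
      stop("array too short for multimer order ", n,
           " (primer sites not found)")
    cl <- substr(array, start + 1, end)
    m <- model
    m$seed <- child_seed(model$seed, n)
    clones[sprintf("clone_n%d", n)] <- apply_mutations(cl, m)
  }
  clones
}

#' Outward-facing primer pair geometry on a monomer
#'
#' `forward_start`/`forward_end` delimit the forward primer on the plus
#' strand (it extends toward the monomer 3' junction); `reverse_start`/
#' `reverse_end` delimit the reverse primer's annealing site on the plus
#' strand (the primer extends leftward, toward the 5' junction), so the
#' reverse-primer 5' end projects to plus-strand position `reverse_end`.
#'
#' @param forward_start,forward_end,reverse_start,reverse_end 0-based
#'   positions on the monomer.
#' @param forward_seq,reverse_seq Optional primer sequences (reverse given
#'   5'->3' on the minus strand).
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward_start, forward_end,
                        reverse_start, reverse_end,
                        forward_seq = NULL, reverse_seq = NULL) {
  stopifnot(forward_start >= 0, forward_end > forward_start,
            reverse_start >= 0, reverse_end > reverse_start)
  structure(list(forward_start = as.integer(forward_start),
                 forward_end = as.integer(forward_end),
                 reverse_start = as.integer(reverse_start),
                 reverse_end = as.integer(reverse_end),
                 forward_seq = forward_seq, reverse_seq = reverse_seq),
            class = "primer_pair")
}
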