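## Canned synthetic study scenarios. These define the benchmark conditions
## used by the analysis scripts, the test suite and the acceptance script:
## family presets mirroring the published monomer lengths and GC contents,
## the four satellite-TE association archetypes, and a 12-chromosome genome
## with central / multisite / dispersed placements.

#' Synthetic satellite family presets
#'
#' One preset per family: monomer length, GC content, and HOR architecture.
#' `hor = "three_part"` plants S1-1 + S1-2 + S2 (two diverged variants of a
#' short subunit followed by a long unique subunit); `"two_part"` plants
#' S1 + S2 where S2 begins with a diverged echo of S1; `"none"` plants an
#' unstructured monomer. `variant_divergence` is the substitution divergence
#' between subunit copies.
#'
#' @return A named list of preset lists.
#' @export
sat_family_presets <- function() {
  list(
    sat1 = list(name = "sat1", length = 146L, gc = 0.184,
                hor = "three_part", s1 = 27L, variant_divergence = 0.15,
                proportion = 0.00999),
    sat2 = list(name = "sat2", length = 238L, gc = 0.409,
                hor = "two_part", s1 = 119L, variant_divergence = 0.15,
                proportion = 0.00124),
    sat3 = list(name = "sat3", length = 154L, gc = 0.211,
                hor = "none", s1 = NA_integer_, variant_divergence = 0,
                proportion = 0.0036),
    sat5 = list(name = "sat5", length = 37L, gc = 0.199,
                hor = "two_part", s1 = 10L, variant_divergence = 0.10,
                proportion = 0.00015),
    sat6 = list(name = "sat6", length = 49L, gc = 0.224,
                hor = "two_part", s1 = 17L, variant_divergence = 0.10,
                proportion = 0.00015),
    sat7 = list(name = "sat7", length = 70L, gc = 0.314,
                hor = "none", s1 = NA_integer_, variant_divergence = 0,
                proportion = 0.00069))
}

#' Build a monomer template (with truth) from a family preset
#'
#' @param preset A preset from [sat_family_presets()] (or its name).
#' @param seed Integer seed.
#' @return A list with `monomer`, `boundaries` (planted subunit boundary
#'   positions, 0-based, including 0 and the monomer length), `subunits`
#'   (data.frame label/start/end) and `preset`.
#' @export
make_family_template <- function(preset, seed = 1L) {
  if (is.character(preset)) preset <- sat_family_presets()[[preset]]
  L <- preset$length
  if (preset$hor == "none") {
    mono <- make_random_sequence(L, preset$gc, seed = seed)
    sub <- data.frame(label = "S1", start = 0L, end = L,
                      stringsAsFactors = FALSE)
    return(list(monomer = mono, boundaries = c(0L, L), subunits = sub,
                preset = preset))
  }
  d <- preset$s1
  s1 <- make_random_sequence(d, preset$gc, seed = child_seed(seed, 1))
  echo <- apply_mutations(
    s1, mutation_model(substitution_rate = preset$variant_divergence,
                       seed = child_seed(seed, 2)))
  if (preset$hor == "three_part") {
    tail_len <- L - 2L * d
    s2 <- make_random_sequence(tail_len, preset$gc,
                               seed = child_seed(seed, 3))
    hb <- build_hor_monomer(
      hor_spec(c("S1-1" = s1, "S1-2" = echo, "S2" = s2)), seed = seed)
  } else {
    tail_len <- L - 2L * d
    tail_seq <- if (tail_len > 0)
      make_random_sequence(tail_len, preset$gc, seed = child_seed(seed, 3))
    else ""
    hb <- build_hor_monomer(
      hor_spec(c("S1" = s1, "S2" = paste0(echo, tail_seq))), seed = seed)
  }
  list(monomer = hb$monomer,
       boundaries = unique(c(hb$subunits$start, L)),
       subunits = hb$subunits, preset = preset)
}

#' Generate a monomer set for HOR recovery experiments
#'
#' Builds the family template and draws `n_monomers` independently mutated
#' copies (star phylogeny, substitutions only by default).
#'
#' @param preset Preset (or name) from [sat_family_presets()].
#' @param seed Integer seed.
#' @param n_monomers Number of monomers.
#' @param divergence Per-copy substitution rate from the template.
#' @return A list with `monomers` (named vector), `template`, `boundaries`.
#' @export
scenario_hor_monomers <- function(preset, seed = 1L, n_monomers = 10L,
                                  divergence = 0.05) {
  tpl <- make_family_template(preset, seed = seed)
  mono <- vapply(seq_len(n_monomers), function(i)
    apply_mutations(tpl$monomer,
                    mutation_model(substitution_rate = divergence,
                                   seed = child_seed(seed, 100 + i))),
    character(1))
  names(mono) <- sprintf("mono_%02d", seq_len(n_monomers))
  list(monomers = mono, template = tpl$monomer,
       boundaries = tpl$boundaries, subunits = tpl$subunits)
}

#' The four satellite-TE association archetypes
#'
#' Builds four mini-chromosomes, one per archetype: (A) retroelement whose
#' two LTRs each embed one satellite unit, 8-bp TSD; (B) TIR element with 4
#' tandem units, 3-bp TSD; (C) retroelement with one unit per LTR, 9-bp TSD;
#' (D) TIR element with 4 tandem units inserted at a TAA target site (3-bp
#' TAA TSD, the Harbinger hallmark). Expected calls: dispersed, tandem,
#' dispersed, tandem.
#'
#' @param seed Integer seed.
#' @param unit_divergence Substitution rate applied per satellite unit.
#' @param backbone_length Mini-chromosome backbone length.
#' @return A list of four scenario lists, each with `chrom`, `truth`,
#'   `query` (unit template), `expected_arrangement`, `expected_tsd_length`,
#'   and for (D) `expected_tsd_seq = "TAA"`.
#' @export
scenario_te_archetypes <- function(seed = 1L, unit_divergence = 0.05,
                                   backbone_length = 6000L) {
  presets <- sat_family_presets()
  specs <- list(
    list(id = "A", kind = "ltr_retro", family = "sat1", n_units = 1L,
         arrangement = "single", tsd = 8L, expected = "dispersed_in_te"),
    list(id = "B", kind = "tir_dna", family = "sat3", n_units = 4L,
         arrangement = "tandem", tsd = 3L, expected = "tandem_in_te"),
    list(id = "C", kind = "ltr_retro", family = "sat6", n_units = 1L,
         arrangement = "single", tsd = 9L, expected = "dispersed_in_te"),
    list(id = "D", kind = "tir_dna", family = "sat7", n_units = 4L,
         arrangement = "tandem", tsd = 3L, expected = "tandem_in_te",
         tsd_seq = "TAA"))
  out <- list()
  for (k in seq_along(specs)) {
    sc <- specs[[k]]
    sseed <- child_seed(seed, 1000 + k)
    tpl <- make_family_template(presets[[sc$family]],
                                seed = child_seed(sseed, 1))
    units <- vapply(seq_len(sc$n_units), function(i)
      apply_mutations(tpl$monomer,
                      mutation_model(substitution_rate = unit_divergence,
                                     seed = child_seed(sseed, 10 + i))),
      character(1))
    internal <- make_random_sequence(800L, 0.38, seed = child_seed(sseed, 2))
    te <- build_te_with_satellite(
      kind = sc$kind, internal = internal, sat_units = units,
      arrangement = sc$arrangement, tsd_length = sc$tsd,
      seed = child_seed(sseed, 3))
    pos <- 2500L
    if (!is.null(sc$tsd_seq)) {
      # insert at a backbone site carrying the wanted TSD motif
      bb <- make_random_sequence(backbone_length, 0.38,
                                 seed = child_seed(sseed, 4))
      cand <- gregexpr(sc$tsd_seq, bb, fixed = TRUE)[[1]]
      cand <- cand[cand > 1500 & cand < backbone_length - 2000]
      pos <- NA_integer_
      for (p in cand) {
        p0 <- p - 1L  # 0-based
        if (resolve_tsd_site(bb, p0, nchar(sc$tsd_seq)) == p0) {
          pos <- p0; break
        }
      }
      if (is.na(pos)) pos <- cand[1] - 1L
      asm <- assemble_chromosome(backbone_length,
                                 list(list(obj = te, position = pos,
                                           family = sc$family)),
                                 seed = child_seed(sseed, 4))
    } else {
      asm <- assemble_chromosome(backbone_length,
                                 list(list(obj = te, position = pos,
                                           family = sc$family)),
                                 seed = child_seed(sseed, 4))
    }
    out[[sc$id]] <- list(
      chrom = asm$seq, truth = asm$truth, query = tpl$monomer,
      family = sc$family,
      expected_arrangement = sc$expected,
      expected_tsd_length = sc$tsd,
      expected_tsd_seq = if (!is.null(sc$tsd_seq)) sc$tsd_seq else NULL)
  }
  out
}

#' Twelve-chromosome genome with planted distribution patterns
#'
#' Chromosomes 1-4 carry one central 30-copy array of the 146-bp family
#' (expected pattern `central`); 5-8 carry five 6-copy arrays of the 49-bp
#' family at 5/25/50/75/95% of the chromosome (`multisite`); 9-12 carry ten
#' TE-borne single units of the 154-bp family spaced beyond the run gap
#' (`dispersed`). Planted divergence 5%.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes (multiple of 3; default 12).
#' @param chrom_len Chromosome length in bp (default 1.2 Mb).
#' @param divergence Per-copy substitution rate.
#' @return A list with `chroms` (named vector), `truth` (data.frame with
#'   seqid column), `families` (named list of templates), and
#'   `expected_pattern` (named per chromosome).
#' @export
scenario_distribution_genome <- function(seed = 1L, n_chrom = 12L,
                                         chrom_len = 1.2e6,
                                         divergence = 0.05) {
  stopifnot(n_chrom %% 3 == 0)
  presets <- sat_family_presets()
  tpl_central <- make_family_template(presets$sat1,
                                      seed = child_seed(seed, 1))
  tpl_multi <- make_family_template(presets$sat6,
                                    seed = child_seed(seed, 2))
  tpl_disp <- make_family_template(presets$sat3,
                                   seed = child_seed(seed, 3))
  grp_size <- n_chrom / 3
  chroms <- character(0)
  truth <- list()
  expected <- character(0)
  for (ci in seq_len(n_chrom)) {
    cn <- sprintf("chr%02d", ci)
    cseed <- child_seed(seed, 50 + ci)
    group <- ceiling(ci / grp_size)
    placements <- list()
    if (group == 1L) {
      arr <- build_array(tpl_central$monomer, 30L,
                         mutation_model(substitution_rate = divergence,
                                        seed = child_seed(cseed, 1)))
      placements <- list(list(obj = arr, position = as.integer(chrom_len / 2),
                              family = "sat1"))
      expected[cn] <- "central"
    } else if (group == 2L) {
      at <- as.integer(chrom_len * c(0.05, 0.25, 0.50, 0.75, 0.95))
      placements <- lapply(seq_along(at), function(k) {
        arr <- build_array(tpl_multi$monomer, 6L,
                           mutation_model(substitution_rate = divergence,
                                          seed = child_seed(cseed, 10 + k)))
        list(obj = arr, position = at[k], family = "sat6")
      })
      expected[cn] <- "multisite"
    } else {
      at <- as.integer(seq(0.05, 0.95, length.out = 10) * chrom_len)
      placements <- lapply(seq_along(at), function(k) {
        unit <- apply_mutations(
          tpl_disp$monomer,
          mutation_model(substitution_rate = divergence,
                         seed = child_seed(cseed, 20 + k)))
        te <- build_te_with_satellite(
          kind = "tir_dna",
          internal = make_random_sequence(300L, 0.38,
                                          seed = child_seed(cseed, 40 + k)),
          sat_units = unit, arrangement = "single", tsd_length = 3L,
          seed = child_seed(cseed, 60 + k))
        list(obj = te, position = at[k], family = "sat3")
      })
      expected[cn] <- "dispersed"
    }
    asm <- assemble_chromosome(chrom_len, placements,
                               seed = child_seed(cseed, 99))
    chroms[cn] <- asm$seq
    if (nrow(asm$truth) > 0) asm$truth$seqid <- cn
    truth[[cn]] <- asm$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(chroms = chroms, truth = truth,
       families = list(sat1 = tpl_central$monomer,
                       sat6 = tpl_multi$monomer,
                       sat3 = tpl_disp$monomer),
       expected_pattern = expected)
}

#' Clone-ladder scenario for the 146-bp family
#'
#' Builds a clean tandem array of the 146-bp family template with the
#' published primer geometry (first band 119 bp) and simulates a clone set.
#'
#' @param seed Integer seed.
#' @param copies Array copies.
#' @param max_multimer Largest multimer order cloned.
#' @return A list with `array`, `primers`, `clones`, `monomer_length`.
#' @export
scenario_clone_ladder <- function(seed = 1L, copies = 8L, max_multimer = 3L) {
  tpl <- make_family_template(sat_family_presets()$sat1, seed = seed)
  arr <- build_array(tpl$monomer, copies)
  primers <- primer_pair(forward_start = 47L, forward_end = 67L,
                         reverse_start = 0L, reverse_end = 20L)
  clones <- simulate_clone_set(arr$array, primers, monomer_length = 146L,
                               max_multimer = max_multimer)
  list(array = arr$array, primers = primers, clones = clones,
       monomer_length = 146L, template = tpl$monomer)
}
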