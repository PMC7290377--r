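test_that("make_random_sequence honors composition and seeding", {
  expect_false(grepl("[GC]", make_random_sequence(500, gc = 0, seed = 1)))
  expect_false(grepl("[AT]", make_random_sequence(500, gc = 1, seed = 1)))
  s <- make_random_sequence(10000, gc = 0.224, seed = 3)
  expect_lt(abs(gc_content(s) - 0.224), 0.02)
  expect_identical(make_random_sequence(100, 0.4, seed = 9),
                   make_random_sequence(100, 0.4, seed = 9))
})

test_that("apply_mutations matches its binomial expectation", {
  s <- make_random_sequence(1000, 0.4, seed = 5)
  expect_identical(apply_mutations(s, mutation_model()), s)
  m <- apply_mutations(s, mutation_model(substitution_rate = 0.05, seed = 6))
  expect_equal(nchar(m), 1000)
  expect_lt(abs(global_align(s, m)$identity - 0.95), 0.02)
  expect_error(mutation_model(deletion_rate = 1), "rates")
  # indels change length roughly by (ins - del) x n
  mi <- apply_mutations(s, mutation_model(insertion_rate = 0.05, seed = 7))
  expect_gt(nchar(mi), 1020)
})

test_that("build_hor_monomer plants exact subunit boundaries", {
  s1 <- make_random_sequence(10, 0.2, seed = 1)
  s2 <- make_random_sequence(27, 0.2, seed = 2)
  hb <- build_hor_monomer(hor_spec(c(S1 = s1, S2 = s2)), seed = 3)
  expect_identical(hb$monomer, paste0(s1, s2))
  expect_equal(hb$subunits$start, c(0L, 10L))
  expect_equal(hb$subunits$end, c(10L, 37L))

  # derived variant: S1-2 is a diverged copy of S1-1
  hb2 <- build_hor_monomer(
    hor_spec(c("S1-1" = s2, "S1-2" = NA, "S2" = s1),
             variant_divergence = 0.4), seed = 4)
  expect_equal(nchar(hb2$monomer), 27 + 27 + 10)
  v <- substr(hb2$monomer, 28, 54)
  ident <- global_align(s2, v)$identity
  expect_gt(ident, 0.35)
  expect_lt(ident, 0.85)

  single <- build_hor_monomer(hor_spec(c(S1 = s1)))
  expect_identical(single$monomer, s1)
})

test_that("build_array tiles truth intervals and bounds divergence", {
  mono <- make_random_sequence(154, 0.25, seed = 8)
  arr <- build_array(mono, 1)
  expect_identical(arr$array, mono)

  arr <- build_array(mono, 50, mutation_model(0.05, 0.005, 0.005, seed = 9))
  expect_gte(nchar(arr$array), 50 * 154 * 0.98)
  expect_lte(nchar(arr$array), 50 * 154 * 1.02)
  # tiling
  expect_equal(arr$monomers$start[-1], head(arr$monomers$end, -1))
  expect_equal(arr$monomers$start[1], 0L)
  expect_equal(tail(arr$monomers$end, 1), nchar(arr$array))
  # pairwise copy identities bounded below (union bound with slack)
  set.seed(10)
  idx <- cbind(sample(50, 8), sample(50, 8))
  for (r in seq_len(nrow(idx))) {
    a <- substr(arr$array, arr$monomers$start[idx[r, 1]] + 1,
                arr$monomers$end[idx[r, 1]])
    b <- substr(arr$array, arr$monomers$start[idx[r, 2]] + 1,
                arr$monomers$end[idx[r, 2]])
    expect_gte(global_align(a, b)$identity, 1 - 2 * (0.05 + 0.01) - 0.05)
  }
})

test_that("TE builder embeds satellite units per architecture", {
  unit <- make_random_sequence(70, 0.3, seed = 11)
  internal <- make_random_sequence(300, 0.38, seed = 12)

  te <- build_te_with_satellite("tir_dna", internal,
                                sat_units = rep(unit, 4),
                                arrangement = "tandem", tsd_length = 3,
                                seed = 13)
  su <- te$features[te$features$kind == "sat_unit", ]
  expect_equal(nrow(su), 4)
  expect_equal(su$start[-1], head(su$end, -1))  # adjacent units
  tir <- te$features[te$features$kind == "tir", ]
  expect_identical(substr(te$seq, tir$start[1] + 1, tir$end[1]),
                   reverse_complement(substr(te$seq, tir$start[2] + 1,
                                             tir$end[2])))

  ltr <- build_te_with_satellite("ltr_retro", internal, sat_units = unit,
                                 arrangement = "single", tsd_length = 0,
                                 seed = 14)
  expect_equal(sum(ltr$features$kind == "sat_unit"), 2)
  lf <- ltr$features[ltr$features$kind == "ltr", ]
  expect_identical(substr(ltr$seq, lf$start[1] + 1, lf$end[1]),
                   substr(ltr$seq, lf$start[2] + 1, lf$end[2]))

  expect_error(build_te_with_satellite("tir_dna", internal, unit,
                                       arrangement = "tandem"),
               "tandem")
  expect_error(build_te_with_satellite("tir_dna", internal, unit,
                                       tsd_length = 5), "tsd_length")
})

test_that("assemble_chromosome lifts truth and duplicates target sites", {
  asm <- assemble_chromosome(5000, seed = 15)
  expect_equal(nchar(asm$seq), 5000)
  expect_equal(nrow(asm$truth), 0)

  mono <- make_random_sequence(100, 0.3, seed = 16)
  arr <- build_array(mono, 5, mutation_model(0.05, seed = 17))
  asm <- assemble_chromosome(10000,
                             list(list(obj = arr, position = 5000L,
                                       family = "fam")),
                             seed = 18)
  a <- asm$truth[asm$truth$kind == "array", ]
  mid <- (a$start + a$end) / 2
  expect_gt(mid, nchar(asm$seq) / 3)
  expect_lt(mid, 2 * nchar(asm$seq) / 3)
  # every planted monomer aligns back to the template at high identity
  mt <- asm$truth[asm$truth$kind == "monomer", ]
  for (i in seq_len(nrow(mt))) {
    frag <- substr(asm$seq, mt$start[i] + 1, mt$end[i])
    expect_gte(global_align(frag, mono)$identity, 1 - 0.05 - 0.05)
  }

  # TSD: the 3 bp flanking the element are identical on both sides
  unit <- make_random_sequence(70, 0.3, seed = 19)
  te <- build_te_with_satellite("tir_dna",
                                make_random_sequence(200, 0.38, seed = 20),
                                sat_units = rep(unit, 2),
                                arrangement = "tandem",
                                tsd_length = 3, seed = 21)
  asm2 <- assemble_chromosome(4000,
                              list(list(obj = te, position = 2000L)),
                              seed = 22)
  el <- asm2$truth[asm2$truth$kind == "te", ]
  expect_identical(substr(asm2$seq, el$start - 2, el$start),
                   substr(asm2$seq, el$end + 1, el$end + 3))
  tsds <- asm2$truth[asm2$truth$kind == "tsd", ]
  expect_equal(nrow(tsds), 2)
  expect_identical(tsds$attr[1], tsds$attr[2])

  expect_error(
    assemble_chromosome(1000, list(list(obj = mono, position = 10L),
                                   list(obj = mono, position = 10L))),
    "overlapping")
})

test_that("generator output is byte-identical under identical seeds", {
  a1 <- scenario_distribution_genome(seed = 2, n_chrom = 3L,
                                     chrom_len = 5e4)
  a2 <- scenario_distribution_genome(seed = 2, n_chrom = 3L,
                                     chrom_len = 5e4)
  expect_identical(a1$chroms, a2$chroms)
  expect_identical(a1$truth, a2$truth)
  b <- scenario_distribution_genome(seed = 3, n_chrom = 3L, chrom_len = 5e4)
  expect_false(identical(a1$chroms, b$chroms))
})

test_that("simulated clone set follows the amplicon ladder law", {
  sc <- scenario_clone_ladder(seed = 4, max_multimer = 3)
  expect_equal(unname(nchar(sc$clones)), c(119, 265, 411))
  expect_equal(diff(unname(nchar(sc$clones))), c(146, 146))

  one <- simulate_clone_set(sc$array, sc$primers, 146, max_multimer = 1)
  expect_length(one, 1)
  expect_error(simulate_clone_set(substr(sc$array, 1, 200), sc$primers,
                                  146, max_multimer = 5),
               "primer sites not found|too short")
})
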