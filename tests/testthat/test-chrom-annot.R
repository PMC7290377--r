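test_that("annotation recovers a planted array and respects the identity
           floor", {
  tpl <- make_random_sequence(146, 0.25, seed = 701)
  arr <- build_array(tpl, 30, mutation_model(0.05, seed = 702))
  asm <- assemble_chromosome(5e4, list(list(obj = arr, position = 25000L,
                                            family = "fam")), seed = 703)
  chroms <- c(chrA = asm$seq, chrB = make_random_sequence(3e4, 0.38,
                                                          seed = 704))
  rec <- annotate_chromosomes(chroms, list(name = "fam", consensus = tpl))
  expect_gte(sum(rec$seqid == "chrA"), 29)
  expect_equal(sum(rec$seqid == "chrB"), 0)
  expect_true(all(rec$identity >= 0.80))
  arr_t <- asm$truth[asm$truth$kind == "array", ]
  expect_true(all(rec$start >= arr_t$start - 5 & rec$end <= arr_t$end + 5))

  # 30% divergence: nothing at the 0.80 floor
  far <- apply_mutations(tpl, mutation_model(0.30, seed = 705))
  g <- paste0(make_random_sequence(2000, 0.38, seed = 706), far,
              make_random_sequence(2000, 0.38, seed = 707))
  rec2 <- annotate_chromosomes(c(chr = g), list(name = "fam",
                                                consensus = tpl))
  expect_equal(nrow(rec2), 0)
})

test_that("annotation is strand-symmetric", {
  tpl <- make_random_sequence(100, 0.3, seed = 711)
  arr <- build_array(tpl, 5, mutation_model(0.05, seed = 712))
  asm <- assemble_chromosome(1e4, list(list(obj = arr, position = 5000L)),
                             seed = 713)
  fwd <- annotate_chromosomes(c(c1 = asm$seq),
                              list(name = "f", consensus = tpl))
  rev <- annotate_chromosomes(c(c1 = reverse_complement(asm$seq)),
                              list(name = "f", consensus = tpl))
  L <- nchar(asm$seq)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = chartr("+-", "-+", rev$strand))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(mirrored$start, fwd$start, tolerance = 1e-8)
  expect_equal(mirrored$end, fwd$end)
  expect_equal(mirrored$strand, fwd$strand)
})

test_that("per-chromosome counts zero-fill and conserve totals", {
  rec <- annotation_records(
    seqid = c("c1", "c1", "c3"), start = c(0, 100, 5),
    end = c(50, 150, 60), strand = "+", family = "f",
    identity = 0.9)
  ct <- count_per_chromosome(rec, c("c1", "c2", "c3", "c4"))
  expect_equal(unname(ct$counts), c(2L, 0L, 1L, 0L))
  expect_equal(ct$presence, 2)
  expect_equal(sum(ct$counts), nrow(rec))
  empty <- rec[0, ]
  ct0 <- count_per_chromosome(empty, c("c1", "c2"))
  expect_true(all(ct0$counts == 0))
  expect_error(count_per_chromosome(rec, c("c1", "c2")), "unknown")
})

test_that("presence counts follow the planted chromosome subset", {
  # 12 chromosomes, arrays planted on 5
  tpl <- make_random_sequence(100, 0.3, seed = 721)
  chroms <- character(0)
  for (i in 1:12) {
    cn <- sprintf("chr%02d", i)
    if (i <= 5) {
      arr <- build_array(tpl, 4, mutation_model(0.05, seed = 730 + i))
      chroms[cn] <- assemble_chromosome(
        2e4, list(list(obj = arr, position = 10000L)),
        seed = 740 + i)$seq
    } else {
      chroms[cn] <- make_random_sequence(2e4, 0.38, seed = 750 + i)
    }
  }
  rec <- annotate_chromosomes(chroms, list(name = "f", consensus = tpl))
  ct <- count_per_chromosome(rec, names(chroms))
  expect_equal(ct$presence, 5)
})

test_that("distribution classification agrees with its brute-force
           definition", {
  clen <- 1e6
  mk <- function(starts, w = 150) {
    n <- length(starts)
    annotation_records(seqid = rep("c", n), start = starts,
                       end = starts + w, strand = rep("+", n),
                       family = rep("f", n), identity = rep(0.9, n))
  }
  cases <- list(
    central = seq(45e4, 50e4, by = 200),
    multisite = as.vector(vapply(c(5e4, 25e4, 50e4, 75e4, 95e4),
                                 function(p) p + seq(0, 800, by = 200),
                                 numeric(5))),
    dispersed = seq(5e4, 95e4, length.out = 9),
    absent = numeric(0))
  for (nm in names(cases)) {
    rec <- mk(cases[[nm]])
    dc <- classify_distribution(rec, c(c = clen))
    expect_equal(dc$per_chromosome$pattern[1], nm, label = nm)
    expect_equal(dc$per_chromosome$pattern[1],
                 oracle_pattern(rec$start, rec$end, clen))
  }
  # randomized record sets always agree with the oracle
  set.seed(761)
  for (r in 1:25) {
    n <- sample(0:30, 1)
    starts <- sort(sample(seq(0, clen - 200, by = 50), n))
    rec <- mk(starts)
    dc <- classify_distribution(rec, c(c = clen))
    expect_equal(dc$per_chromosome$pattern[1],
                 oracle_pattern(rec$start, rec$end, clen))
  }
})

test_that("the family-level pattern is the modal per-chromosome pattern", {
  clen <- c(c1 = 1e6, c2 = 1e6, c3 = 1e6)
  rec <- rbind(
    annotation_records("c1", seq(45e4, 46e4, by = 200),
                       seq(45e4, 46e4, by = 200) + 150, "+", "f", 0.9),
    annotation_records("c2", seq(45e4, 46e4, by = 200),
                       seq(45e4, 46e4, by = 200) + 150, "+", "f", 0.9))
  dc <- classify_distribution(rec, clen)
  expect_equal(dc$pattern, "central")
  dc0 <- classify_distribution(rec[0, ], clen)
  expect_equal(dc0$pattern, "absent")
})
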