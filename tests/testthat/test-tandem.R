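test_that("word-match segments agree exactly with brute-force enumeration", {
  set.seed(61)
  for (i in 1:25) {
    a <- random_seq(sample(20:100, 1), gc = runif(1, 0.2, 0.5))
    b <- random_seq(sample(20:100, 1), gc = runif(1, 0.2, 0.5))
    k <- sample(4:12, 1)
    S <- sample(0:min(3, k - 1), 1)
    got <- wordmatch_segments(a, b, k, S)
    exp <- oracle_wordmatch(a, b, k, S)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got[, c("a_start", "a_end", "b_start", "b_end",
                         "mismatches")], exp)
  }
})

test_that("self-comparison yields the full main diagonal", {
  s <- random_seq(60)
  seg <- wordmatch_segments(s, s, word_size = 10, max_mismatch = 0)
  main <- seg[seg$a_start == seg$b_start, ]
  expect_true(any(main$a_start == 0 & main$a_end == 60 & main$mismatches == 0))
})

test_that("minus-strand segments map to the reverse complement", {
  set.seed(71)
  a <- random_seq(50)
  seg <- wordmatch_segments(a, reverse_complement(a), word_size = 10,
                            max_mismatch = 0, both_strands = TRUE)
  minus <- seg[seg$strand == "-", ]
  expect_true(any(minus$a_start == 0 & minus$a_end == 50 &
                    minus$b_start == 0 & minus$b_end == 50))
  expect_identical(
    wordmatch_segments("ACGTACGTACGT", "TTTTTTTTTTTT", word_size = 20,
                       max_mismatch = 0),
    wordmatch_segments("ACGTACGTACGT", "TTTTTTTTTTTT", word_size = 20,
                       max_mismatch = 0))  # k > len -> consistent empties
  expect_equal(nrow(wordmatch_segments(a, a, word_size = 51)), 0)
})

test_that("windowed dotplot agrees with brute force and its arithmetic", {
  s <- random_seq(40)
  dp <- windowed_dotplot(s, s, window = 14, threshold = 27)
  # identical sequences: every main-diagonal window scores 70 >= 27
  main <- dp[dp$i == dp$j, ]
  expect_equal(main$i, 0:(40 - 14))

  # a window with <= 4 matches cannot reach threshold 27
  a <- paste0(strrep("A", 4), strrep("C", 10))
  b <- paste0(strrep("A", 4), strrep("G", 10))
  expect_equal(nrow(windowed_dotplot(a, b, 14, 27)), 0)

  set.seed(81)
  for (i in 1:15) {
    a <- random_seq(sample(20:60, 1)); b <- random_seq(sample(20:60, 1))
    got <- windowed_dotplot(a, b, 14, 27)
    exp <- oracle_windowed(a, b, 14, 27)
    rownames(got) <- rownames(exp) <- NULL
    expect_equal(got, exp)
  }
})

test_that("estimate_period finds planted periods and rejects noise", {
  pe <- estimate_period(strrep("ACGT", 25))
  expect_equal(pe$period, 4L)
  expect_equal(pe$support, 1)

  # planted 37-bp monomer x 12 at 5% substitutions
  mono <- make_random_sequence(37, 0.2, seed = 91)
  arr <- build_array(mono, 12, mutation_model(0.05, seed = 92))
  pe <- estimate_period(arr$array, min_period = 10)
  expect_equal(pe$period, 37L)

  set.seed(93)
  expect_null(estimate_period(random_seq(1000), min_period = 10,
                              max_period = 300))
})

test_that("period recovery is exact across the monomer length range", {
  for (len in c(36L, 49L, 101L, 154L, 240L)) {
    mono <- make_random_sequence(len, 0.3, seed = len)
    arr <- build_array(mono, 10, mutation_model(0.10, seed = len + 1))
    pe <- estimate_period(arr$array, min_period = 10,
                          max_period = min(300, nchar(arr$array) %/% 2))
    expect_equal(pe$period, len)
  }
})

test_that("extract_monomers cuts at reference alignments", {
  mono <- make_random_sequence(100, 0.3, seed = 95)
  perfect <- build_array(mono, 5)
  ex <- extract_monomers(perfect$array, mono)
  expect_length(ex$monomers, 5)
  expect_true(all(vapply(ex$monomers, identical, logical(1), mono)))

  # 2.5 monomer-lengths: 2 monomers + 1 partial
  clone <- substr(perfect$array, 1, 250)
  ex <- extract_monomers(clone, mono)
  expect_length(ex$monomers, 2)
  expect_length(ex$partials, 1)

  expect_error(extract_monomers(random_seq(300), mono), "no alignment")
})

test_that("extraction recovers planted boundaries within 2 bp", {
  mono <- make_random_sequence(146, 0.25, seed = 96)
  arr <- build_array(mono, 20, mutation_model(0.05, seed = 97))
  ex <- extract_monomers(arr$array, mono)
  expect_gte(length(ex$monomers), 19)
  hit <- vapply(seq_len(nrow(ex$intervals)), function(i) {
    any(abs(arr$monomers$start - ex$intervals$start[i]) <= 2 &
          abs(arr$monomers$end - ex$intervals$end[i]) <= 2)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("period-mode extraction cuts at phase + n x period", {
  mono <- make_random_sequence(40, 0.3, seed = 98)
  arr <- build_array(mono, 6)
  pe <- estimate_period(arr$array, min_period = 10)
  ex <- extract_monomers(arr$array, pe)
  expect_length(ex$monomers, 6)
  expect_equal(unname(nchar(ex$monomers)), rep(40L, 6))
})

test_that("consensus is majority-rule with fixed tie-breaking", {
  mono <- make_random_sequence(80, 0.3, seed = 99)
  cp <- build_consensus(rep(mono, 4))
  expect_identical(cp$residues, mono)
  expect_true(all(cp$column_support == 1))

  # three monomers differing at one column: majority wins, support 2/3
  m1 <- "AACGTACGTA"; m2 <- "AACGTACGTA"; m3 <- "ACCGTACGTA"
  cp <- build_consensus(c(m1, m2, m3))
  expect_identical(cp$residues, m1)
  expect_equal(sort(unique(cp$column_support)), c(2 / 3, 1))

  # 20 mutated copies at 5%: consensus within 1 mismatch of the template
  tpl <- make_random_sequence(150, 0.25, seed = 100)
  copies <- vapply(1:20, function(i)
    apply_mutations(tpl, mutation_model(0.05, seed = 100 + i)),
    character(1))
  cp <- build_consensus(copies)
  al <- global_align(cp$residues, tpl)
  expect_gte(al$identity, 1 - 1 / 150)
})

test_that("identity matrix handles masks on the reference frame", {
  m <- make_random_sequence(60, 0.3, seed = 110)
  expect_equal(unname(identity_matrix(c(m, m))[1, 2]), 1)

  expect_error(
    identity_matrix(c(m, m), mask = data.frame(start = 0, end = 60),
                    reference = m),
    "mask")

  # masking a conserved region lowers identity for a pair differing only
  # outside it
  conserved <- strrep("ACGTG", 4)                      # 20-bp "primer"
  v1 <- paste0(conserved, make_random_sequence(40, 0.4, seed = 111))
  v2 <- paste0(conserved, make_random_sequence(40, 0.4, seed = 112))
  full <- identity_matrix(c(v1, v2))[1, 2]
  masked <- identity_matrix(c(v1, v2),
                            mask = data.frame(start = 0, end = 20),
                            reference = v1)[1, 2]
  expect_lt(masked, full)
})

test_that("HOR array self-dotplot shows subunit and monomer off-diagonals", {
  sc <- scenario_hor_monomers("sat1", seed = 7)
  arr <- paste(sc$monomers[1:4], collapse = "")
  seg <- wordmatch_segments(arr, arr, word_size = 8, max_mismatch = 2)
  lag <- abs(seg$a_start - seg$b_start)
  expect_true(any(abs(lag - 146) <= 2))  # monomer period
  expect_true(any(abs(lag - 27) <= 2))   # subunit period
})
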