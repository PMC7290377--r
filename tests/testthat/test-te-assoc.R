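test_that("scan finds exact and diverged planted copies with correct
           thresholding", {
  q <- make_random_sequence(100, 0.35, seed = 201)
  genome <- paste0(make_random_sequence(2000, 0.38, seed = 202), q,
                   make_random_sequence(2000, 0.38, seed = 203))
  h <- scan_similarity(q, genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(h$coverage, 1)
  expect_equal(h$start, 2000)
  expect_equal(h$end, 2100)
  expect_equal(h$strand, "+")

  # diverged copies against the 0.80 floor: the 10% copy (identity ~0.90)
  # is reported and the 40% copy is not; copies near 20-30% divergence sit
  # at the floor once local end-trimming is accounted for, so nothing is
  # asserted about the middle copy
  copies <- vapply(c(0.10, 0.20, 0.40), function(r)
    apply_mutations(q, mutation_model(r, seed = round(1000 * r))),
    character(1))
  g2 <- paste0(make_random_sequence(500, 0.38, seed = 204), copies[1],
               make_random_sequence(500, 0.38, seed = 205), copies[2],
               make_random_sequence(500, 0.38, seed = 206), copies[3],
               make_random_sequence(500, 0.38, seed = 207))
  h2 <- scan_similarity(q, g2, min_identity = 0.80)
  expect_true(any(abs(h2$start - 500) <= 3))            # 10% copy found
  expect_false(any(abs(h2$start - (500 + 100 + 500 + 100 + 500)) <= 10))

  # minus-strand copy
  g3 <- paste0(make_random_sequence(800, 0.38, seed = 208),
               reverse_complement(q),
               make_random_sequence(800, 0.38, seed = 209))
  h3 <- scan_similarity(q, g3)
  expect_equal(nrow(h3), 1)
  expect_equal(h3$strand, "-")
  expect_equal(h3$start, 800)
  expect_equal(h3$end, 900)
})

test_that("planted-copy recall is total at 10% divergence, zero at 30%", {
  for (len in c(49L, 154L, 238L)) {
    q <- make_random_sequence(len, 0.3, seed = len + 300)
    pieces <- character(0)
    for (i in 1:5) {
      pieces <- c(pieces,
                  make_random_sequence(400, 0.38, seed = len + 10 * i),
                  apply_mutations(q, mutation_model(0.10,
                                                    seed = len + 100 + i)))
    }
    g <- paste0(paste(pieces, collapse = ""),
                make_random_sequence(400, 0.38, seed = len + 999))
    h <- scan_similarity(q, g, min_identity = 0.80)
    expect_gte(nrow(h), 5)

    pieces30 <- character(0)
    for (i in 1:5) {
      pieces30 <- c(pieces30,
                    make_random_sequence(400, 0.38, seed = len + 20 * i),
                    apply_mutations(q, mutation_model(0.30,
                                                      seed = len + 200 + i)))
    }
    g30 <- paste(pieces30, collapse = "")
    h30 <- scan_similarity(q, g30, min_identity = 0.80)
    expect_equal(nrow(h30), 0)
  }
})

test_that("hit clustering follows single-linkage 75/75 semantics", {
  tpl <- make_random_sequence(120, 0.35, seed = 401)
  copies <- vapply(1:5, function(i)
    apply_mutations(tpl, mutation_model(0.05, seed = 401 + i)),
    character(1))
  genome <- paste0(
    paste(vapply(seq_along(copies), function(i)
      paste0(make_random_sequence(200, 0.38, seed = 500 + i), copies[i]),
      character(1)), collapse = ""),
    make_random_sequence(200, 0.38, seed = 599))
  h <- scan_similarity(tpl, genome, seqid = "g")
  cl <- cluster_hits(h, c(g = genome))
  expect_equal(cl$n_clusters, 1L)
  expect_gte(global_align(cl$consensus[1], tpl)$identity, 0.9)

  # two templates at ~50% identity: two clusters
  tplB <- apply_mutations(tpl, mutation_model(0.45, seed = 402))
  hits2 <- data.frame(seqid = "g2", start = c(0, 120), end = c(120, 240),
                      strand = "+", identity = 1, coverage = 1, score = 1,
                      query = "q")
  g2 <- paste0(tpl, tplB)
  cl2 <- cluster_hits(hits2, c(g2 = g2))
  expect_equal(cl2$n_clusters, 2L)

  # chain a-b and b-c link even when a-c alone would not (single linkage)
  a <- make_random_sequence(100, 0.5, seed = 403)
  b <- apply_mutations(a, mutation_model(0.12, seed = 404))
  cc <- apply_mutations(b, mutation_model(0.12, seed = 405))
  gabc <- paste0(a, b, cc)
  hits3 <- data.frame(seqid = "g3", start = c(0, 100, 200),
                      end = c(100, 200, 300), strand = "+", identity = 1,
                      coverage = 1, score = 1, query = "q")
  cl3 <- cluster_hits(hits3, c(g3 = gabc))
  expect_equal(cl3$n_clusters, 1L)
})

test_that("TSD detection recovers planted lengths exactly", {
  for (tlen in c(3L, 8L, 9L)) {
    unit <- make_random_sequence(70, 0.3, seed = 600 + tlen)
    te <- build_te_with_satellite(
      "tir_dna", make_random_sequence(200, 0.38, seed = 610 + tlen),
      sat_units = rep(unit, 2), arrangement = "tandem",
      tsd_length = tlen, seed = 620 + tlen)
    asm <- assemble_chromosome(3000, list(list(obj = te, position = 1500L)),
                               seed = 630 + tlen)
    el <- asm$truth[asm$truth$kind == "te", ]
    tsd <- detect_tsd(asm$seq, el$start, el$end)
    expect_equal(tsd$length, tlen)
    planted <- asm$truth[asm$truth$kind == "tsd", ]
    expect_identical(tsd$seq, planted$attr[1])
  }

  # random flanks: no planted duplication, mostly none or very short
  set.seed(641)
  lens <- replicate(60, {
    g <- random_seq(200, gc = 0.38)
    t <- detect_tsd(g, 80, 120)
    if (is.null(t)) 0L else t$length
  })
  expect_gte(mean(lens == 0), 0.5)   # >= 2 bp anchored match ~ 1/16 + 1/64...
  expect_true(all(lens <= 4))

  expect_warning(res <- detect_tsd(random_seq(100), 2, 50), "edge")
  expect_null(res)
})

test_that("association calls follow the tandem/dispersed/standalone rules", {
  qlen <- 100
  mkhits <- function(starts, ends)
    data.frame(seqid = "c", start = starts, end = ends, strand = "+",
               identity = 0.95, coverage = 1, score = 1, query = "q")
  # 4 adjacent units inside an element
  h <- mkhits(c(200, 300, 402, 510), c(300, 400, 502, 610))
  expect_equal(classify_association(h, element = c(100, 800),
                                    query_length = qlen)$arrangement,
               "tandem_in_te")
  # two distant units inside an element
  h2 <- mkhits(c(200, 600), c(300, 700))
  expect_equal(classify_association(h2, element = c(100, 800),
                                    query_length = qlen)$arrangement,
               "dispersed_in_te")
  # single unit inside
  h3 <- mkhits(250, 350)
  expect_equal(classify_association(h3, element = c(100, 800),
                                    query_length = qlen)$arrangement,
               "dispersed_in_te")
  # array with no element
  h4 <- mkhits(seq(0, 900, by = 100), seq(100, 1000, by = 100))
  expect_equal(classify_association(h4, element = NULL,
                                    query_length = qlen)$arrangement,
               "standalone_array")
  # lone hit, no element
  expect_equal(classify_association(mkhits(10, 110), element = NULL,
                                    query_length = qlen)$arrangement,
               "none")
})

test_that("the four TE archetypes classify as planted with exact TSDs", {
  arcs <- scenario_te_archetypes(seed = 77)
  calls <- character(0)
  for (a in arcs) {
    el <- a$truth[a$truth$kind == "te", ]
    hits <- scan_similarity(a$query, a$chrom)
    call <- classify_association(hits, element = c(el$start, el$end),
                                 query_length = nchar(a$query))
    calls <- c(calls, call$arrangement)
    tsd <- detect_tsd(a$chrom, el$start, el$end)
    expect_equal(tsd$length, a$expected_tsd_length)
    if (!is.null(a$expected_tsd_seq))
      expect_identical(tsd$seq, a$expected_tsd_seq)
  }
  expect_equal(calls, c("dispersed_in_te", "tandem_in_te",
                        "dispersed_in_te", "tandem_in_te"))
})
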