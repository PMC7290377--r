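# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use different algorithmic routes
# (top-down memoized recursion, dense matrix enumeration) than the package's
# bottom-up C++ kernels.

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# top-down recursive optimal global alignment score (memoized)
oracle_global_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  ca <- chars(a); cb <- chars(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else {
      s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
      max(rec(i - 1, j - 1) + s, rec(i - 1, j) + gap, rec(i, j - 1) + gap)
    }
    memo[[key]] <- res
    res
  }
  rec(length(ca), length(cb))
}

# optimal local score = best global score over all substring pairs, floored
# at zero
oracle_local_score <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in 1:la) for (i2 in i1:la) for (j1 in 1:lb) for (j2 in j1:lb) {
    s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2),
                             match, mismatch, gap)
    if (s > best) best <- s
  }
  best
}

# dense-matrix window enumeration for the word-match dotplot
oracle_wordmatch <- function(a, b, k, S) {
  ca <- chars(a); cb <- chars(b)
  la <- length(ca); lb <- length(cb)
  Mx <- outer(ca, cb, `==`) & (ca != "N")
  W <- matrix(0, la - k + 1, lb - k + 1)
  for (t in 0:(k - 1))
    W <- W + Mx[(1 + t):(la - k + 1 + t), (1 + t):(lb - k + 1 + t),
                drop = FALSE]
  good <- which(k - W <= S, arr.ind = TRUE)  # 1-based window starts
  if (nrow(good) == 0)
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      mismatches = integer()))
  d <- good[, 1] - good[, 2]
  segs <- list()
  for (dd in sort(unique(d))) {
    ii <- sort(good[d == dd, 1])
    runs <- split(ii, cumsum(c(1, diff(ii) != 1)))
    for (r in runs) {
      i0 <- min(r); i1 <- max(r) + k - 1
      j0 <- i0 - dd; j1 <- i1 - dd
      mism <- sum(!Mx[cbind(i0:i1, j0:j1)])
      segs[[length(segs) + 1]] <- data.frame(
        a_start = i0 - 1L, a_end = i1, b_start = j0 - 1L, b_end = j1,
        mismatches = mism)
    }
  }
  out <- do.call(rbind, segs)
  out[order(out$a_start, out$b_start), , drop = FALSE]
}

# dense-matrix enumeration for the windowed dotplot
oracle_windowed <- function(a, b, w, threshold, match = 5, mismatch = -4) {
  ca <- chars(a); cb <- chars(b)
  la <- length(ca); lb <- length(cb)
  Mx <- outer(ca, cb, `==`) & (ca != "N")
  W <- matrix(0, la - w + 1, lb - w + 1)
  for (t in 0:(w - 1))
    W <- W + Mx[(1 + t):(la - w + 1 + t), (1 + t):(lb - w + 1 + t),
                drop = FALSE]
  score <- match * W + mismatch * (w - W)
  good <- which(score >= threshold, arr.ind = TRUE)
  out <- data.frame(i = good[, 1] - 1L, j = good[, 2] - 1L)
  out[order(out$i, out$j), , drop = FALSE]
}

# dinucleotide-preserving shuffle
shuffle_dinuc <- function(s) {
  ch <- chars(s)
  n <- length(ch) - (length(ch) %% 2)
  pairs <- split(ch[1:n], rep(seq_len(n / 2), each = 2))
  ord <- sample(length(pairs))
  paste(c(unlist(pairs[ord], use.names = FALSE), ch[setdiff(seq_along(ch),
                                                            1:n)]),
        collapse = "")
}

# plain evaluation of the distribution-pattern definition, written
# independently of classify_distribution
oracle_pattern <- function(starts, ends, clen, run_gap = 1e5) {
  if (length(starts) == 0) return("absent")
  o <- order(starts); starts <- starts[o]; ends <- ends[o]
  runs <- cumsum(c(1, as.integer(starts[-1] - head(ends, -1) > run_gap)))
  rs <- as.integer(table(runs))
  n <- length(starts)
  central <- mean(starts >= clen / 3 & ends <= 2 * clen / 3)
  if (central >= 0.8 && length(rs) <= 2) return("central")
  span <- (max(ends) - min(starts)) / clen
  if (span >= 0.8 && length(rs) >= max(3, n / 2) && max(rs) <= 0.3 * n)
    return("dispersed")
  "multisite"
}
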