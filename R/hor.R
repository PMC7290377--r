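## Higher-order-repeat (HOR) decomposition of satellite monomers.
##
## Satellite HOR subunits are adjacent diverged duplications: the monomer
## starts with a subunit whose diverged echo immediately follows it. The
## decomposition therefore compares the consensus prefix [0,d) with [d,2d)
## at every candidate lag d and keeps the smallest lag whose match count is
## significant under a composition-calibrated binomial null (random match
## probability = sum of squared base frequencies, which is far above 0.25 in
## the AT-rich monomers typical of plant satellites). Whether the echo is
## reported as its own subunit variant (S1-1/S1-2 + S2) or absorbed into the
## second subunit (S1 + S2) follows the remaining tail length, reproducing
## both arrangements seen in real satellite families.

#' Decompose monomers into HOR subunits
#'
#' @param monomers Character vector of monomer sequences (>= 3), or a single
#'   multimeric sequence (which is first segmented at its estimated period).
#' @param min_lag Smallest subunit length considered (default 8 bp).
#' @param alpha Family-wise significance level for the lag test (Bonferroni
#'   over all lags scanned); the null match probability is calibrated on the
#'   monomer composition excluding the candidate echo copy, so AT-rich
#'   monomers do not inflate it.
#' @param strong_support Inter-copy identity that accepts a lag outright
#'   (default 0.8, the usual satellite-annotation similarity convention;
#'   adds about 1% false positives summed over short lags).
#' @param submultiple_tol Support slack when preferring a smaller lag that
#'   divides the most significant one (sub-multiple resolution).
#' @return A list of class `hor_model`: `subunits` (data.frame label, start,
#'   end, consensus), `lag`, `support` (inter-copy identity at the lag),
#'   `p_value`, `consensus`, `n_monomers`. A single-subunit model has `lag`
#'   `NA`.
#' @export
decompose_monomer <- function(monomers, min_lag = 8L, alpha = 0.05,
                              strong_support = 0.8, submultiple_tol = 0.05) {
  if (length(monomers) == 1L) {
    pe <- estimate_period(monomers[[1]], min_period = 10L)
    if (is.null(pe))
      stop("no tandem period detected in the multimeric sequence")
    monomers <- extract_monomers(monomers[[1]], pe)$monomers
  }
  if (length(monomers) < 3)
    stop("need at least 3 monomers or one multimeric sequence")
  cons <- build_consensus(monomers)$residues
  L <- nchar(cons)
  if (L < 2 * min_lag)
    stop("monomers shorter than twice the minimum lag (", 2 * min_lag, " bp)")
  ch <- s2c(cons)
  lags <- min_lag:(L %/% 2)
  stat <- vapply(lags, function(d) {
    x <- ch[seq_len(d)]; y <- ch[d + seq_len(d)]
    M <- sum(x == y & x != "N")
    bg <- ch[-(d + seq_len(d))]          # exclude the echo copy itself
    bg <- bg[bg != "N"]
    freq <- table(factor(bg, levels = BASES))
    p0 <- sum((freq / sum(freq))^2)
    c(M = M, p = pbinom(M - 1, d, p0, lower.tail = FALSE))
  }, numeric(2))
  M <- stat["M", ]; pval <- stat["p", ]
  supp <- M / lags
  sig <- (pval * length(lags) <= alpha) | (supp >= strong_support)
  single <- data.frame(label = "S1", start = 0L, end = L,
                       consensus = cons, stringsAsFactors = FALSE)
  if (!any(sig)) {
    return(structure(list(subunits = single, lag = NA_integer_,
                          support = NA_real_, p_value = NA_real_,
                          consensus = cons,
                          n_monomers = length(monomers)),
                     class = "hor_model"))
  }
  d <- lags[sig][which.min(pval[sig])]
  # sub-multiple resolution: a smaller significant lag that divides the most
  # significant one with comparable support takes precedence
  for (ds in lags[sig & lags < d]) {
    r <- d %% ds
    if ((r <= 1 || r >= ds - 1) &&
        supp[match(ds, lags)] >= supp[match(d, lags)] - submultiple_tol) {
      d <- ds
      break
    }
  }
  tail_len <- L - 2L * d
  if (tail_len >= 2L * d) {
    sub <- data.frame(
      label = c("S1-1", "S1-2", "S2"),
      start = c(0L, d, 2L * d), end = c(d, 2L * d, L),
      stringsAsFactors = FALSE)
  } else {
    sub <- data.frame(
      label = c("S1", "S2"),
      start = c(0L, d), end = c(d, L),
      stringsAsFactors = FALSE)
  }
  sub$consensus <- substring(cons, sub$start + 1, sub$end)
  structure(list(subunits = sub, lag = as.integer(d),
                 support = supp[match(d, lags)],
                 p_value = pval[match(d, lags)],
                 consensus = cons, n_monomers = length(monomers)),
            class = "hor_model")
}

#' @export
print.hor_model <- function(x, ...) {
  if (is.na(x$lag)) {
    cat("no HOR structure:", nchar(x$consensus), "bp single-subunit model\n")
  } else {
    cat(sprintf("HOR model: lag %d bp, inter-copy identity %.2f (p = %.2g)\n",
                x$lag, x$support, x$p_value))
    print(x$subunits[, c("label", "start", "end")], row.names = FALSE)
  }
  invisible(x)
}

#' Map HOR subunit boundaries onto individual monomers
#'
#' Each monomer is globally aligned to the model consensus; subunit
#' boundaries are mapped through the alignment and per-subunit identity to
#' the subunit consensus is recorded.
#'
#' @param monomers Named character vector.
#' @param model An `hor_model` from [decompose_monomer()].
#' @param match,mismatch,gap Alignment scoring.
#' @return data.frame: monomer, label, start, end, length, identity, seq.
#' @export
hor_assign_subunits <- function(monomers, model,
                                match = 2, mismatch = -3, gap = -5) {
  stopifnot(inherits(model, "hor_model"))
  ids <- names(monomers)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_along(monomers))
  out <- list()
  for (i in seq_along(monomers)) {
    al <- global_align(model$consensus, monomers[[i]], match, mismatch, gap)
    ca <- s2c(al$aligned_a); cb <- s2c(al$aligned_b)
    cpos <- cumsum(ca != "-")  # consensus position (1-based) per column
    mpos <- cumsum(cb != "-")  # monomer position per column
    for (k in seq_len(nrow(model$subunits))) {
      s0 <- model$subunits$start[k]; s1 <- model$subunits$end[k]
      cols <- which(cpos > s0 & cpos <= s1)
      if (length(cols) == 0) next
      mstart <- if (any(cb[cols] != "-"))
        mpos[cols[which(cb[cols] != "-")[1]]] - 1L else NA_integer_
      mend <- max(mpos[cols])
      if (is.na(mstart) || mend <= mstart) next
      ident <- mean(ca[cols] == cb[cols] & ca[cols] != "-" &
                      ca[cols] != "N")
      out[[length(out) + 1L]] <- data.frame(
        monomer = ids[i], label = model$subunits$label[k],
        start = mstart, end = mend, length = mend - mstart,
        identity = ident,
        seq = substr(monomers[[i]], mstart + 1, mend),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster subunit instances into variant classes
#'
#' Average-linkage clustering on pairwise identity; the cut (up to
#' `max_classes`) maximizing the within-minus-between identity gap is kept
#' when the gap reaches `min_gap`, otherwise a single class is returned.
#' Deterministic and invariant to input order.
#'
#' @param instances Named character vector of subunit instance sequences
#'   (>= 4).
#' @param max_classes Upper bound on the number of classes (default 3).
#' @param min_gap Minimum identity gap to split (default 0.1).
#' @return A list of class `variant_classes`: `n_classes`, `membership`
#'   (named integer vector), `class_consensus`, `gap`.
#' @export
assign_subunit_variants <- function(instances, max_classes = 3L,
                                    min_gap = 0.1) {
  if (length(instances) < 4) stop("need at least 4 subunit instances")
  ids <- names(instances)
  if (is.null(ids)) ids <- sprintf("u%03d", seq_along(instances))
  names(instances) <- ids
  ord <- order(ids)                      # order invariance
  inst <- instances[ord]
  I <- identity_matrix(inst)
  hc <- hclust(as.dist(1 - I), method = "average")
  ut <- upper.tri(I)
  best_k <- 1L; best_gap <- -Inf; best_ct <- rep(1L, length(inst))
  for (k in 2:min(max_classes, length(inst) - 1L)) {
    ct <- cutree(hc, k)
    same <- outer(ct, ct, `==`)
    if (!any(same & ut)) next
    gap <- mean(I[same & ut]) - mean(I[!same & ut])
    if (gap > best_gap + 1e-12) { best_gap <- gap; best_k <- k; best_ct <- ct }
  }
  if (best_gap < min_gap) { best_k <- 1L; best_ct <- rep(1L, length(inst)) }
  names(best_ct) <- names(inst)
  membership <- best_ct[ids]             # restore caller order
  cons <- vapply(seq_len(best_k), function(cl)
    build_consensus(inst[best_ct == cl])$residues, character(1))
  structure(list(n_classes = as.integer(best_k), membership = membership,
                 class_consensus = cons,
                 gap = if (is.finite(best_gap)) best_gap else NA_real_),
            class = "variant_classes")
}

#' Per-species subunit length and identity ranges
#'
#' @param assignments data.frame from [hor_assign_subunits()] (must carry a
#'   `seq` column).
#' @param species Named character vector mapping monomer id to species.
#' @return data.frame: species, label, n, length_min, length_max,
#'   identity_min, identity_max (pairwise identity range within the group;
#'   NA when a group has a single instance). Species without assignments are
#'   omitted, not zero-filled.
#' @export
subunit_stats <- function(assignments, species) {
  sp <- species[assignments$monomer]
  if (anyNA(sp)) stop("species labels missing for some monomers")
  groups <- split(assignments, list(sp, assignments$label), drop = TRUE)
  out <- lapply(groups, function(g) {
    idr <- c(NA_real_, NA_real_)
    if (nrow(g) >= 2) {
      I <- identity_matrix(setNames(g$seq, seq_len(nrow(g))))
      idr <- range(I[upper.tri(I)])
    }
    data.frame(species = species[g$monomer[1]], label = g$label[1],
               n = nrow(g),
               length_min = min(g$length), length_max = max(g$length),
               identity_min = idr[1], identity_max = idr[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$species, res$label), ]
  rownames(res) <- NULL
  res
}
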