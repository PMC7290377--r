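## Multiple alignment, distance matrices, neighbor-joining dendrograms and
## species-specificity scoring.

## 5 x L one-hot profile (rows A,C,G,T,N) for a gapped or ungapped string;
## gap columns have all-zero rows
seq_profile <- function(gapped) {
  ch <- s2c(gapped)
  mat <- matrix(0, nrow = 5, ncol = length(ch),
                dimnames = list(c(BASES, "N"), NULL))
  for (r in seq_len(5)) mat[r, ch == rownames(mat)[r]] <- 1
  mat
}

## average column profile of an alignment (rows of gapped strings)
aln_profile <- function(aln) {
  profs <- lapply(aln, seq_profile)
  Reduce(`+`, profs) / length(profs)
}

## fraction-of-common-k-mers distance used for the guide tree
kmer_distance <- function(seqs, k = 4L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    common <- sum(pmin(ci[shared], cj[shared]))
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- if (denom > 0) 1 - common / denom else 1
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from k-mer distances (average linkage), then profile-profile
#' global alignment with the package's pairwise scoring. Deterministic: with
#' two sequences it reduces exactly to [global_align()].
#'
#' @param seqs Character vector of sequences (>= 2).
#' @param match,mismatch,gap Scoring parameters.
#' @param k Word length for guide-tree distances.
#' @return Character vector of equal-length gapped strings, named like the
#'   input, in input order.
#' @export
progressive_msa <- function(seqs, match = 2, mismatch = -3, gap = -5,
                            k = 4L) {
  stopifnot(length(seqs) >= 2)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(seqs))
  seqs <- unname(seqs)
  n <- length(seqs)
  if (n == 2) {
    al <- global_align(seqs[1], seqs[2], match, mismatch, gap)
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- ids
    return(out)
  }
  D <- kmer_distance(seqs, k)
  hc <- hclust(as.dist(D), method = "average")
  ## alignments indexed by node: negatives = leaves, positives = merges
  get_aln <- function(node, store) {
    if (node < 0) list(idx = -node, aln = seqs[-node]) else store[[node]]
  }
  store <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_aln(hc$merge[m, 1], store)
    b <- get_aln(hc$merge[m, 2], store)
    pa <- if (length(a$aln) == 1) seq_profile(a$aln) else aln_profile(a$aln)
    pb <- if (length(b$aln) == 1) seq_profile(b$aln) else aln_profile(b$aln)
    ops <- profile_nw_cpp(pa, pb, match, mismatch, gap)
    merged <- merge_alignments(a$aln, b$aln, ops)
    store[[m]] <- list(idx = c(a$idx, b$idx), aln = merged)
  }
  final <- store[[nrow(hc$merge)]]
  out <- final$aln[order(final$idx)]
  names(out) <- ids
  out
}

## apply a profile-alignment operation path to two blocks of gapped strings
merge_alignments <- function(alnA, alnB, ops) {
  chA <- strsplit(alnA, ""); chB <- strsplit(alnB, "")
  la <- length(chA[[1]]); lb <- length(chB[[1]])
  total <- length(ops)
  outA <- matrix("-", nrow = length(alnA), ncol = total)
  outB <- matrix("-", nrow = length(alnB), ncol = total)
  ia <- 0L; ib <- 0L
  for (t in seq_len(total)) {
    op <- ops[t]
    if (op == 0L || op == 1L) {
      ia <- ia + 1L
      for (r in seq_along(chA)) outA[r, t] <- chA[[r]][ia]
    }
    if (op == 0L || op == 2L) {
      ib <- ib + 1L
      for (r in seq_along(chB)) outB[r, t] <- chB[[r]][ib]
    }
  }
  c(apply(outA, 1, c2s), apply(outB, 1, c2s))
}

#' Distance matrix from a monomer collection
#'
#' Values are 1 - pairwise alignment identity (see [identity_matrix()]).
#'
#' @inheritParams identity_matrix
#' @return Symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(monomers, ...) {
  1 - identity_matrix(monomers, ...)
}

#' Neighbor-joining tree
#'
#' Canonical NJ agglomeration with deterministic tie-breaking (the pair whose
#' sorted labels are lexicographically smallest wins a Q tie). Negative
#' branch-length estimates are clamped to zero and flagged.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa).
#' @return A list of class `nj_result` with `newick` (text) and `tree`
#'   (an `ape::phylo`), plus `clamped` (count of negative branches set to 0).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor-joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  nodes <- labels          # newick fragment per active node
  key <- labels            # tie-breaking key per active node
  D <- unname(d)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- cl(vi); vj <- cl(vj)
    newdist <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    newnode <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], vi, nodes[j], vj)
    newkey <- min(key[i], key[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nodes <- c(nodes[keep], newnode)
    key <- c(key[keep], newkey)
  }
  ## final three nodes joined in a star (standard unrooted NJ termination)
  va <- cl(0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  vb <- cl(0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  vc <- cl(0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[1], va, nodes[2], vb, nodes[3], vc)
  tree <- ape::read.tree(text = newick)
  structure(list(newick = newick, tree = tree, clamped = clamped),
            class = "nj_result")
}

#' @export
print.nj_result <- function(x, ...) {
  cat("neighbor-joining tree,", length(x$tree$tip.label), "tips",
      if (x$clamped > 0) sprintf("(%d negative branches clamped)", x$clamped)
      else "", "\n")
  cat(x$newick, "\n")
  invisible(x)
}

## does any edge of the (unrooted) tree split exactly this tip set?
tips_form_clade <- function(tree, tips) {
  all_tips <- tree$tip.label
  idx <- match(tips, all_tips)
  if (anyNA(idx)) return(FALSE)
  if (length(idx) <= 1) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(idx)
  comp <- sort(setdiff(seq_along(all_tips), idx))
  for (p in parts) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}

#' Species-specificity score for a satellite family
#'
#' Score = mean within-species identity minus mean between-species identity,
#' in percentage points. The verdict is "species-specific" iff the score
#' reaches `threshold` points and at least one species forms a clade in the
#' NJ tree. Species with a single monomer are excluded from the within-species
#' mean (and noted).
#'
#' @param d Distance matrix (1 - identity) with monomer labels.
#' @param species Named character vector mapping monomer label to species.
#' @param threshold Score threshold in percentage points (default 5).
#' @return A list of class `specificity_result`: `score`, `within`,
#'   `between`, `monophyletic_species`, `excluded_species`, `verdict`.
#' @export
species_specificity <- function(d, species, threshold = 5) {
  if (!is.matrix(d)) d <- as.matrix(d)
  labs <- rownames(d)
  sp <- species[labs]
  if (anyNA(sp)) stop("species labels missing for some monomers")
  if (length(unique(sp)) < 2) stop("need at least 2 species")
  I <- 1 - d
  same <- outer(sp, sp, `==`)
  ut <- upper.tri(I)
  counts <- table(sp)
  excluded <- names(counts)[counts < 2]
  ok_within <- same & ut & !(sp[row(I)] %in% excluded)
  within <- mean(I[ok_within])
  between <- mean(I[!same & ut])
  score <- (within - between) * 100
  nj <- nj_tree(d)
  mono <- vapply(unique(sp), function(s) {
    tips <- labs[sp == s]
    length(tips) >= 2 && tips_form_clade(nj$tree, tips)
  }, logical(1))
  structure(list(score = score, within = within, between = between,
                 monophyletic_species = names(mono)[mono],
                 excluded_species = excluded,
                 verdict = score >= threshold && any(mono)),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("within %.3f between %.3f score %.1f points; %s\n",
              x$within, x$between, x$score,
              if (x$verdict) "species-specific" else "not species-specific"))
  if (length(x$monophyletic_species))
    cat("monophyletic:", paste(x$monophyletic_species, collapse = ", "), "\n")
  invisible(x)
}
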