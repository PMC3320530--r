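## Per-pair, per-locus matching fractions m_l/2, where m_l is the size of
## the multiset intersection of the two allele pairs (0, 1 or 2).
## Returns a pairs x loci matrix (NA where either call is unusable) plus
## the pair index.  Shared by simple_matching() and the locus bootstrap.
match_contributions <- function(gm, loci = colnames(gm),
                                null_as_state = FALSE) {
  m <- observed_calls(gm[, loci, drop = FALSE])
  if (!null_as_state) m[!is.na(m) & m == "00"] <- NA_character_
  gmx <- genotype_matrix(m)
  cnt <- allele_count_arrays(gmx)
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  contrib <- matrix(NA_real_, nrow(pairs), ncol(m))
  for (al in names(cnt)) {
    a <- cnt[[al]][pairs[, 1], , drop = FALSE]
    b <- cnt[[al]][pairs[, 2], , drop = FALSE]
    mm <- pmin(a, b)
    contrib <- ifelse(is.na(contrib), 0, contrib) + mm  # NA propagates via pmin
  }
  ## redo NA bookkeeping: a cell is NA iff either call is NA
  na_mask <- is.na(cnt$A[pairs[, 1], , drop = FALSE]) |
    is.na(cnt$A[pairs[, 2], , drop = FALSE])
  contrib[na_mask] <- NA_real_
  list(contrib = contrib / 2, pairs = pairs, ids = rownames(m))
}

#' Simple-matching dissimilarity
#'
#' For accessions i and j, `d = 1 - mean(m_l / 2)` over the loci typed in
#' both, where `m_l` is the number of matching alleles at locus l (the
#' multiset intersection of the two diploid allele pairs: AA vs AB share
#' one allele, AA vs AA two, AA vs BB none).  Pairwise deletion: loci
#' missing in either member are skipped.
#'
#' By default calls containing the null state "00" are treated as missing
#' (allele identity unobservable); with `null_as_state = TRUE` the null
#' allele is matched like any allele ("00" matches only "00" fully), the
#' appropriate mode for marker sets with null alleles.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param loci locus ids (default all).
#' @param null_as_state match null alleles as alleles (default `FALSE`).
#' @param strict error when a pair shares no typed locus (default `TRUE`;
#'   otherwise the distance is `NA`).
#' @return symmetric dissimilarity matrix in \[0, 1\] with zero diagonal
#'   and attribute `"n_loci"` (per-pair count of loci used).
#' @export
simple_matching <- function(gm, loci = colnames(gm), null_as_state = FALSE,
                            strict = TRUE) {
  mc <- match_contributions(gm, loci, null_as_state)
  n <- length(mc$ids)
  used <- rowSums(!is.na(mc$contrib))
  dvec <- 1 - rowMeans(mc$contrib, na.rm = TRUE)
  if (any(used == 0L)) {
    if (strict) stop("some accession pair shares no typed locus")
    dvec[used == 0L] <- NA_real_
  }
  d <- matrix(0, n, n, dimnames = list(mc$ids, mc$ids))
  nl <- matrix(0L, n, n, dimnames = list(mc$ids, mc$ids))
  d[mc$pairs] <- dvec; d[mc$pairs[, 2:1, drop = FALSE]] <- dvec
  nl[mc$pairs] <- used; nl[mc$pairs[, 2:1, drop = FALSE]] <- used
  attr(d, "n_loci") <- nl
  d
}

fmt_bl <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion.  Ties on Q are
#' broken deterministically by the lowest-index pair.  Negative branch
#' lengths are clamped to zero with the length transferred to the sister
#' edge (total path length of the joined pair preserved).  The last three
#' nodes are connected by the closed-form three-point formulas, giving the
#' usual unrooted (trifurcating-root) tree.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) with labels,
#'   n >= 3, no missing entries.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (anyNA(d)) stop("incomplete distance matrix")
  n <- nrow(d)
  if (n < 3L) stop("need >= 3 accessions")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  nodes <- labels
  D <- unname(d)
  clamp_pair <- function(vi, vj) {
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    c(max(vi, 0), max(vj, 0))
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    v <- clamp_pair(vi, D[i, j] - vi)
    newnode <- paste0("(", nodes[i], ":", fmt_bl(v[1]), ",",
                      nodes[j], ":", fmt_bl(v[2]), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newnode)
    D <- D2
  }
  v1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  v2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  v3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  txt <- paste0("(", nodes[1], ":", fmt_bl(v1), ",",
                nodes[2], ":", fmt_bl(v2), ",",
                nodes[3], ":", fmt_bl(v3), ");")
  ape::read.tree(text = txt)
}

## Canonical keys of the non-trivial bipartitions of an unrooted tree:
## each internal edge splits the leaves in two; the side not containing
## the first reference label, sorted and collapsed, is the key.
split_keys <- function(tree, ref_labels) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    v <- labs[idx]
    if (ref_labels[1] %in% v) v <- setdiff(ref_labels, v)
    if (length(v) < 2L || length(v) > length(ref_labels) - 2L) return(NA_character_)
    paste(sort(v), collapse = "|")
  }, character(1))
  keys
}

#' Bootstrap-supported neighbor-joining tree
#'
#' Resamples loci with replacement, rebuilds the simple-matching distance
#' and NJ tree per replicate, and reports for each internal bipartition of
#' the full-data tree the percentage of replicates containing it.  Supports
#' are stored as internal node labels of the returned tree (root label
#' empty).  Figures conventionally display only supports above 60%, but
#' all values are retained.
#'
#' @inheritParams simple_matching
#' @param n_reps bootstrap replicates (>= 1; 1000 is the conventional
#'   choice).
#' @param seed integer seed for the locus resampling.
#' @return list of class `nj_boot`: `tree` (`phylo`, node labels =
#'   supports), `support` (named vector, key = bipartition), `n_reps`.
#' @export
bootstrap_nj <- function(gm, loci = colnames(gm), n_reps = 100, seed = 1,
                         null_as_state = FALSE) {
  stopifnot(n_reps >= 1)
  mc <- match_contributions(gm, loci, null_as_state)
  n <- length(mc$ids)
  build <- function(contrib_cols) {
    dvec <- 1 - rowMeans(contrib_cols, na.rm = TRUE)
    if (anyNA(dvec)) stop("some accession pair shares no typed locus")
    d <- matrix(0, n, n, dimnames = list(mc$ids, mc$ids))
    d[mc$pairs] <- dvec; d[mc$pairs[, 2:1, drop = FALSE]] <- dvec
    nj_tree(d)
  }
  main <- build(mc$contrib)
  main_keys <- split_keys(main, mc$ids)
  hits <- numeric(length(main_keys))
  set.seed(seed)
  L <- ncol(mc$contrib)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_tree <- build(mc$contrib[, idx, drop = FALSE])
    rk <- split_keys(rep_tree, mc$ids)
    hits <- hits + (main_keys %in% rk[!is.na(rk)])
  }
  support <- 100 * hits / n_reps
  labels <- ifelse(is.na(main_keys), "", sprintf("%g", support))
  main$node.label <- labels
  sup <- support[!is.na(main_keys)]
  names(sup) <- main_keys[!is.na(main_keys)]
  structure(list(tree = main, support = sup, n_reps = n_reps),
            class = "nj_boot")
}
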