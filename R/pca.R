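#' PCA on within-individual allele frequencies
#'
#' Builds the individual-by-allele frequency matrix (per accession each
#' allele column holds 0, 0.5 or 1 — the allele's frequency in the diploid
#' genotype), centers columns on the *active* individuals (no variance
#' scaling: allele frequencies share a scale), and eigen-decomposes the
#' active rows only.  Supplementary individuals are projected onto the
#' resulting axes and never influence them — the standard device for
#' placing putative hybrids against the axes defined by their candidate
#' parental gene pools.  "00" and missing calls are imputed with the
#' active-column mean; columns with zero variance among active individuals
#' are dropped with a message.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param loci locus ids (default all).
#' @param active accession ids defining the axes (>= 3).
#' @param supplementary accession ids to project (default none).
#' @return list of class `pca_freq`: `eig` (axis eigenvalues), `pct_var`
#'   (percent variance per axis), `scores` (coordinates, active then
#'   supplementary rows, column per axis), `role` (per-row
#'   active/supplementary), `var_cos2` (variable x axis squared
#'   loading-correlations), `loci`.
#' @export
pca_frequencies <- function(gm, loci = colnames(gm), active,
                            supplementary = character()) {
  stopifnot(length(active) >= 3L, all(active %in% rownames(gm)),
            all(supplementary %in% rownames(gm)))
  obs <- observed_calls(gm)[c(active, supplementary), loci, drop = FALSE]
  dos <- dosage_matrix(genotype_matrix(obs)) / 2   # frequency of allele B
  X <- cbind(1 - dos, dos)
  colnames(X) <- c(paste0(loci, ".A"), paste0(loci, ".B"))
  na <- length(active)
  act <- seq_len(na)
  mu <- colMeans(X[act, , drop = FALSE], na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  keep <- apply(X[act, , drop = FALSE], 2, stats::var) > 1e-12
  if (!all(keep)) {
    message(sum(!keep), " zero-variance allele column(s) dropped")
    X <- X[, keep, drop = FALSE]
    mu <- mu[keep]
  }
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc[act, , drop = FALSE])
  k <- sum(sv$d > max(sv$d) * 1e-9)
  V <- sv$v[, seq_len(k), drop = FALSE]
  eig <- sv$d[seq_len(k)]^2 / (na - 1)
  scores <- Xc %*% V
  colnames(scores) <- paste0("axis", seq_len(k))
  var_cos2 <- matrix(NA_real_, ncol(Xc), k,
                     dimnames = list(colnames(Xc), colnames(scores)))
  for (ax in seq_len(k)) {
    r <- suppressWarnings(
      stats::cor(Xc[act, , drop = FALSE], scores[act, ax]))
    var_cos2[, ax] <- as.vector(r)^2
  }
  structure(list(
    eig = eig,
    pct_var = 100 * eig / sum(eig),
    scores = scores,
    role = c(rep("active", na), rep("supplementary", length(supplementary))),
    var_cos2 = var_cos2,
    loci = loci
  ), class = "pca_freq")
}

#' Per-locus cos2 contribution on one axis
#'
#' The two allele columns of a biallelic locus are exactly collinear, so
#' they share one cos2 value; this helper returns it per locus (taking the
#' A-allele column, falling back to B when A was dropped).
#'
#' @param pca a [pca_frequencies()] result.
#' @param axis axis number (default 1).
#' @return named numeric vector over loci (NA where both columns dropped).
#' @export
locus_cos2 <- function(pca, axis = 1) {
  out <- stats::setNames(rep(NA_real_, length(pca$loci)), pca$loci)
  for (suf in c(".B", ".A")) {
    cols <- paste0(pca$loci, suf)
    hit <- cols %in% rownames(pca$var_cos2)
    out[hit] <- pca$var_cos2[cols[hit], axis]
  }
  out
}
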