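#' Composite linkage disequilibrium between two loci
#'
#' r2 is the squared Pearson correlation of allele-dosage vectors (0/1/2
#' copies of the B allele) over pairwise-complete accessions — the
#' composite, phase-free LD estimate appropriate for unphased diploid
#' genotypes.  Significance comes from a seeded Monte-Carlo exact test:
#' one dosage vector is permuted `n_perm` times and the p-value is the
#' fraction of permutations reaching the observed r2 (with the +1
#' correction).
#'
#' @param gm observed-call [genotype_matrix()].
#' @param locusA,locusB locus ids.
#' @param accessions rows to use (default all).
#' @param n_perm permutations for the p-value (default 1000; 0 skips it).
#' @param seed integer seed for the permutations.
#' @param min_n minimum pairwise-complete accessions (default 5).
#' @return list of class `ld_result`: `locusA`, `locusB`, `r2`, `p_value`,
#'   `n`.  `r2` is `NA` when a locus has zero variance on the
#'   pairwise-complete set.
#' @export
ld_r2 <- function(gm, locusA, locusB, accessions = rownames(gm),
                  n_perm = 1000, seed = 1, min_n = 5) {
  d <- dosage_matrix(gm[accessions, c(locusA, locusB)])
  keep <- stats::complete.cases(d)
  x <- d[keep, 1]; y <- d[keep, 2]
  n <- sum(keep)
  out <- list(locusA = locusA, locusB = locusB, r2 = NA_real_,
              p_value = NA_real_, n = n)
  class(out) <- "ld_result"
  if (n < min_n) return(out)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(out)
  out$r2 <- stats::cor(x, y)^2
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (stats::cor(x, sample(y))^2 >= out$r2 - 1e-12) hits <- hits + 1L
    }
    out$p_value <- (hits + 1) / (n_perm + 1)
  }
  out
}

#' Pairwise LD over a locus panel
#'
#' Computes composite r2 for every locus pair over the given accessions
#' (vectorized through [stats::cor()] with pairwise-complete observations),
#' then optionally permutation p-values per pair.  Pairs with fewer than
#' `min_n` complete observations or zero variance are dropped with a
#' message.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param loci locus ids (default all).
#' @param accessions rows to use (default all).
#' @param n_perm permutations per pair (default 0: no p-values; exact
#'   testing every pair is expensive).
#' @param seed base seed; pair i gets `seed + i`.
#' @param min_n minimum pairwise-complete accessions (default 5).
#' @return data.frame with columns `locusA`, `locusB`, `r2`, `p_value`,
#'   `n`.
#' @export
ld_pairs <- function(gm, loci = colnames(gm), accessions = rownames(gm),
                     n_perm = 0, seed = 1, min_n = 5) {
  d <- dosage_matrix(gm[accessions, loci])
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  nonmiss <- (!is.na(d)) + 0
  npair <- t(nonmiss) %*% nonmiss
  idx <- which(upper.tri(r), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(
    locusA = loci[idx[, 1]], locusB = loci[idx[, 2]],
    r2 = r[idx]^2, p_value = NA_real_, n = npair[idx],
    stringsAsFactors = FALSE
  )
  bad <- out$n < min_n | is.na(out$r2)
  if (any(bad)) {
    message(sum(bad), " locus pair(s) dropped (too few observations or no variance)")
    out <- out[!bad, , drop = FALSE]
  }
  if (n_perm > 0) {
    for (i in seq_len(nrow(out))) {
      res <- ld_r2(gm, out$locusA[i], out$locusB[i], accessions,
                   n_perm = n_perm, seed = seed + i, min_n = min_n)
      out$p_value[i] <- res$p_value
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize an LD scan
#'
#' Mean r2, the count and percentage of pairs above the conventional
#' r2 > 0.2 linkage threshold, and counts below each significance level
#' (when p-values are present).
#'
#' @param results data.frame from [ld_pairs()].
#' @param r2_threshold threshold (default 0.2).
#' @param alpha significance levels (default `c(0.05, 0.01)`).
#' @return list: `n_pairs`, `mean_r2`, `n_above`, `pct_above`,
#'   `n_below_alpha` (named by level).
#' @export
ld_summary <- function(results, r2_threshold = 0.2, alpha = c(0.05, 0.01)) {
  if (nrow(results) == 0L) stop("no LD results")
  above <- results$r2 > r2_threshold
  nb <- vapply(alpha, function(a) sum(results$p_value < a, na.rm = TRUE),
               numeric(1))
  names(nb) <- paste0("p<", alpha)
  list(
    n_pairs = nrow(results),
    mean_r2 = mean(results$r2),
    n_above = sum(above),
    pct_above = round_half_up(100 * mean(above), 2),
    n_below_alpha = nb
  )
}
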