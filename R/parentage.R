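## Candidate true allele pairs for an observed call under a trio-scoring
## mode.  Strict: the observed alleles are taken at face value.
## Null-aware: an observed homozygote X may hide X/NULL (the array cannot
## tell), so both readings are allowed.
call_allele_options <- function(call, null_aware) {
  if (is.na(call)) return(NULL)
  opts <- list(strsplit(call, "")[[1]])
  if (null_aware && call %in% c("AA", "BB")) {
    opts <- c(opts, list(c(substr(call, 1, 1), "0")))
  }
  opts
}

#' Score a parentage trio by Mendelian compatibility
#'
#' For every locus typed in all three members, counts
#' \itemize{
#'   \item genotype-incompatible loci: no allele `a` of parent A and `b` of
#'     parent B recompose the hybrid genotype `\{a, b\}`;
#'   \item orphan-allele loci: the hybrid carries an allele observed in
#'     neither parent (a strictly stronger exclusion, robust to which
#'     parent contributed what).
#' }
#' In null-aware mode every homozygous call X (in parents and hybrid) is
#' also allowed the reading X/NULL, so a parent typed "AA" can transmit a
#' null allele — this absorbs the spurious exclusions that heterozygous
#' null alleles cause at face value.  Null-aware counts are never larger
#' than strict ones.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param hybrid,parentA,parentB accession ids.
#' @param loci locus ids (default all).
#' @param null_aware allow hidden null alleles (default `FALSE`).
#' @return list of class `parentage_report`: the trio ids,
#'   `n_loci_tested`, `n_genotype_incompatible`, `n_orphan_allele`,
#'   `percent_agreement`, `incompatible_loci`, `null_aware`.
#' @export
trio_score <- function(gm, hybrid, parentA, parentB, loci = colnames(gm),
                       null_aware = FALSE) {
  stopifnot(all(c(hybrid, parentA, parentB) %in% rownames(gm)))
  if (hybrid %in% c(parentA, parentB)) {
    warning("hybrid is also listed as a parent (self-comparison)")
  }
  obs <- observed_calls(gm[c(hybrid, parentA, parentB), loci, drop = FALSE])
  ok <- colSums(is.na(obs)) == 0L
  tested <- loci[ok]
  inc <- logical(length(tested)); orph <- logical(length(tested))
  for (k in seq_along(tested)) {
    h <- obs[1, tested[k]]; pa <- obs[2, tested[k]]; pb <- obs[3, tested[k]]
    h_opts <- call_allele_options(h, null_aware)
    a_all <- unique(unlist(call_allele_options(pa, null_aware)))
    b_all <- unique(unlist(call_allele_options(pb, null_aware)))
    compatible <- FALSE
    for (hg in h_opts) {
      hs <- sort(hg)
      for (a in a_all) for (b in b_all) {
        if (identical(sort(c(a, b)), hs)) { compatible <- TRUE; break }
      }
      if (compatible) break
    }
    inc[k] <- !compatible
    pool <- union(a_all, b_all)
    orph[k] <- !any(vapply(h_opts, function(hg) all(hg %in% pool),
                           logical(1)))
  }
  structure(list(
    hybrid = hybrid, parentA = parentA, parentB = parentB,
    n_loci_tested = length(tested),
    n_genotype_incompatible = sum(inc),
    n_orphan_allele = sum(orph),
    percent_agreement =
      round_half_up(100 * (1 - sum(inc) / length(tested)), 1),
    incompatible_loci = tested[inc],
    null_aware = null_aware
  ), class = "parentage_report")
}

#' @export
print.parentage_report <- function(x, ...) {
  cat(sprintf("trio %s = %s x %s (%s)\n", x$hybrid, x$parentA, x$parentB,
              if (x$null_aware) "null-aware" else "strict"))
  cat(sprintf("  %d loci tested; %d genotype-incompatible; %d orphan-allele; %.1f%% agreement\n",
              x$n_loci_tested, x$n_genotype_incompatible,
              x$n_orphan_allele, x$percent_agreement))
  invisible(x)
}

#' Rank candidate parent pairs for a putative hybrid
#'
#' Scores each candidate pair with [trio_score()] and orders the reports by
#' ascending genotype-incompatible count, then ascending orphan-allele
#' count, then lexically by parent ids.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param hybrid accession id.
#' @param pairs two-column matrix or data.frame of candidate parent ids.
#' @param loci locus ids (default all).
#' @param null_aware passed to [trio_score()].
#' @return data.frame, one row per candidate pair, best first.
#' @export
rank_hypotheses <- function(gm, hybrid, pairs, loci = colnames(gm),
                            null_aware = FALSE) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, nrow(pairs) >= 1L)
  reports <- lapply(seq_len(nrow(pairs)), function(i) {
    trio_score(gm, hybrid, pairs[i, 1], pairs[i, 2], loci, null_aware)
  })
  out <- data.frame(
    parentA = pairs[, 1], parentB = pairs[, 2],
    n_loci_tested = vapply(reports, `[[`, numeric(1), "n_loci_tested"),
    n_genotype_incompatible =
      vapply(reports, `[[`, numeric(1), "n_genotype_incompatible"),
    n_orphan_allele = vapply(reports, `[[`, numeric(1), "n_orphan_allele"),
    percent_agreement = vapply(reports, `[[`, numeric(1), "percent_agreement"),
    stringsAsFactors = FALSE
  )
  ord <- order(out$n_genotype_incompatible, out$n_orphan_allele,
               out$parentA, out$parentB)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
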