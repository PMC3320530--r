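#' Round half away from zero
#'
#' Printed percentages in marker reports use conventional half-up rounding
#' (81.35 -> 81.4), not the IEEE banker's rounding of [round()].
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize marker selection and transferability
#'
#' Counts the selected valid marker sets and estimates marker
#' transferability as the fraction of valid loci that carry no null allele:
#' `WONA / (WONA + WNA)`, overall and restricted to loci discovered in
#' genomic BAC-end sequences (source `"BES"`).  A marker whose null allele
#' segregates somewhere in the genus is one that failed to transfer cleanly
#' from the discovery genotype to the whole gene pool.
#'
#' @param markers a [marker_table()].
#' @return list with component counts (`n_wona`, `n_wna`, `n_excluded`,
#'   `n_wona_bes`, `n_wna_bes`) and percentages
#'   (`transferability_pct`, `transferability_bes_pct`, 1 decimal).
#' @export
summarize_selection <- function(markers) {
  if (nrow(markers) == 0L) stop("empty marker table")
  n_wona <- sum(markers$valid_set == "WONA")
  n_wna <- sum(markers$valid_set == "WNA")
  bes <- markers$source == "BES"
  n_wona_bes <- sum(markers$valid_set == "WONA" & bes)
  n_wna_bes <- sum(markers$valid_set == "WNA" & bes)
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  list(
    n_wona = n_wona,
    n_wna = n_wna,
    n_excluded = sum(markers$valid_set == "excluded"),
    n_wona_bes = n_wona_bes,
    n_wna_bes = n_wna_bes,
    transferability_pct = pct(n_wona, n_wona + n_wna),
    transferability_bes_pct = pct(n_wona_bes, n_wona_bes + n_wna_bes)
  )
}

#' Concordance between two genotype matrices
#'
#' Agreement of observable genotype states over the accessions and loci
#' shared by two matrices (e.g. array calls vs re-sequencing calls for a
#' validation subset).  Cells missing in either matrix are not compared.
#'
#' @param gm_a,gm_b [genotype_matrix()] objects.
#' @return list with `n_compared`, `n_agree` and `percent_agree`
#'   (1 decimal, half-up).
#' @export
genotype_concordance <- function(gm_a, gm_b) {
  acc <- intersect(rownames(gm_a), rownames(gm_b))
  loc <- intersect(colnames(gm_a), colnames(gm_b))
  if (!length(acc) || !length(loc)) stop("matrices share no cells")
  a <- observed_calls(gm_a[acc, loc])
  b <- observed_calls(gm_b[acc, loc])
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  n_agree <- sum(a[keep] == b[keep])
  list(n_compared = n, n_agree = n_agree,
       percent_agree = round_half_up(100 * n_agree / n, 1))
}

#' Composition of a mined SNP set
#'
#' Percentage breakdown of in-silico mined polymorphisms into transitions,
#' transversions and InDels (1 decimal, half-up).
#'
#' @param n_transition,n_transversion,n_indel counts.
#' @return list with the three counts, `n_total` and
#'   `transition_pct`, `transversion_pct`, `indel_pct`.
#' @export
snp_composition <- function(n_transition, n_transversion, n_indel = 0) {
  n_total <- n_transition + n_transversion + n_indel
  if (n_total == 0) stop("no polymorphisms")
  list(
    n_transition = n_transition, n_transversion = n_transversion,
    n_indel = n_indel, n_total = n_total,
    transition_pct = round_half_up(100 * n_transition / n_total, 1),
    transversion_pct = round_half_up(100 * n_transversion / n_total, 1),
    indel_pct = round_half_up(100 * n_indel / n_total, 1)
  )
}

#' SNP density of re-sequenced fragments
#'
#' @param n_snps SNPs found.
#' @param kb kilobases of exploitable sequence.
#' @return SNPs per kb, 1 decimal (half-up).
#' @export
snp_density <- function(n_snps, kb) {
  if (kb <= 0) stop("kb must be positive")
  round_half_up(n_snps / kb, 1)
}
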