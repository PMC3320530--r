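#' Nei expected heterozygosity
#'
#' He = 1 - sum(p_i^2) over allele frequencies at one locus (Nei's gene
#' diversity).  The plain (biased) form is the default; the small-sample
#' correction 2n/(2n-1) is available via `n`.
#'
#' @param p numeric allele-frequency vector summing to 1.
#' @param n optional number of diploid individuals; when given the
#'   unbiased correction `2n/(2n-1)` is applied.
#' @return He in \[0, 1\] (at most 0.5 for a biallelic locus).
#' @examples
#' nei_he(c(0.5, 0.5))   # 0.5
#' nei_he(c(0.05, 0.95)) # 0.095, the rare-allele boundary
#' @export
nei_he <- function(p, n = NULL) {
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  he <- 1 - sum(p^2)
  if (!is.null(n)) he <- he * 2 * n / (2 * n - 1)
  he
}

## Per-locus observable allele frequencies (A, B) within a set of calls,
## ignoring 00 and missing.  Returns c(pA, pB) or NULL if no data.
locus_allele_freq <- function(obs_calls) {
  x <- obs_calls[!is.na(obs_calls) & obs_calls != "00"]
  if (!length(x)) return(NULL)
  nA <- sum(x == "AA") * 2 + sum(x == "AB")
  nB <- sum(x == "BB") * 2 + sum(x == "AB")
  c(A = nA, B = nB) / (nA + nB)
}

se_of <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  stats::sd(v) / sqrt(length(v))
}

#' Per-group diversity summary
#'
#' For each group of the scheme (germplasm panel only) and for the pooled
#' panel ("all"), computes over the given locus set:
#' percent polymorphic loci, the number of distinct multilocus genotypes
#' (MLG, a measure of clonal redundancy), observed heterozygosity Ho,
#' Nei expected heterozygosity He, the fixation index F = 1 - Ho/He,
#' and — in null-aware mode, for marker sets with null alleles —
#' genotypic diversity GD = 1 - sum(g_i^2) over observed genotype-state
#' frequencies and the null-homozygote ("00") frequency.  Ho, He and GD
#' are means over loci with standard errors over loci; in null-aware mode
#' "00" calls are excluded from the Ho denominator (null-homozygote
#' frequency is reported separately).
#'
#' @param gm observed-call [genotype_matrix()].
#' @param scheme a [population_scheme()].
#' @param loci locus ids (default all).
#' @param null_aware treat "00" as a real genotype state (WNA marker sets).
#' @param groups group names to summarize (default all germplasm groups).
#' @return data.frame with one row per group plus a pooled `all` row.
#' @export
group_summary <- function(gm, scheme, loci = colnames(gm),
                          null_aware = FALSE, groups = NULL) {
  obs <- observed_calls(gm)[, loci, drop = FALSE]
  germ <- germplasm_ids(scheme)
  if (is.null(groups)) {
    groups <- unique(scheme$group[scheme$accession %in% germ])
  }
  one <- function(ids, label) {
    if (!length(ids)) stop("group of size 0: ", label)
    m <- obs[ids, , drop = FALSE]
    per_locus <- lapply(seq_len(ncol(m)), function(j) {
      x <- m[, j][!is.na(m[, j])]
      if (!length(x)) {
        return(list(poly = NA, ho = NA_real_, he = NA_real_,
                    gd = NA_real_, null = NA_real_))
      }
      states <- unique(x)
      called <- x[x != "00"]
      ho <- if (null_aware) {
        if (length(called)) mean(called == "AB") else NA_real_
      } else mean(x == "AB")
      p <- locus_allele_freq(x)
      he <- if (is.null(p)) NA_real_ else nei_he(p)
      g <- table(x) / length(x)
      list(poly = length(states) >= 2L, ho = ho, he = he,
           gd = 1 - sum(g^2), null = mean(x == "00"))
    })
    get <- function(f) vapply(per_locus, `[[`, numeric(1), f)
    poly <- vapply(per_locus, function(z) as.numeric(z$poly), numeric(1))
    ho <- get("ho"); he <- get("he"); gd <- get("gd"); nl <- get("null")
    mlg <- length(unique(apply(m, 1, paste, collapse = "/")))
    mean_ho <- mean(ho, na.rm = TRUE)
    mean_he <- mean(he, na.rm = TRUE)
    data.frame(
      group = label, n = length(ids),
      pct_polymorphic = 100 * mean(poly, na.rm = TRUE),
      n_mlg = mlg,
      ho = mean_ho, ho_se = se_of(ho),
      he = mean_he, he_se = se_of(he),
      f = if (!is.na(mean_he) && mean_he > 0) 1 - mean_ho / mean_he else NA_real_,
      gd = if (null_aware) mean(gd, na.rm = TRUE) else NA_real_,
      gd_se = if (null_aware) se_of(gd) else NA_real_,
      null_freq = if (null_aware) mean(nl, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(groups, function(g) one(intersect(group_ids(scheme, g), germ), g))
  rows <- c(rows, list(one(germ, "all")))
  do.call(rbind, rows)
}

## Weir & Cockerham (1984) per-locus variance components (a, b, c) for the
## A allele of a biallelic locus, from observed calls of >= 2 groups.
wc_components <- function(obs_locus, group_of) {
  keep <- !is.na(obs_locus) & obs_locus != "00"
  x <- obs_locus[keep]
  g <- group_of[keep]
  tab <- split(x, g)
  tab <- tab[lengths(tab) > 0L]
  r <- length(tab)
  if (r < 2L) return(NULL)
  n_i <- lengths(tab)
  p_i <- vapply(tab, function(v) (2 * sum(v == "AA") + sum(v == "AB")) /
                  (2 * length(v)), numeric(1))
  h_i <- vapply(tab, function(v) mean(v == "AB"), numeric(1))
  nbar <- mean(n_i)
  N <- sum(n_i)
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  pbar <- sum(n_i * p_i) / N
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / N
  if (nbar <= 1 || n_c <= 0) return(NULL)
  a <- (nbar / n_c) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir-Cockerham F-statistics
#'
#' Multi-locus Fis, Fit and Fst from the Weir & Cockerham (1984) per-locus
#' variance components (a: among groups, b: among individuals within
#' groups, c: within individuals), combined across loci as ratios of summed
#' components: Fst = sum(a)/sum(a+b+c), Fit = sum(a+b)/sum(a+b+c),
#' Fis = sum(b)/sum(b+c).  Standard errors are jackknife-over-loci.
#' "00" calls are treated as missing (allele frequencies are unobservable
#' under nulls); monomorphic loci contribute nothing.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param scheme a [population_scheme()].
#' @param loci locus ids (default all).
#' @param groups groups to contrast (default: all germplasm groups with
#'   >= 2 accessions).
#' @return list of class `fstats`: `fis`, `fit`, `fst`, their jackknife
#'   standard errors (`fis_se`, ...), `per_locus` (data.frame of
#'   components), `n_loci`.
#' @export
weir_cockerham <- function(gm, scheme, loci = colnames(gm), groups = NULL) {
  obs <- observed_calls(gm)[, loci, drop = FALSE]
  germ <- germplasm_ids(scheme)
  if (is.null(groups)) {
    tab <- table(scheme$group[scheme$accession %in% germ])
    groups <- names(tab)[tab >= 2L]
  }
  ids <- scheme$accession[scheme$group %in% groups &
                            scheme$accession %in% germ]
  if (length(unique(scheme$group[match(ids, scheme$accession)])) < 2L) {
    stop("need >= 2 groups")
  }
  group_of <- scheme$group[match(ids, scheme$accession)]
  comp <- lapply(seq_len(ncol(obs)), function(j) {
    wc_components(obs[ids, j], group_of)
  })
  keep <- !vapply(comp, is.null, logical(1))
  comp <- do.call(rbind, comp[keep])
  if (is.null(comp) || nrow(comp) == 0L ||
      sum(comp[, "a"] + comp[, "b"] + comp[, "c"]) == 0) {
    stop("locus set is monomorphic: F-statistics undefined")
  }
  est <- function(m) {
    tot <- sum(m[, "a"] + m[, "b"] + m[, "c"])
    c(fst = sum(m[, "a"]) / tot,
      fit = sum(m[, "a"] + m[, "b"]) / tot,
      fis = sum(m[, "b"]) / sum(m[, "b"] + m[, "c"]))
  }
  full <- est(comp)
  nl <- nrow(comp)
  se <- c(fst = NA_real_, fit = NA_real_, fis = NA_real_)
  if (nl >= 2L) {
    jk <- t(vapply(seq_len(nl), function(i) est(comp[-i, , drop = FALSE]),
                   numeric(3)))
    se <- sqrt((nl - 1) / nl * colSums(sweep(jk, 2, colMeans(jk))^2))
  }
  structure(list(
    fis = unname(full["fis"]), fit = unname(full["fit"]),
    fst = unname(full["fst"]),
    fis_se = unname(se["fis"]), fit_se = unname(se["fit"]),
    fst_se = unname(se["fst"]),
    per_locus = data.frame(locus = loci[keep],
                           a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
                           fst = comp[, "a"] /
                             (comp[, "a"] + comp[, "b"] + comp[, "c"]),
                           stringsAsFactors = FALSE),
    n_loci = nl
  ), class = "fstats")
}

#' @export
print.fstats <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics over %d loci\n", x$n_loci))
  cat(sprintf("  Fis = %.3f +/- %.3f\n", x$fis, x$fis_se))
  cat(sprintf("  Fit = %.3f +/- %.3f\n", x$fit, x$fit_se))
  cat(sprintf("  Fst = %.3f +/- %.3f\n", x$fst, x$fst_se))
  invisible(x)
}
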