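#' Simulation configuration for a stratified clonal gene pool
#'
#' Defines the generative scenario the analysis stack is exercised on:
#' a few strongly differentiated ancestral taxa (Balding-Nichols
#' divergence), clonally propagated interspecific hybrids with fixed
#' heterozygosity, taxon-specific null-allele frequencies concentrated on a
#' subset of null-prone loci, a small fraction of duplicated
#' (fixed-heterozygous) and assay-failed loci, and an F1 progeny of a wide
#' cross between a pummelo-like female parent and the mandarin-like hybrid
#' discovery genotype ("clementine").
#'
#' Default sample sizes mirror a typical citrus germplasm panel:
#' 12 mandarin-like (reticulata), 10 pummelo-like (maxima), 5 citron-like
#' (medica) and 5 wild papeda-like accessions, plus hybrid groups (sweet
#' orange, sour orange, clementine, grapefruit, lemon, Mexican lime) and a
#' 52-member F1 progeny.  Default null-allele frequencies are chosen so the
#' expected null-homozygote frequencies at null-prone loci are about 0.11
#' (reticulata), 0.61 (maxima), 0.64 (medica) and 0.47 (papeda):
#' high outside the discovery taxon, low within it.
#'
#' @param n_loci number of loci (default 600).
#' @param taxa data.frame with columns `name`, `n` (accessions),
#'   `divergence` (Balding-Nichols F in (0,1)) and `null_rate`
#'   (null-allele frequency at null-prone loci).
#' @param hybrids list of `list(name=, parents=c(p1, p2), n=)`; a parent is
#'   a taxon name (gamete drawn from taxon frequencies) or the name of an
#'   earlier hybrid (gamete drawn from its stored genotype).  Each hybrid
#'   is a single F1 genotype emitted as `n` clonal accessions.
#' @param progeny_size F1 progeny of the mapping cross (default 52).
#' @param prop_null_loci,prop_duplicated,prop_failed fractions of loci that
#'   are null-prone, duplicated (fixed-heterozygous paralog pairs) and
#'   technically failed (heavy missingness), defaults 0.19 / 0.04 / 0.05.
#' @param missing_rate,error_rate observation noise: per-call missing
#'   probability and symmetric allele-swap genotyping error probability.
#'   Defaults 0 (a noise-free scenario; raise them to stress the
#'   missing-data filter).
#' @param failed_missing_rate missing probability at failed loci (0.5).
#' @param discovery name of the hybrid used as marker-discovery genotype.
#' @param seed integer root seed (default 42).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 600,
                       taxa = default_taxa(),
                       hybrids = default_hybrids(),
                       progeny_size = 52,
                       prop_null_loci = 0.19,
                       prop_duplicated = 0.04,
                       prop_failed = 0.05,
                       missing_rate = 0,
                       error_rate = 0,
                       failed_missing_rate = 0.5,
                       discovery = "clementine",
                       seed = 42) {
  stopifnot(
    n_loci >= 1,
    is.data.frame(taxa),
    all(c("name", "n", "divergence", "null_rate") %in% names(taxa)),
    all(taxa$divergence > 0 & taxa$divergence < 1),
    all(taxa$null_rate >= 0 & taxa$null_rate <= 1),
    prop_null_loci >= 0, prop_duplicated >= 0, prop_failed >= 0,
    prop_null_loci + prop_duplicated + prop_failed <= 1,
    missing_rate >= 0 && missing_rate <= 1,
    error_rate >= 0 && error_rate <= 1
  )
  cfg <- list(n_loci = as.integer(n_loci), taxa = taxa, hybrids = hybrids,
              progeny_size = as.integer(progeny_size),
              prop_null_loci = prop_null_loci,
              prop_duplicated = prop_duplicated, prop_failed = prop_failed,
              missing_rate = missing_rate, error_rate = error_rate,
              failed_missing_rate = failed_missing_rate,
              discovery = discovery, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_taxa <- function() {
  data.frame(
    name = c("reticulata", "maxima", "medica", "papeda"),
    n = c(12L, 10L, 5L, 5L),
    divergence = c(0.6, 0.6, 0.6, 0.6),
    null_rate = c(0.33, 0.78, 0.80, 0.69),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_hybrids <- function() {
  list(
    list(name = "sweet_orange", parents = c("reticulata", "maxima"), n = 2L),
    list(name = "sour_orange", parents = c("reticulata", "maxima"), n = 2L),
    list(name = "clementine", parents = c("reticulata", "sweet_orange"), n = 1L),
    list(name = "grapefruit", parents = c("maxima", "sweet_orange"), n = 2L),
    list(name = "lemon", parents = c("sour_orange", "medica"), n = 2L),
    list(name = "mexican_lime", parents = c("papeda", "medica"), n = 1L)
  )
}

#' Simulate per-taxon ancestral allele frequencies
#'
#' For each locus the ancestral frequency of allele A is drawn from
#' Uniform(0.05, 0.95); each taxon's frequency is then drawn from a Beta
#' distribution with mean p and variance F p(1-p) (the Balding-Nichols
#' model), so the realized between-taxon Fst is close to the configured
#' divergence F.  Loci are also assigned their structural type here:
#' `snp` (ordinary), `null` (null-prone), `dup` (duplicated paralog pair,
#' fixed heterozygous everywhere) or `fail` (assay failure, heavy
#' missingness).
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_freqs` with elements `p_anc` (length
#'   `n_loci`), `freq` (loci x taxa matrix), `locus_type`, `locus_ids`.
#' @export
simulate_ancestral_frequencies <- function(cfg) {
  L <- cfg$n_loci
  locus_ids <- sprintf("L%04d", seq_len(L))
  p_anc <- stats::runif(L, 0.05, 0.95)
  locus_type <- rep("snp", L)
  n_dup <- round(cfg$prop_duplicated * L)
  n_fail <- round(cfg$prop_failed * L)
  n_null <- round(cfg$prop_null_loci * L)
  special <- sample.int(L, n_dup + n_fail + n_null)
  locus_type[special[seq_len(n_dup)]] <- "dup"
  locus_type[special[n_dup + seq_len(n_fail)]] <- "fail"
  locus_type[special[n_dup + n_fail + seq_len(n_null)]] <- "null"
  freq <- matrix(NA_real_, L, nrow(cfg$taxa),
                 dimnames = list(locus_ids, cfg$taxa$name))
  for (t in seq_len(nrow(cfg$taxa))) {
    f <- cfg$taxa$divergence[t]
    if (f < 1e-9) {
      freq[, t] <- p_anc
    } else {
      freq[, t] <- stats::rbeta(L, p_anc * (1 - f) / f,
                                (1 - p_anc) * (1 - f) / f)
    }
  }
  structure(list(p_anc = p_anc, freq = freq, locus_type = locus_type,
                 locus_ids = locus_ids), class = "sim_freqs")
}

## Draw one gamete (allele vector over loci) from a taxon: allele A with the
## taxon frequency, then converted to the null allele with the taxon's
## null rate at null-prone loci.
taxon_gamete <- function(freqs, cfg, taxon) {
  p <- freqs$freq[, taxon]
  al <- ifelse(stats::runif(length(p)) < p, "A", "B")
  nu <- cfg$taxa$null_rate[match(taxon, cfg$taxa$name)]
  if (nu > 0) {
    hit <- freqs$locus_type == "null" & stats::runif(length(p)) < nu
    al[hit] <- "0"
  }
  al
}

## Draw one gamete from a stored diploid genotype (random allele per locus).
genotype_gamete <- function(geno) {
  a1 <- substr(geno, 1L, 1L)
  a2 <- substr(geno, 2L, 2L)
  ifelse(stats::runif(length(geno)) < 0.5, a1, a2)
}

pair_tokens <- function(g1, g2) {
  canonicalize_calls(paste0(g1, g2))
}

#' Simulate germplasm accessions
#'
#' Basic-taxon accessions are drawn under Hardy-Weinberg equilibrium within
#' taxon (two independent gametes).  Each hybrid is one F1 genotype (one
#' gamete from each parent) replicated as clonal accessions — the fixed
#' heterozygosity of clonally propagated interspecific hybrids.  Duplicated
#' loci are heterozygous-like ("AB") in every accession including the
#' haploid control derived from the discovery genotype.
#'
#' The returned matrix holds *true* calls: null alleles appear explicitly
#' as "A0", "B0" or "00".  Apply [observe_genotypes()] to obtain what the
#' array would report.
#'
#' @param freqs result of [simulate_ancestral_frequencies()].
#' @param cfg a [sim_config()].
#' @return list with `gm` (true-call [genotype_matrix()]) and `scheme`
#'   (a [population_scheme()]; the first accession of the second taxon is
#'   the female cross parent, the discovery hybrid the male).
#' @export
simulate_accessions <- function(freqs, cfg) {
  L <- cfg$n_loci
  dup <- freqs$locus_type == "dup"
  rows <- list(); acc <- character(); grp <- character()
  for (t in seq_len(nrow(cfg$taxa))) {
    tn <- cfg$taxa$name[t]
    for (i in seq_len(cfg$taxa$n[t])) {
      g <- pair_tokens(taxon_gamete(freqs, cfg, tn),
                       taxon_gamete(freqs, cfg, tn))
      g[dup] <- "AB"
      rows[[length(rows) + 1L]] <- g
      acc <- c(acc, sprintf("%s_%02d", tn, i))
      grp <- c(grp, tn)
    }
  }
  hybrid_geno <- list()
  gamete_of <- function(parent) {
    if (parent %in% cfg$taxa$name) {
      taxon_gamete(freqs, cfg, parent)
    } else if (parent %in% names(hybrid_geno)) {
      genotype_gamete(hybrid_geno[[parent]])
    } else {
      stop("unknown hybrid parent: ", parent)
    }
  }
  for (h in cfg$hybrids) {
    g <- pair_tokens(gamete_of(h$parents[1]), gamete_of(h$parents[2]))
    g[dup] <- "AB"
    hybrid_geno[[h$name]] <- g
    for (i in seq_len(h$n)) {
      rows[[length(rows) + 1L]] <- g
      acc <- c(acc, sprintf("%s_%02d", h$name, i))
      grp <- c(grp, h$name)
    }
  }
  disc <- sprintf("%s_01", cfg$discovery)
  have_disc <- disc %in% acc
  if (have_disc) {
    ## haploid control: one gamete of the discovery genotype, doubled;
    ## duplicated loci stay heterozygous-like (both paralogs signal).
    hap <- genotype_gamete(hybrid_geno[[cfg$discovery]])
    hapg <- pair_tokens(hap, hap)
    hapg[dup] <- "AB"
    rows[[length(rows) + 1L]] <- hapg
    acc <- c(acc, "haploid_control")
    grp <- c(grp, "haploid_control")
  }
  gm <- genotype_matrix(do.call(rbind, rows), accessions = acc,
                        loci = freqs$locus_ids)
  role <- rep("germplasm", length(acc))
  if (have_disc) {
    role[acc == sprintf("%s_01", cfg$taxa$name[2])] <- "parent_female"
    role[acc == disc] <- "parent_male"
  }
  scheme <- population_scheme(acc, grp, role)
  list(gm = gm, scheme = scheme)
}

#' Simulate an F1 progeny
#'
#' Each progeny individual draws one allele per parent per locus,
#' independently across loci (no linkage map); null alleles are inherited
#' like any allele.  Loci listed in `fixed_het_loci` (duplicated paralog
#' pairs) are emitted heterozygous-like in every individual.
#'
#' @param gm [genotype_matrix()] of true calls containing both parents.
#' @param parentA,parentB accession ids.
#' @param n progeny size.
#' @param prefix accession-id prefix (default `"progeny"`).
#' @param fixed_het_loci locus ids forced to "AB".
#' @return a [genotype_matrix()] of the progeny (true calls).
#' @export
simulate_progeny <- function(gm, parentA, parentB, n, prefix = "progeny",
                             fixed_het_loci = character()) {
  stopifnot(parentA %in% rownames(gm), parentB %in% rownames(gm))
  ga <- unclass(gm)[parentA, ]
  gb <- unclass(gm)[parentB, ]
  if (anyNA(ga) || anyNA(gb)) stop("parents must be fully typed true calls")
  dup <- colnames(gm) %in% fixed_het_loci
  rows <- lapply(seq_len(n), function(i) {
    g <- pair_tokens(genotype_gamete(ga), genotype_gamete(gb))
    g[dup] <- "AB"
    g
  })
  genotype_matrix(do.call(rbind, rows),
                  accessions = sprintf("%s_%03d", prefix, seq_len(n)),
                  loci = colnames(gm))
}

#' Apply the array observation process
#'
#' Collapses null heterozygotes to the homozygous-like state the array
#' reports (`A0 -> AA`, `B0 -> BB`), then applies a symmetric allele-swap
#' genotyping error (one allele of a non-null call flipped A<->B with
#' probability `error_rate`), then missingness (`missing_rate` per call;
#' `failed_missing_rate` at failed loci).
#'
#' @param gm true-call [genotype_matrix()].
#' @param missing_rate,error_rate per-call probabilities.
#' @param failed_loci locus ids with elevated missingness.
#' @param failed_missing_rate missing probability at failed loci.
#' @return an observed-call [genotype_matrix()] (tokens
#'   `"AA","AB","BB","00"`, `NA`).
#' @export
observe_genotypes <- function(gm, missing_rate = 0, error_rate = 0,
                              failed_loci = character(),
                              failed_missing_rate = 0.5) {
  obs <- observed_calls(gm)
  if (error_rate > 0) {
    idx <- which(!is.na(obs) & obs != "00" &
                   stats::runif(length(obs)) < error_rate)
    if (length(idx)) {
      cur <- obs[idx]
      flip_first <- stats::runif(length(idx)) < 0.5
      swapped <- ifelse(cur == "AA", "AB",
                 ifelse(cur == "BB", "AB",
                        ifelse(flip_first, "AA", "BB")))
      obs[idx] <- swapped
    }
  }
  rate <- matrix(missing_rate, nrow(obs), ncol(obs))
  rate[, colnames(obs) %in% failed_loci] <- failed_missing_rate
  obs[stats::runif(length(obs)) < rate] <- NA_character_
  genotype_matrix(obs)
}

#' Ascertain markers through one discovery genotype
#'
#' Emulates discovering SNPs by sequencing a single (hybrid) genotype:
#' `CHet` keeps loci heterozygous-like in the discovery accession, `CHom`
#' keeps loci homozygous-like in it but still polymorphic across the
#' germplasm panel, `genus_wide` keeps every locus polymorphic in the
#' panel.  Works on observable states.
#'
#' @param gm observed-call [genotype_matrix()].
#' @param discovery_accession accession id.
#' @param mode `"CHet"`, `"CHom"` or `"genus_wide"`.
#' @param panel accession ids defining "polymorphic genus-wide"
#'   (default all rows).
#' @return character vector of locus ids.
#' @export
ascertain_markers <- function(gm, discovery_accession,
                              mode = c("CHet", "CHom", "genus_wide"),
                              panel = rownames(gm)) {
  mode <- match.arg(mode)
  stopifnot(discovery_accession %in% rownames(gm))
  obs <- observed_calls(gm)
  disc <- obs[discovery_accession, ]
  poly <- apply(obs[panel, , drop = FALSE], 2, function(x) {
    length(unique(x[!is.na(x)])) >= 2L
  })
  keep <- switch(mode,
    CHet = !is.na(disc) & disc == "AB",
    CHom = !is.na(disc) & disc %in% c("AA", "BB", "00") & poly,
    genus_wide = poly
  )
  out <- colnames(gm)[keep]
  if (!length(out)) warning("ascertainment returned no loci")
  out
}

## True marker category from the generative state, mirroring the
## classifier's definitions on noise-free data (see classify_locus).
truth_categories <- function(gm_true, scheme, discovery, locus_type) {
  germ <- setdiff(germplasm_ids(scheme), "haploid_control")
  tru <- unclass(gm_true)[germ, , drop = FALSE]
  obs <- observed_calls(tru)
  disc <- unclass(gm_true)[discovery, ]
  vapply(seq_len(ncol(tru)), function(j) {
    switch(locus_type[j], fail = return("C1"), dup = return("C7"))
    null_present <- any(grepl("0", tru[, j], fixed = TRUE))
    dg <- disc[j]
    if (dg == "AB") return(if (null_present) "C3" else "C2")
    if (dg %in% c("A0", "B0")) return("C4")
    states <- unique(obs[, j])
    has_null <- "00" %in% states
    if (has_null && length(states) >= 2L) return("C6")
    if (!has_null && length(states) >= 2L) return("C5")
    "C8"
  }, character(1))
}

#' Simulate a complete study dataset
#'
#' Runs the whole generative scenario: ancestral frequencies, germplasm
#' and hybrid accessions, the F1 mapping progeny, the observation process,
#' and ground-truth labels per locus.
#'
#' @param cfg a [sim_config()].
#' @return list of class `citrus_sim` with elements `truth` (true-call
#'   matrix, germplasm + progeny), `observed` (array-observed matrix),
#'   `scheme`, `freqs`, `truth_table` (locus, locus_type, true_category,
#'   per-taxon ancestral frequencies) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  freqs <- simulate_ancestral_frequencies(cfg)
  base <- simulate_accessions(freqs, cfg)
  pf <- parent_id(base$scheme, "female")
  pm <- parent_id(base$scheme, "male")
  prog <- simulate_progeny(base$gm, pf, pm, cfg$progeny_size,
                           fixed_het_loci =
                             freqs$locus_ids[freqs$locus_type == "dup"])
  truth <- genotype_matrix(rbind(unclass(base$gm), unclass(prog)))
  scheme <- population_scheme(
    c(base$scheme$accession, rownames(prog)),
    c(base$scheme$group, rep("progeny", nrow(prog))),
    c(base$scheme$role, rep("progeny", nrow(prog)))
  )
  observed <- observe_genotypes(
    truth, missing_rate = cfg$missing_rate, error_rate = cfg$error_rate,
    failed_loci = freqs$locus_ids[freqs$locus_type == "fail"],
    failed_missing_rate = cfg$failed_missing_rate
  )
  cat_true <- truth_categories(base$gm, base$scheme, pm, freqs$locus_type)
  truth_table <- data.frame(
    locus = freqs$locus_ids,
    locus_type = freqs$locus_type,
    true_category = cat_true,
    stringsAsFactors = FALSE
  )
  truth_table <- cbind(truth_table, as.data.frame(freqs$freq))
  structure(list(truth = truth, observed = observed, scheme = scheme,
                 freqs = freqs, truth_table = truth_table, config = cfg),
            class = "citrus_sim")
}
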