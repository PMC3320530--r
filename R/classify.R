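## Gametes produced by a true diploid genotype (alleles A, B, null "0").
gametes_of <- function(geno) {
  c(substr(geno, 1L, 1L), substr(geno, 2L, 2L))
}

## Observable-state distribution of offspring of a true genotype pair,
## by gamete enumeration.  States are what the array reports:
## "AA" (A-like, includes A0), "AB", "BB" (B-like), "00".
offspring_state_probs <- function(g1, g2) {
  probs <- c(AA = 0, AB = 0, BB = 0, `00` = 0)
  for (a in gametes_of(g1)) {
    for (b in gametes_of(g2)) {
      st <- observed_calls(canonicalize_calls(paste0(a, b)))
      probs[st] <- probs[st] + 0.25
    }
  }
  probs
}

## Candidate true genotypes compatible with an observed parental call.
## An observed homozygote may hide a null heterozygote; observed "00" and
## "AB" are unambiguous; a missing parent call leaves all genotypes open.
parent_candidates <- function(observed_call) {
  if (is.na(observed_call)) return(GT_ALPHABET)
  switch(observed_call,
         AA = c("AA", "A0"),
         BB = c("BB", "B0"),
         AB = "AB",
         `00` = "00",
         stop("unexpected observed call: ", observed_call))
}

n_null_alleles <- function(geno) {
  vapply(strsplit(geno, ""), function(a) sum(a == "0"), integer(1))
}

#' Candidate segregation models for a cross
#'
#' Enumerates the true-genotype hypotheses for the two parents compatible
#' with their observed calls (each observed homozygote may hide a null
#' heterozygote) and derives each hypothesis' expected observable-state
#' ratios by gamete enumeration.  E.g. `AB x A0` gives A-like : AB : B-like
#' = 2 : 1 : 1 — the unexpected B-like homozygote is what betrays the null.
#'
#' @param parent_calls length-2 character vector of observed parental calls
#'   (`NA` allowed).
#' @param allow_null include hypotheses with null alleles (default `TRUE`).
#' @return data.frame with columns `model`, `g1`, `g2`, `n_null` and the
#'   expected probabilities `AA`, `AB`, `BB`, `00`.
#' @export
segregation_models <- function(parent_calls, allow_null = TRUE) {
  stopifnot(length(parent_calls) == 2L)
  c1 <- parent_candidates(parent_calls[1])
  c2 <- parent_candidates(parent_calls[2])
  if (!allow_null) {
    c1 <- c1[n_null_alleles(c1) == 0L]
    c2 <- c2[n_null_alleles(c2) == 0L]
  }
  grid <- expand.grid(g1 = c1, g2 = c2, stringsAsFactors = FALSE)
  pr <- t(apply(grid, 1, function(g) offspring_state_probs(g[1], g[2])))
  out <- data.frame(model = paste0(grid$g1, "x", grid$g2),
                    g1 = grid$g1, g2 = grid$g2,
                    n_null = n_null_alleles(grid$g1) + n_null_alleles(grid$g2),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pr))
}

#' Goodness-of-fit of progeny segregation to candidate models
#'
#' Chi-square goodness-of-fit of the observed progeny state counts against
#' each candidate model's expected ratios.  A model expecting probability 0
#' for an observed state is impossible (p = 0).  The best model is the one
#' with the highest p-value; ties are broken in favour of the hypothesis
#' with fewer null alleles (parsimony), then by model name.  If no model
#' reaches `alpha` the best model is `"none"`.
#'
#' @param progeny_calls observed progeny calls at one locus (`NA` skipped).
#' @param parent_calls length-2 observed parental calls.
#' @param models optional model table from [segregation_models()]; derived
#'   from `parent_calls` when `NULL`.
#' @param alpha rejection level (default 0.01; this is QC screening, so no
#'   multiple-testing correction is applied across loci).
#' @param min_progeny minimum typed progeny (default 10).
#' @return list of class `segregation_test`: `counts`, `models` (with
#'   `chisq`, `df`, `p`), `best_model`, `best_p`, `n_typed`.
#' @export
test_segregation <- function(progeny_calls, parent_calls, models = NULL,
                             alpha = 0.01, min_progeny = 10) {
  obs <- observed_calls(progeny_calls)
  obs <- obs[!is.na(obs)]
  if (length(obs) < min_progeny) {
    stop("fewer than ", min_progeny, " typed progeny")
  }
  if (is.null(models)) models <- segregation_models(parent_calls)
  states <- c("AA", "AB", "BB", "00")
  counts <- table(factor(obs, levels = states))
  n <- sum(counts)
  fit <- t(vapply(seq_len(nrow(models)), function(i) {
    e <- unlist(models[i, states]) * n
    support <- e > 0
    if (any(counts[!support] > 0)) return(c(NA_real_, NA_real_, 0))
    if (sum(support) == 1L) return(c(0, 0, 1))  # monomorphic expectation met
    stat <- sum((counts[support] - e[support])^2 / e[support])
    df <- sum(support) - 1L
    c(stat, df, stats::pchisq(stat, df, lower.tail = FALSE))
  }, numeric(3)))
  models$chisq <- fit[, 1]; models$df <- fit[, 2]; models$p <- fit[, 3]
  ord <- order(-models$p, models$n_null, models$model)
  best <- models[ord[1L], ]
  structure(list(
    counts = counts,
    models = models[ord, ],
    best_model = if (best$p >= alpha) best$model else "none",
    best_p = best$p,
    best_g1 = best$g1, best_g2 = best$g2,
    n_typed = n
  ), class = "segregation_test")
}

#' Classify one locus into categories C1-C8
#'
#' Decision tree over observable evidence:
#' \itemize{
#'   \item C1 — call rate below `call_rate_min` across all samples
#'     (technical failure).
#'   \item C7 — heterozygous-like in every accession (and in the haploid
#'     control when supplied): suspected duplicated locus.
#'   \item discovery heterozygous: segregation in the progeny is tested
#'     against all candidate models; a null-bearing best model, or null
#'     homozygotes ("00") observed in the germplasm, gives C3, otherwise C2.
#'   \item discovery homozygous-like but the best segregation model makes
#'     it a null heterozygote: C4.
#'   \item otherwise (no segregation from the discovery genotype): C6 when
#'     the germplasm shows null presence/absence polymorphism, C5 when it
#'     shows ordinary SNP polymorphism without null states, C8 when
#'     monomorphic.
#' }
#' Conflicting evidence (no model fits a segregating heterozygous locus, or
#' a haploid control contradicting duplication) yields `"unassigned"` with
#' a diagnostic, never a silent guess.
#'
#' @param gm observed-call [genotype_matrix()] (germplasm + progeny).
#' @param locus locus id.
#' @param scheme a [population_scheme()] identifying germplasm, cross
#'   parents and progeny.
#' @param discovery accession id of the discovery genotype (default: the
#'   male cross parent).
#' @param haploid_control optional accession id of a haploid line derived
#'   from the discovery genotype; excluded from all other evidence.
#' @param alpha segregation rejection level (default 0.01).
#' @param call_rate_min minimum call rate (default 0.8).
#' @return list: `category`, `best_model`, `p`, `diagnostic`.
#' @export
classify_locus <- function(gm, locus, scheme,
                           discovery = parent_id(scheme, "male"),
                           haploid_control = NULL, alpha = 0.01,
                           call_rate_min = 0.8) {
  obs <- observed_calls(gm)
  x <- obs[, locus]
  samples <- setdiff(rownames(gm), haploid_control)
  call_rate <- mean(!is.na(x[samples]))
  res <- function(category, best_model = NA_character_, p = NA_real_,
                  diagnostic = NA_character_) {
    list(category = category, best_model = best_model, p = p,
         diagnostic = diagnostic)
  }
  if (call_rate < call_rate_min) return(res("C1"))
  germ <- intersect(germplasm_ids(scheme), samples)
  prog <- intersect(progeny_ids(scheme), samples)
  typed <- x[samples][!is.na(x[samples])]
  if (length(typed) && all(typed == "AB")) {
    if (!is.null(haploid_control) && !is.na(x[haploid_control])) {
      if (x[haploid_control] == "AB") return(res("C7"))
      return(res("unassigned",
                 diagnostic = "monomorphic heterozygous but haploid control homozygous"))
    }
    return(res("C7"))
  }
  disc_call <- x[discovery]
  germ_other <- setdiff(germ, discovery)
  germ_states <- unique(x[germ_other][!is.na(x[germ_other])])
  null_in_germ <- "00" %in% germ_states
  seg <- NULL
  if (length(prog) >= 10) {
    pf <- parent_id(scheme, "female")
    pm <- parent_id(scheme, "male")
    seg <- tryCatch(
      test_segregation(x[prog], c(x[pf], x[pm]), alpha = alpha),
      error = function(e) NULL)
  }
  if (!is.na(disc_call) && disc_call == "AB") {
    if (is.null(seg)) {
      return(res(if (null_in_germ) "C3" else "C2",
                 diagnostic = "no progeny; germplasm evidence only"))
    }
    if (seg$best_model == "none") {
      return(res("unassigned", "none", seg$best_p,
                 "heterozygous discovery genotype but no segregation model fits"))
    }
    best_has_null <- n_null_alleles(seg$best_g1) + n_null_alleles(seg$best_g2) > 0
    cat <- if (best_has_null || null_in_germ) "C3" else "C2"
    return(res(cat, seg$best_model, seg$best_p))
  }
  ## discovery homozygous-like (or missing): null heterozygosity in the
  ## discovery genotype is only detectable through progeny segregation
  disc_is_male <- identical(discovery, parent_id(scheme, "male"))
  if (!is.null(seg) && seg$best_model != "none" && disc_is_male) {
    disc_best <- seg$best_g2
    if (n_null_alleles(disc_best) == 1L && disc_best != "00") {
      return(res("C4", seg$best_model, seg$best_p))
    }
  }
  states <- unique(x[germ][!is.na(x[germ])])
  has_null <- "00" %in% states
  if (has_null && length(states) >= 2L) {
    return(res("C6", if (!is.null(seg)) seg$best_model else NA_character_,
               if (!is.null(seg)) seg$best_p else NA_real_))
  }
  if (!has_null && length(states) >= 2L) return(res("C5"))
  res("C8")
}

#' Classify all loci of a study
#'
#' Applies [classify_locus()] across loci and records the discovery
#' genotype's state per locus.
#'
#' @inheritParams classify_locus
#' @param source per-locus discovery source passed through to the marker
#'   table (default `"BES"`).
#' @return a [marker_table()] with extra columns `best_model`, `p`,
#'   `diagnostic` (valid sets all `"excluded"`; see [select_valid()]).
#' @export
classify_markers <- function(gm, scheme,
                             discovery = parent_id(scheme, "male"),
                             haploid_control = NULL, alpha = 0.01,
                             call_rate_min = 0.8, source = "BES") {
  obs <- observed_calls(gm)
  out <- lapply(colnames(gm), function(l) {
    classify_locus(gm, l, scheme, discovery = discovery,
                   haploid_control = haploid_control, alpha = alpha,
                   call_rate_min = call_rate_min)
  })
  disc_state <- vapply(colnames(gm), function(l) {
    d <- obs[discovery, l]
    if (is.na(d)) "unknown"
    else if (d == "AB") "het"
    else "hom"
  }, character(1))
  cat <- vapply(out, `[[`, character(1), "category")
  disc_state[cat == "C4"] <- "null_het"
  mt <- marker_table(colnames(gm), source = source, category = cat,
                     clementine_state = disc_state)
  mt$best_model <- vapply(out, `[[`, character(1), "best_model")
  mt$p <- vapply(out, `[[`, numeric(1), "p")
  mt$diagnostic <- vapply(out, `[[`, character(1), "diagnostic")
  mt
}

#' Select the valid WONA / WNA marker sets
#'
#' WONA (without null alleles) = categories C2 + C5; WNA (with null
#' alleles) = C3 + C4 + C6; in both cases only loci with a missing-data
#' fraction strictly below `max_missing` (default 0.05, i.e. "less than 5%
#' missing data") are retained.  Everything else is excluded.
#'
#' @param markers a [marker_table()] with categories assigned.
#' @param gm the observed-call [genotype_matrix()] (for missing fractions).
#' @param max_missing exclusion threshold (default 0.05).
#' @param samples accessions over which missingness is measured
#'   (default all).
#' @return the marker table with `valid_set` filled in.
#' @export
select_valid <- function(markers, gm, max_missing = 0.05,
                         samples = rownames(gm)) {
  mf <- missing_fraction(gm[samples, markers$locus])
  pass <- mf < max_missing
  vs <- rep("excluded", nrow(markers))
  vs[markers$category %in% c("C2", "C5") & pass] <- "WONA"
  vs[markers$category %in% c("C3", "C4", "C6") & pass] <- "WNA"
  markers$valid_set <- vs
  markers
}
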