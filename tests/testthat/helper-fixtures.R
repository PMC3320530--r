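## Small fixtures and independent oracles shared across test files.

## Build a genotype matrix from a named list of per-accession call vectors.
gm_from_rows <- function(rows, loci = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(m)))
  genotype_matrix(m, accessions = names(rows), loci = loci)
}

## A random valid genotype matrix (for round-trip property tests).
random_gm <- function(n_acc, n_loci, missing = 0.1) {
  tok <- c("AA", "AB", "BB", "A0", "B0", "00")
  m <- matrix(sample(tok, n_acc * n_loci, replace = TRUE), n_acc,
              dimnames = list(sprintf("acc%02d", seq_len(n_acc)),
                              sprintf("L%03d", seq_len(n_loci))))
  m[runif(length(m)) < missing] <- NA_character_
  genotype_matrix(m)
}

## The default simulated study, computed once per test run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config())
    cache
  }
})

## Independent Weir-Cockerham oracle: raw ANOVA sums of squares on allele
## indicators (gene copies nested in individuals nested in populations),
## a different computational route from the package's moment formulas.
wc_oracle <- function(gm, pops) {
  obs <- observed_calls(gm)
  comp <- matrix(0, 0, 3)
  for (j in seq_len(ncol(obs))) {
    x <- obs[, j]
    keep <- !is.na(x) & x != "00"
    x <- x[keep]; p <- pops[keep]
    copies <- list()  # per individual: two 0/1 indicators of allele A
    pop_of <- character()
    for (i in seq_along(x)) {
      y <- switch(x[i], AA = c(1, 1), AB = c(1, 0), BB = c(0, 0))
      copies[[length(copies) + 1L]] <- y
      pop_of <- c(pop_of, p[i])
    }
    ups <- unique(pop_of)
    r <- length(ups)
    if (r < 2L) next
    n_i <- table(factor(pop_of, levels = ups))
    N <- sum(n_i)
    ybar <- mean(unlist(copies))
    ybar_pop <- sapply(ups, function(u) mean(unlist(copies[pop_of == u])))
    ybar_ind <- sapply(copies, mean)
    SSP <- sum(2 * n_i * (ybar_pop - ybar)^2)
    SSI <- sum(2 * (ybar_ind - ybar_pop[pop_of])^2)
    SSG <- sum(sapply(seq_along(copies), function(i)
      sum((copies[[i]] - ybar_ind[i])^2)))
    MSP <- SSP / (r - 1)
    MSI <- SSI / (N - r)
    MSG <- SSG / N
    n_c <- (N - sum(n_i^2) / N) / (r - 1)
    a <- (MSP - MSI) / (2 * n_c)
    b <- (MSI - MSG) / 2
    cc <- MSG
    comp <- rbind(comp, c(a, b, cc))
  }
  tot <- sum(comp)
  list(fst = sum(comp[, 1]) / tot,
       fit = sum(comp[, 1] + comp[, 2]) / tot,
       fis = sum(comp[, 2]) / sum(comp[, 2] + comp[, 3]))
}

## Independent simple-matching oracle by direct allele enumeration.
sm_oracle <- function(call_i, call_j) {
  stopifnot(!is.na(call_i), !is.na(call_j))
  ai <- strsplit(call_i, "")[[1]]
  aj <- strsplit(call_j, "")[[1]]
  m <- 0
  for (a in ai) {
    hit <- match(a, aj)
    if (!is.na(hit)) { m <- m + 1; aj <- aj[-hit] }
  }
  m
}

## Exhaustive trio-compatibility oracle over observable biallelic calls:
## enumerates every gamete choice of every candidate true genotype.
trio_oracle <- function(h, pa, pb, null_aware = FALSE) {
  cands <- function(g) {
    if (null_aware && g %in% c("AA", "BB")) {
      list(strsplit(g, "")[[1]], c(substr(g, 1, 1), "0"))
    } else list(strsplit(g, "")[[1]])
  }
  compatible <- FALSE
  for (hg in cands(h)) {
    for (ga in unlist(cands(pa))) for (gb in unlist(cands(pb))) {
      if (identical(sort(c(ga, gb)), sort(hg))) compatible <- TRUE
    }
  }
  orphan <- TRUE
  pool <- union(unlist(cands(pa)), unlist(cands(pb)))
  for (hg in cands(h)) if (all(hg %in% pool)) orphan <- FALSE
  list(incompatible = !compatible, orphan = orphan)
}
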