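#' Loci mappable within a species
#'
#' A locus is potentially mappable in a species when it is polymorphic
#' within that species' accessions — it could segregate in a cross between
#' them.  With `include_null = TRUE` (marker sets with null alleles),
#' presence/absence polymorphism ("00" vs called) counts too.  When
#' `species` is a single accession id rather than a group, mappable means
#' heterozygous in that genotype (directly segregating from a cross with it
#' as parent).
#'
#' @param gm observed-call [genotype_matrix()].
#' @param scheme a [population_scheme()].
#' @param species group name, or one accession id.
#' @param loci locus ids (default all).
#' @param include_null count null presence/absence polymorphism
#'   (default `FALSE`).
#' @return character vector of locus ids.
#' @export
mappable_loci <- function(gm, scheme, species, loci = colnames(gm),
                          include_null = FALSE) {
  obs <- observed_calls(gm)[, loci, drop = FALSE]
  if (species %in% rownames(gm) && !species %in% scheme$group) {
    x <- obs[species, ]
    return(loci[!is.na(x) & x == "AB"])
  }
  ids <- group_ids(scheme, species)
  if (!length(ids)) stop("empty species group: ", species)
  keep <- apply(obs[ids, , drop = FALSE], 2, function(x) {
    st <- unique(x[!is.na(x)])
    if (!include_null) st <- setdiff(st, "00")
    ## a clonal group with a fixed heterozygote has no inter-accession
    ## polymorphism yet the locus segregates from any cross: count it
    length(st) >= 2L || "AB" %in% st
  })
  loci[keep]
}

#' Species-by-species mappability matrices
#'
#' Entry (s, t) is the number of loci mappable in both species — the
#' candidate markers for a comparative map between them; the diagonal is
#' the within-species count.  One symmetric matrix per marker class:
#' loci without null alleles (counted on SNP polymorphism) and loci with
#' null alleles (null presence/absence counts as polymorphism).
#'
#' @param gm observed-call [genotype_matrix()].
#' @param scheme a [population_scheme()].
#' @param wona_loci,wna_loci locus ids of the two valid marker classes.
#' @param species group names and/or single accession ids (default: all
#'   germplasm groups).
#' @return list of class `map_matrix`: `wona`, `wna` (symmetric count
#'   matrices) and `totals` (per-species data.frame with `wona`, `wna`
#'   and `combined` — the combined value is the conventional headline
#'   count for the species).
#' @export
mappability_matrix <- function(gm, scheme, wona_loci, wna_loci,
                               species = NULL) {
  if (is.null(species)) {
    species <- unique(scheme$group[scheme$accession %in% germplasm_ids(scheme)])
  }
  if (length(species) < 2L) stop("need >= 2 species")
  sets_wona <- lapply(species, function(s)
    mappable_loci(gm, scheme, s, wona_loci, include_null = FALSE))
  sets_wna <- lapply(species, function(s)
    mappable_loci(gm, scheme, s, wna_loci, include_null = TRUE))
  cross <- function(sets) {
    k <- length(sets)
    m <- matrix(0L, k, k, dimnames = list(species, species))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
    m
  }
  wona <- cross(sets_wona)
  wna <- cross(sets_wna)
  totals <- data.frame(
    species = species,
    wona = diag(wona), wna = diag(wna),
    combined = diag(wona) + diag(wna),
    stringsAsFactors = FALSE
  )
  structure(list(wona = wona, wna = wna, totals = totals),
            class = "map_matrix")
}
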