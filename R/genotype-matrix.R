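#' @keywords internal
"_PACKAGE"

## Canonical genotype token alphabet.  Alleles are the two array alleles A
## and B plus the null allele "0" (no array signal); a call is an unordered
## allele pair.  "00" (null homozygote, a reproducible no-signal genotype)
## is distinct from NA (assay failure / missing).
GT_ALPHABET <- c("AA", "AB", "BB", "A0", "B0", "00")
MISSING_TOKEN <- "--"

#' Canonicalize genotype call tokens
#'
#' Genotype calls are unordered allele pairs over the alphabet \{A, B, 0\},
#' where "0" denotes a null allele (no array signal).  Canonical order puts
#' A before B before 0, so "BA" becomes "AB" and "0A" becomes "A0".  The
#' missing token `"--"` (and `NA`) map to `NA`; any other token is an error.
#'
#' @param x character vector of two-character genotype tokens.
#' @return character vector of canonical tokens, `NA` for missing.
#' @examples
#' canonicalize_calls(c("BA", "0B", "AB", "--"))
#' @export
canonicalize_calls <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == MISSING_TOKEN] <- NA_character_
  idx <- which(!is.na(x))
  if (length(idx)) {
    tok <- x[idx]
    bad <- nchar(tok) != 2L
    a1 <- substr(tok, 1L, 1L)
    a2 <- substr(tok, 2L, 2L)
    ord <- c(A = 1L, B = 2L, `0` = 3L)
    bad <- bad | !(a1 %in% names(ord)) | !(a2 %in% names(ord))
    if (any(bad)) {
      stop("unknown genotype token(s): ",
           paste(unique(tok[bad]), collapse = ", "))
    }
    swap <- ord[a1] > ord[a2]
    tok[swap] <- paste0(a2[swap], a1[swap])
    x[idx] <- tok
  }
  x
}

#' Construct a genotype matrix
#'
#' The central container: a rectangular accession-by-locus grid of diploid
#' genotype calls over the alphabet `"AA","AB","BB","A0","B0","00"` with
#' `NA` for missing.  Stored calls may contain the null allele "0"; on a
#' real array a null heterozygote such as "A0" is indistinguishable from
#' "AA" — that collapse is applied by [observed_calls()] where an analysis
#' needs the observable state, never in storage.
#'
#' @param calls character matrix (accessions in rows, loci in columns) of
#'   genotype tokens; canonicalized on construction.
#' @param accessions,loci optional id vectors; default to dimnames.
#' @return an object of class `genotype_matrix` (a character matrix with
#'   unique row/column names).
#' @export
genotype_matrix <- function(calls, accessions = rownames(calls),
                            loci = colnames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(accessions) || is.null(loci)) {
    stop("accession and locus ids are required")
  }
  accessions <- as.character(accessions)
  loci <- as.character(loci)
  if (length(accessions) != nrow(calls) || length(loci) != ncol(calls)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(accessions)) stop("duplicate accession ids")
  if (anyDuplicated(loci)) stop("duplicate locus ids")
  m <- matrix(canonicalize_calls(calls), nrow = nrow(calls),
              dimnames = list(accessions, loci))
  class(m) <- c("genotype_matrix", "matrix", "array")
  m
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(m)) class(m) <- c("genotype_matrix", "matrix", "array")
  m
}

#' Observable array states of stored calls
#'
#' Collapses null heterozygotes to the homozygous-like state the array
#' reports (`A0 -> AA`, `B0 -> BB`); `00` and `NA` are unchanged.
#'
#' @param gm a [genotype_matrix()] or character vector of tokens.
#' @return object of the same shape with observable tokens
#'   `"AA","AB","BB","00"`.
#' @export
observed_calls <- function(gm) {
  out <- unclass(gm)
  out[!is.na(out) & out == "A0"] <- "AA"
  out[!is.na(out) & out == "B0"] <- "BB"
  out
}

#' Per-locus missing-data fraction
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector in \[0, 1\], one entry per locus.
#' @export
missing_fraction <- function(gm) {
  colMeans(is.na(unclass(gm)))
}

## Allele counts per call: a 3-column (A, B, 0) integer representation.
## Internal workhorse for matching / dosage computations.
allele_count_arrays <- function(gm) {
  m <- unclass(gm)
  a1 <- substr(m, 1L, 1L)
  a2 <- substr(m, 2L, 2L)
  cnt <- function(al) {
    k <- (a1 == al) + (a2 == al)
    matrix(k, nrow = nrow(m), dimnames = dimnames(m))
  }
  list(A = cnt("A"), B = cnt("B"), `0` = cnt("0"))
}

#' Allele dosage matrix
#'
#' Count of the B allele in each *observable* call (`AA`=0, `AB`=1, `BB`=2);
#' `00` and missing calls give `NA`.  This is the substrate for composite
#' linkage disequilibrium and PCA.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric accession-by-locus matrix.
#' @export
dosage_matrix <- function(gm) {
  obs <- observed_calls(gm)
  d <- matrix(NA_real_, nrow(obs), ncol(obs), dimnames = dimnames(obs))
  d[!is.na(obs) & obs == "AA"] <- 0
  d[!is.na(obs) & obs == "AB"] <- 1
  d[!is.na(obs) & obs == "BB"] <- 2
  d
}

#' Construct a population scheme
#'
#' Maps accessions to taxon/variety groups and to their role in the study
#' design.  Every accession has exactly one role: `germplasm` (diversity
#' panel member), `parent_female` / `parent_male` (parents of the mapping
#' cross, themselves germplasm members), or `progeny` (F1 individual).
#'
#' @param accession,group,role equal-length character vectors.
#' @return a `data.frame` of class `population_scheme`.
#' @export
population_scheme <- function(accession, group, role = "germplasm") {
  accession <- as.character(accession)
  group <- as.character(group)
  role <- rep_len(as.character(role), length(accession))
  ok <- c("germplasm", "parent_female", "parent_male", "progeny")
  if (!all(role %in% ok)) {
    stop("roles must be one of: ", paste(ok, collapse = ", "))
  }
  if (anyDuplicated(accession)) stop("duplicate accession in scheme")
  if (sum(role == "parent_female") > 1L || sum(role == "parent_male") > 1L) {
    stop("at most one parent of each sex")
  }
  out <- data.frame(accession = accession, group = group, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_scheme", "data.frame")
  out
}

#' Accessions of the germplasm diversity panel
#'
#' The parents of the mapping cross are germplasm accessions too (they carry
#' a dedicated role only so the cross is identifiable), so they are included
#' by default; F1 progeny never are.
#'
#' @param scheme a [population_scheme()].
#' @param include_parents include the cross parents (default `TRUE`).
#' @return character vector of accession ids.
#' @export
germplasm_ids <- function(scheme, include_parents = TRUE) {
  roles <- "germplasm"
  if (include_parents) roles <- c(roles, "parent_female", "parent_male")
  scheme$accession[scheme$role %in% roles]
}

#' @rdname germplasm_ids
#' @export
progeny_ids <- function(scheme) {
  scheme$accession[scheme$role == "progeny"]
}

#' @rdname germplasm_ids
#' @param sex `"female"` or `"male"`.
#' @export
parent_id <- function(scheme, sex = c("female", "male")) {
  sex <- match.arg(sex)
  id <- scheme$accession[scheme$role == paste0("parent_", sex)]
  if (length(id) != 1L) stop("scheme has no ", sex, " parent")
  id
}

#' Accession ids of one group
#'
#' @param scheme a [population_scheme()].
#' @param group group name.
#' @param germplasm_only restrict to the germplasm panel (default `TRUE`).
#' @return character vector of accession ids.
#' @export
group_ids <- function(scheme, group, germplasm_only = TRUE) {
  ids <- scheme$accession[scheme$group == group]
  if (germplasm_only) ids <- intersect(ids, germplasm_ids(scheme))
  ids
}
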