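#' Read a genotype table
#'
#' Plain-text genotype format: a TSV (or CSV) with a header row of locus
#' ids, one row per accession, first column the accession id, and cell
#' tokens from the declared alphabet (`"AA","AB","BB","A0","B0","00"`,
#' missing `"--"`).  Allele order within a token is free on input and
#' canonicalized on read.
#'
#' @param path file path.
#' @param sep field separator; default inferred from the file extension
#'   (`","` for `.csv`, tab otherwise).
#' @param missing_token token representing an assay failure (default `"--"`).
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = NULL, missing_token = MISSING_TOKEN) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype table needs a header and >= 1 row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    stop("ragged genotype table: rows have differing field counts")
  }
  header <- fields[[1L]]
  loci <- header[-1L]
  body <- fields[-1L]
  accessions <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(accessions)) stop("duplicate accession ids in table")
  if (anyDuplicated(loci)) stop("duplicate locus ids in table")
  cells <- do.call(rbind, lapply(body, function(f) f[-1L]))
  cells[cells == missing_token] <- NA_character_
  genotype_matrix(cells, accessions = accessions, loci = loci)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; a read of the written file
#' reproduces the matrix exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @inheritParams read_genotype_table
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path, sep = "\t",
                                 missing_token = MISSING_TOKEN) {
  m <- unclass(gm)
  m[is.na(m)] <- missing_token
  header <- paste(c("accession", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], m[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export genotypes as minimal VCF
#'
#' Writes a minimal VCF 4.2 file, one site per locus, samples in accession
#' order.  Array alleles are anonymous, so placeholder bases are emitted
#' (REF "A", ALT "C").  VCF has no native null-allele concept; the policy
#' controls how calls containing the null allele "0" are exported:
#' `"missing"` (default) writes them as `./.` and flags the site with
#' `INFO NULLALLELE=1`, `"symbolic"` keeps them as genotypes over a
#' symbolic `<NULL>` second ALT allele (index 2).  The policy is recorded
#' in the header; the TSV format remains the lossless representation.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param null_policy `"missing"` or `"symbolic"`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, null_policy = c("missing", "symbolic")) {
  null_policy <- match.arg(null_policy)
  m <- unclass(gm)
  gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  if (null_policy == "symbolic") {
    gt_map <- c(gt_map, A0 = "0/2", B0 = "1/2", `00` = "2/2")
  } else {
    gt_map <- c(gt_map, A0 = "./.", B0 = "./.", `00` = "./.")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=citrusnp %s", as.character(utils::packageVersion("citrusnp"))),
    sprintf("##nullAllelePolicy=%s", null_policy),
    "##INFO=<ID=NULLALLELE,Number=0,Type=Flag,Description=\"Site has calls containing a null allele\">",
    if (null_policy == "symbolic")
      "##ALT=<ID=NULL,Description=\"Null allele (no array signal)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(m)), function(j) {
    calls <- m[, j]
    has_null <- any(!is.na(calls) & calls %in% c("A0", "B0", "00"))
    gt <- ifelse(is.na(calls), "./.", gt_map[calls])
    alt <- if (null_policy == "symbolic" && has_null) "C,<NULL>" else "C"
    info <- if (has_null) "NULLALLELE" else "."
    paste(c("un", j, colnames(m)[j], "A", alt, ".", "PASS", info, "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Marker metadata table
#'
#' Per-locus metadata: discovery source, substitution type, assigned
#' category C1-C8 and valid-set membership.  WONA ("without null alleles",
#' categories C2+C5) and WNA ("with null alleles", C3+C4+C6) are the two
#' valid marker sets retained for genetic analysis; everything else is
#' excluded.
#'
#' @param locus character locus ids.
#' @param source `"BES"` (genomic BAC-end sequence mining) or
#'   `"candidate_gene"`.
#' @param category `"C1"`..`"C8"` or `"unassigned"`.
#' @param valid_set `"WONA"`, `"WNA"` or `"excluded"`.
#' @param substitution_type `"transition"`, `"transversion"` or `NA`.
#' @param clementine_state discovery-genotype state: `"het"`, `"hom"`,
#'   `"null_het"` or `"unknown"`.
#' @return a validated `data.frame` of class `marker_table`.
#' @export
marker_table <- function(locus, source = "BES", category = "unassigned",
                         valid_set = "excluded", substitution_type = NA,
                         clementine_state = "unknown") {
  n <- length(locus)
  out <- data.frame(
    locus = as.character(locus),
    source = rep_len(as.character(source), n),
    substitution_type = rep_len(as.character(substitution_type), n),
    category = rep_len(as.character(category), n),
    valid_set = rep_len(as.character(valid_set), n),
    clementine_state = rep_len(as.character(clementine_state), n),
    stringsAsFactors = FALSE
  )
  stopifnot(
    all(out$source %in% c("BES", "candidate_gene")),
    all(out$category %in% c(paste0("C", 1:8), "unassigned")),
    all(out$valid_set %in% c("WONA", "WNA", "excluded"))
  )
  bad_wona <- out$valid_set == "WONA" & !out$category %in% c("C2", "C5")
  bad_wna <- out$valid_set == "WNA" & !out$category %in% c("C3", "C4", "C6")
  if (any(bad_wona | bad_wna)) {
    stop("valid_set inconsistent with category (WONA = C2+C5, WNA = C3+C4+C6)")
  }
  class(out) <- c("marker_table", "data.frame")
  out
}
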