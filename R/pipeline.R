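## Deterministic per-stage seeds derived from one root seed; kept well
## below 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, classify = 211L, diversity = 307L,
               tree = 401L, pca = 503L, ld = 601L, parentage = 701L,
               mapmatrix = 809L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> classify -> (diversity, tree, pca, ld,
#' parentage, mapmatrix) from one configuration, writing every stage
#' output under `out_dir` plus a run manifest (`manifest.json`) with the
#' seed, stage list and MD5 digest of every output file.  Reruns with the
#' same configuration and seed reproduce all output digests.
#'
#' @param config a [sim_config()], a YAML file path, or a list of
#'   [sim_config()] arguments; the optional entries `bootstrap_reps`
#'   (default 100) and `ld_permutations` (default 0) tune the tree and LD
#'   stages.
#' @param out_dir output directory (created if needed).
#' @param seed root seed; each stage draws from a named substream derived
#'   from it.  Defaults to the seed in the configuration.
#' @param stages subset of
#'   `c("simulate","classify","diversity","tree","pca","ld","parentage","mapmatrix")`;
#'   `simulate` and `classify` always run (everything depends on them).
#' @return the manifest, invisibly (list with `seed`, `stages`, `files`,
#'   `digests`, `timestamp`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "citrusnp_run",
                         seed = NULL,
                         stages = c("simulate", "classify", "diversity",
                                    "tree", "pca", "ld", "parentage",
                                    "mapmatrix")) {
  extra <- list(bootstrap_reps = 100, ld_permutations = 0)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) {
    config <- as.list(config)
    for (nm in names(extra)) {
      if (!is.null(config[[nm]])) extra[[nm]] <- config[[nm]]
      config[[nm]] <- NULL
    }
    if (!is.null(config$taxa) && !is.data.frame(config$taxa)) {
      config$taxa <- do.call(rbind, lapply(config$taxa, as.data.frame))
    }
    config <- do.call(sim_config, config)
  }
  if (is.null(seed)) seed <- config$seed
  config$seed <- stage_seed(seed, "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) files <<- c(files, path)
  all_stages <- c("simulate", "classify", "diversity", "tree", "pca", "ld",
                  "parentage", "mapmatrix")
  stages <- union(c("simulate", "classify"), match.arg(stages, all_stages,
                                                       several.ok = TRUE))

  message("stage: simulate")
  sim <- simulate_dataset(config)
  emit(write_genotype_table(sim$observed, file.path(out_dir, "genotypes.tsv")))
  emit(write_tsv(sim$scheme, file.path(out_dir, "scheme.tsv")))
  emit(write_tsv(sim$truth_table, file.path(out_dir, "truth.tsv")))

  message("stage: classify")
  markers <- classify_markers(sim$observed, sim$scheme,
                              haploid_control = "haploid_control")
  markers <- select_valid(markers, sim$observed)
  emit(write_tsv(markers, file.path(out_dir, "markers.tsv")))
  wona <- markers$locus[markers$valid_set == "WONA"]
  wna <- markers$locus[markers$valid_set == "WNA"]
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  gmg <- sim$observed[germ, ]
  scheme_g <- sim$scheme[sim$scheme$accession %in% germ, ]

  if ("diversity" %in% stages) {
    message("stage: diversity")
    emit(write_tsv(group_summary(gmg, scheme_g, wona),
                   file.path(out_dir, "diversity_wona.tsv")))
    if (length(wna)) {
      emit(write_tsv(group_summary(gmg, scheme_g, wna, null_aware = TRUE),
                     file.path(out_dir, "diversity_wna.tsv")))
    }
    fs <- weir_cockerham(gmg, scheme_g, wona, groups = config$taxa$name)
    emit(write_tsv(data.frame(stat = c("Fis", "Fit", "Fst"),
                              estimate = c(fs$fis, fs$fit, fs$fst),
                              se = c(fs$fis_se, fs$fit_se, fs$fst_se)),
                   file.path(out_dir, "fstats_wona.tsv")))
  }
  if ("tree" %in% stages && length(wona) >= 3) {
    message("stage: tree")
    bt <- bootstrap_nj(gmg, wona, n_reps = extra$bootstrap_reps,
                       seed = stage_seed(seed, "tree"))
    ape::write.tree(bt$tree, file.path(out_dir, "nj_wona.nwk"))
    emit(file.path(out_dir, "nj_wona.nwk"))
    emit(write_tsv(data.frame(bipartition = names(bt$support),
                              support = unname(bt$support)),
                   file.path(out_dir, "nj_wona_support.tsv")))
  }
  if ("pca" %in% stages) {
    message("stage: pca")
    active <- unlist(lapply(config$taxa$name[1:2], group_ids,
                            scheme = scheme_g))
    supp <- setdiff(germ, active)
    pc <- pca_frequencies(gmg, wona, active = active, supplementary = supp)
    coords <- data.frame(accession = rownames(pc$scores), role = pc$role,
                         pc$scores[, seq_len(min(3, ncol(pc$scores))),
                                   drop = FALSE])
    emit(write_tsv(coords, file.path(out_dir, "pca_coords.tsv")))
  }
  if ("ld" %in% stages) {
    message("stage: ld")
    seg <- ascertain_markers(sim$observed, parent_id(sim$scheme, "male"),
                             "CHet", panel = germ)
    seg <- intersect(seg, wona)
    prog <- progeny_ids(sim$scheme)
    ld_g <- ld_pairs(sim$observed, seg, germ,
                     n_perm = extra$ld_permutations,
                     seed = stage_seed(seed, "ld"))
    ld_p <- ld_pairs(sim$observed, seg, prog,
                     n_perm = extra$ld_permutations,
                     seed = stage_seed(seed, "ld") + 1L)
    sum_tab <- rbind(
      data.frame(panel = "germplasm", mean_r2 = ld_summary(ld_g)$mean_r2,
                 pct_above_0.2 = ld_summary(ld_g)$pct_above),
      data.frame(panel = "progeny", mean_r2 = ld_summary(ld_p)$mean_r2,
                 pct_above_0.2 = ld_summary(ld_p)$pct_above)
    )
    emit(write_tsv(sum_tab, file.path(out_dir, "ld_summary.tsv")))
  }
  if ("parentage" %in% stages) {
    message("stage: parentage")
    hybrids <- vapply(config$hybrids, `[[`, character(1), "name")
    rows <- lapply(hybrids, function(h) {
      hid <- sprintf("%s_01", h)
      ## score the hybrid against every taxon-representative pair
      reps <- vapply(config$taxa$name, function(t) group_ids(scheme_g, t)[1],
                     character(1))
      pairs <- t(utils::combn(reps, 2))
      best <- rank_hypotheses(gmg, hid, pairs, wona, null_aware = TRUE)[1, ]
      cbind(hybrid = hid, best)
    })
    emit(write_tsv(do.call(rbind, rows),
                   file.path(out_dir, "parentage.tsv")))
  }
  if ("mapmatrix" %in% stages) {
    message("stage: mapmatrix")
    mm <- mappability_matrix(gmg, scheme_g, wona, wna)
    emit(write_tsv(as.data.frame(mm$wona), file.path(out_dir, "mappable_wona.tsv")))
    emit(write_tsv(as.data.frame(mm$wna), file.path(out_dir, "mappable_wna.tsv")))
    emit(write_tsv(mm$totals, file.path(out_dir, "mappable_totals.tsv")))
  }
  manifest <- list(
    seed = as.integer(seed),
    stages = stages,
    files = basename(files),
    digests = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
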