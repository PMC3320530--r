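test_that("supplementary individuals do not influence the axes", {
  sim <- default_sim()
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  active <- c(group_ids(sim$scheme, "reticulata"),
              group_ids(sim$scheme, "maxima"))
  supp <- setdiff(germ, active)
  loci <- colnames(sim$observed)[1:200]
  p1 <- suppressMessages(
    pca_frequencies(sim$observed, loci, active = active))
  p2 <- suppressMessages(
    pca_frequencies(sim$observed, loci, active = active,
                    supplementary = supp))
  k <- min(ncol(p1$scores), ncol(p2$scores))
  expect_equal(abs(p1$scores[active, 1:k]), abs(p2$scores[active, 1:k]),
               tolerance = 1e-8)
  expect_equal(p1$eig[1:k], p2$eig[1:k], tolerance = 1e-10)
  expect_true(all(p2$role[match(supp, rownames(p2$scores))] ==
                    "supplementary"))
  expect_lte(sum(p1$pct_var), 100 + 1e-8)
})

test_that("an F1 hybrid projects midway between its parental pools", {
  ## two fully fixed pools: hybrid is exactly intermediate on axis 1
  n <- 5
  rows <- c(
    setNames(rep(list(rep("AA", 30)), n), paste0("p", 1:n)),
    setNames(rep(list(rep("BB", 30)), n), paste0("q", 1:n)),
    list(hyb = rep("AB", 30)))
  gm <- gm_from_rows(rows)
  pc <- pca_frequencies(gm, active = c(paste0("p", 1:n), paste0("q", 1:n)),
                        supplementary = "hyb")
  a1 <- pc$scores[, 1]
  mid <- (mean(a1[paste0("p", 1:n)]) + mean(a1[paste0("q", 1:n)])) / 2
  expect_equal(unname(a1["hyb"]), mid, tolerance = 1e-10)
})

test_that("axis-1 locus contributions track per-locus Fst", {
  sim <- default_sim()
  sg <- sim$scheme
  active <- c(group_ids(sg, "reticulata"), group_ids(sg, "maxima"))
  wona <- sim$truth_table$locus[sim$truth_table$true_category %in%
                                  c("C2", "C5")]
  pc <- suppressMessages(
    pca_frequencies(sim$observed, wona, active = active))
  cos2 <- locus_cos2(pc, 1)
  fs <- weir_cockerham(sim$observed, sg, wona,
                       groups = c("reticulata", "maxima"))
  fst_l <- setNames(fs$per_locus$fst, fs$per_locus$locus)
  shared <- intersect(names(cos2)[!is.na(cos2)],
                      names(fst_l)[is.finite(fst_l)])
  r2 <- cor(cos2[shared], fst_l[shared])^2
  expect_gt(r2, 0.8)
})

test_that("composite r2 hits its exact endpoints", {
  calls <- c("AA", "AB", "BB", "AB", "AA", "BB", "AB", "AA")
  flip <- c(AA = "BB", AB = "AB", BB = "AA")
  gm <- gm_from_rows(lapply(setNames(seq_along(calls),
                                     paste0("s", seq_along(calls))),
                            function(i) c(calls[i], calls[i], flip[calls[i]])))
  expect_equal(ld_r2(gm, "L01", "L02", n_perm = 0)$r2, 1)
  ## perfect repulsion (dosage 2 - x) is also r2 = 1
  expect_equal(ld_r2(gm, "L01", "L03", n_perm = 0)$r2, 1)
  ## zero variance is undefined
  gm2 <- gm_from_rows(lapply(setNames(1:6, paste0("s", 1:6)),
                             function(i) c("AA", c("AA", "AB")[i %% 2 + 1])))
  expect_true(is.na(ld_r2(gm2, "L01", "L02", n_perm = 0)$r2))
})

test_that("r2 is invariant to allele-label swaps and permutation p-values are calibrated", {
  set.seed(19)
  gm <- random_gm(30, 2, missing = 0)
  r_a <- ld_r2(gm, "L001", "L002", n_perm = 200, seed = 5)
  m <- unclass(gm)
  flip <- c(AA = "BB", AB = "AB", BB = "AA", A0 = "B0", B0 = "A0",
            `00` = "00")
  m[, 1] <- flip[m[, 1]]
  r_b <- ld_r2(genotype_matrix(m), "L001", "L002", n_perm = 200, seed = 5)
  expect_equal(r_a$r2, r_b$r2)
  expect_equal(r_a$p_value, r_b$p_value)
  ## independent loci in a panmictic pool: mean r2 ~ 1/n
  set.seed(23)
  tok <- sample(c("AA", "AB", "BB"), 60 * 80, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
  gm3 <- genotype_matrix(matrix(tok, 60,
                                dimnames = list(sprintf("i%02d", 1:60),
                                                sprintf("L%03d", 1:80))))
  res <- ld_pairs(gm3)
  expect_lt(abs(mean(res$r2) - 1 / 60), 0.01)
})

test_that("LD summaries threshold correctly", {
  res <- data.frame(locusA = "a", locusB = letters[2:5],
                    r2 = c(0, 0.1, 0.3, 0.5),
                    p_value = c(0.5, 0.04, 0.009, 0.2), n = 10)
  s <- ld_summary(res)
  expect_equal(s$n_above, 2)
  expect_equal(s$pct_above, 50)
  expect_equal(unname(s$n_below_alpha), c(2, 1))
  expect_equal(ld_summary(data.frame(locusA = "a", locusB = "b", r2 = 0,
                                     p_value = NA, n = 9))$pct_above, 0)
  all0 <- data.frame(locusA = "a", locusB = c("b", "c"), r2 = c(0.3, 0.4),
                     p_value = NA, n = 9)
  expect_equal(ld_summary(all0, r2_threshold = 0)$pct_above, 100)
})

test_that("structured germplasm shows more LD than the segregating progeny", {
  sim <- default_sim()
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  disc <- parent_id(sim$scheme, "male")
  seg <- ascertain_markers(sim$observed, disc, "CHet", panel = germ)
  ld_g <- suppressMessages(ld_pairs(sim$observed, seg, germ))
  ld_p <- suppressMessages(
    ld_pairs(sim$observed, seg, progeny_ids(sim$scheme)))
  expect_gt(mean(ld_g$r2), mean(ld_p$r2))
})
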