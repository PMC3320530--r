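test_that("Nei diversity follows the closed form", {
  expect_equal(nei_he(c(0.5, 0.5)), 0.5)
  expect_equal(nei_he(c(1, 0)), 0)
  expect_error(nei_he(c(0.5, 0.2)), "sum to 1")
  ## biallelic He is maximal at p = 0.5
  p <- seq(0.01, 0.99, by = 0.01)
  he <- vapply(p, function(q) nei_he(c(q, 1 - q)), numeric(1))
  expect_equal(p[which.max(he)], 0.5)
  expect_true(all(he <= 0.5 + 1e-12))
  ## small-sample correction
  expect_equal(nei_he(c(0.5, 0.5), n = 5), 0.5 * 10 / 9)
})

test_that("group summaries count clones, states and heterozygosity", {
  gm <- gm_from_rows(list(
    c1 = c("AB", "AA", "00"), c2 = c("AB", "AA", "00"),  # two clones
    d1 = c("AA", "AB", "AA"), d2 = c("BB", "AB", "AA")))
  scheme <- population_scheme(c("c1", "c2", "d1", "d2"),
                              c("clone", "clone", "div", "div"))
  s <- group_summary(gm, scheme, null_aware = TRUE)
  clone <- s[s$group == "clone", ]
  expect_equal(clone$n_mlg, 1)
  expect_equal(clone$gd, 0)
  expect_equal(clone$pct_polymorphic, 0)
  div <- s[s$group == "div", ]
  expect_equal(div$n_mlg, 2)
  ## locus 1 in div: states AA/BB at 0.5 each -> GD 0.5
  expect_equal(div$gd, mean(c(0.5, 0, 0)))
  ## null-homozygote frequency: clone group has 00 at locus 3
  expect_equal(clone$null_freq, mean(c(0, 0, 1)))
  ## null-aware Ho excludes 00 from the denominator
  expect_equal(clone$ho, mean(c(1, 0)))
  expect_error(group_summary(gm, scheme, groups = "absent"), "size 0")
})

test_that("HWE simulated taxa show Ho close to He", {
  cfg <- sim_config(n_loci = 800, taxa = data.frame(
    name = "t1", n = 60, divergence = 0.2, null_rate = 0),
    hybrids = list(), prop_null_loci = 0, prop_duplicated = 0,
    prop_failed = 0, seed = 21)
  set.seed(cfg$seed)
  acc <- simulate_accessions(simulate_ancestral_frequencies(cfg), cfg)
  s <- group_summary(observe_genotypes(acc$gm), acc$scheme, groups = "t1")
  expect_lt(abs(s$ho[1] - s$he[1]), 0.02)
})

test_that("Weir-Cockerham matches the brute-force variance-component oracle", {
  ## 3 populations x 4 diploids x 2 loci, moderately messy genotypes
  gm <- gm_from_rows(list(
    a1 = c("AA", "AB"), a2 = c("AA", "AA"), a3 = c("AB", "AA"),
    a4 = c("AA", "AB"),
    b1 = c("AB", "BB"), b2 = c("BB", "AB"), b3 = c("AB", "BB"),
    b4 = c("BB", "BB"),
    c1 = c("AB", "AB"), c2 = c("AA", "BB"), c3 = c("AB", "AB"),
    c4 = c("BB", "AA")))
  pops <- rep(c("p1", "p2", "p3"), each = 4)
  scheme <- population_scheme(rownames(gm), pops)
  fs <- weir_cockerham(gm, scheme)
  orc <- wc_oracle(gm, pops)
  expect_equal(fs$fst, orc$fst, tolerance = 1e-10)
  expect_equal(fs$fit, orc$fit, tolerance = 1e-10)
  expect_equal(fs$fis, orc$fis, tolerance = 1e-10)
  ## oracle agreement with unequal group sizes and missing data
  gm2 <- gm_from_rows(list(
    a1 = c("AA", "AB"), a2 = c("AB", NA), a3 = c("AA", "AA"),
    b1 = c("BB", "AB"), b2 = c("AB", "BB"),
    c1 = c("AB", "AB"), c2 = c(NA, "BB"), c3 = c("BB", "AA"),
    c4 = c("AB", "AB"), c5 = c("AA", "AB")))
  pops2 <- c("p1", "p1", "p1", "p2", "p2", "p3", "p3", "p3", "p3", "p3")
  fs2 <- weir_cockerham(gm2, population_scheme(rownames(gm2), pops2))
  orc2 <- wc_oracle(gm2, pops2)
  expect_equal(fs2$fst, orc2$fst, tolerance = 1e-10)
  expect_equal(fs2$fis, orc2$fis, tolerance = 1e-10)
})

test_that("F-statistics satisfy the Wright decomposition identity", {
  sim <- default_sim()
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  sg <- sim$scheme[sim$scheme$accession %in% germ, ]
  fs <- weir_cockerham(sim$observed[germ, ], sg,
                       groups = c("reticulata", "maxima", "medica"))
  expect_equal((1 - fs$fis) * (1 - fs$fst), 1 - fs$fit, tolerance = 1e-12)
})

test_that("Fst hits its boundary cases", {
  gm <- gm_from_rows(list(a1 = rep("AA", 4), a2 = rep("AA", 4),
                          b1 = rep("BB", 4), b2 = rep("BB", 4)))
  scheme <- population_scheme(rownames(gm), rep(c("p1", "p2"), each = 2))
  expect_equal(weir_cockerham(gm, scheme)$fst, 1)
  ## random split of one panmictic pool: Fst indistinguishable from 0
  set.seed(33)
  tok <- sample(c("AA", "AB", "BB"), 40 * 60, replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
  gm2 <- genotype_matrix(matrix(tok, 40,
                                dimnames = list(sprintf("s%02d", 1:40),
                                                sprintf("L%03d", 1:60))))
  scheme2 <- population_scheme(rownames(gm2),
                               sample(rep(c("g1", "g2"), each = 20)))
  fs <- weir_cockerham(gm2, scheme2)
  expect_lt(abs(fs$fst), 3 * fs$fst_se)
  ## monomorphic set is an error
  gm3 <- gm_from_rows(list(a1 = c("AA", "AA"), a2 = c("AA", "AA"),
                           b1 = c("AA", "AA"), b2 = c("AA", "AA")))
  expect_error(weir_cockerham(gm3, population_scheme(rownames(gm3),
                                                     rep(c("p1", "p2"),
                                                         each = 2))),
               "monomorphic")
})

test_that("statistics are invariant to accession order", {
  sim <- default_sim()
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  sg <- sim$scheme[sim$scheme$accession %in% germ, ]
  gm <- sim$observed[germ, ]
  set.seed(17)
  perm <- sample(germ)
  gmp <- sim$observed[perm, ]
  loci <- colnames(gm)[1:80]
  s1 <- group_summary(gm, sg, loci)
  s2 <- group_summary(gmp, sg, loci)
  expect_equal(s1[order(s1$group), ], s2[order(s2$group), ],
               ignore_attr = TRUE)
  f1 <- weir_cockerham(gm, sg, loci, groups = c("reticulata", "maxima"))
  f2 <- weir_cockerham(gmp, sg, loci, groups = c("reticulata", "maxima"))
  expect_equal(f1$fst, f2$fst)
  d1 <- simple_matching(gm, loci)
  d2 <- simple_matching(gmp, loci)
  expect_equal(d1[germ, germ], d2[germ, germ])
})

test_that("ascertainment through one heterozygous genotype biases diversity", {
  sim <- default_sim()
  germ <- setdiff(germplasm_ids(sim$scheme), "haploid_control")
  sg <- sim$scheme[sim$scheme$accession %in% germ, ]
  gm <- sim$observed[germ, ]
  disc <- parent_id(sim$scheme, "male")
  chet <- ascertain_markers(sim$observed, disc, "CHet", panel = germ)
  chom <- ascertain_markers(sim$observed, disc, "CHom", panel = germ)
  he_disc_taxon <- function(loci) {
    s <- group_summary(gm, sg, loci, groups = "reticulata")
    s$he[s$group == "reticulata"]
  }
  expect_gt(he_disc_taxon(chet), he_disc_taxon(chom))
  taxa <- c("reticulata", "maxima", "medica", "papeda")
  expect_lt(weir_cockerham(gm, sg, chet, groups = taxa)$fst,
            weir_cockerham(gm, sg, chom, groups = taxa)$fst)
})
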