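test_that("clean segregation ratios pick the right model", {
  prog <- c(rep("AA", 26), rep("AB", 26))
  st <- test_segregation(prog, c("AB", "AA"))
  expect_equal(st$best_model, "ABxAA")
  expect_equal(st$best_p, 1)

  prog2 <- c(rep("AA", 13), rep("AB", 26), rep("BB", 13))
  st2 <- test_segregation(prog2, c("AB", "AB"))
  expect_equal(st2$best_model, "ABxAB")
  expect_equal(st2$best_p, 1)
})

test_that("impossible offspring reject every model", {
  ## BB offspring from two apparent A-homozygotes cannot be produced by
  ## any candidate, null hypotheses included
  prog <- c(rep("AA", 40), rep("BB", 10))
  st <- test_segregation(prog, c("AA", "AA"))
  expect_equal(st$best_model, "none")
  expect_equal(st$best_p, 0)
})

test_that("null-bearing models are recognized from their state patterns", {
  ## Chandler 0B x Clementine AB: expect A-like? no — gametes {0,B} x {A,B}:
  ## 0A(A-like), 0B(B-like), AB, BB(B-like) -> A-like 1/4, AB 1/4, B-like 1/2
  set.seed(1)
  prog <- sample(c(rep("AA", 13), rep("AB", 13), rep("BB", 26)))
  st <- test_segregation(prog, c("BB", "AB"))
  expect_equal(st$best_model, "B0xAB")
  ## Chandler 00 x Clementine AB: A-like / B-like 1:1
  st2 <- test_segregation(c(rep("AA", 26), rep("BB", 26)), c("00", "AB"))
  expect_equal(st2$best_model, "00xAB")
  ## Chandler 00 x Clementine A0: A-like / 00 1:1
  st3 <- test_segregation(c(rep("AA", 25), rep("00", 27)), c("00", "AA"))
  expect_equal(st3$best_model, "00xA0")
})

test_that("model ties resolve to the hypothesis without null alleles", {
  ## all-A-like progeny fits AAxAA and AAxA0 equally (p = 1 both)
  st <- test_segregation(rep("AA", 30), c("AA", "AA"))
  expect_equal(st$best_model, "AAxAA")
})

test_that("too few typed progeny is an error", {
  expect_error(test_segregation(rep("AA", 5), c("AA", "AA")), "fewer than")
})

make_trio_gm <- function(germ_calls, prog_calls) {
  rows <- c(list(chandler = germ_calls$chandler,
                 clem = germ_calls$clem),
            germ_calls$others, prog_calls)
  gm_from_rows(rows)
}

test_that("the classifier decision tree handles each category", {
  n_prog <- 20
  others <- list(g1 = "AA", g2 = "AB", g3 = "BB")
  scheme <- population_scheme(
    c("chandler", "clem", names(others), sprintf("p%02d", seq_len(n_prog))),
    c("max", "clem", "ret", "ret", "max",
      rep("progeny", n_prog)),
    c("parent_female", "parent_male", rep("germplasm", 3),
      rep("progeny", n_prog)))
  build <- function(chand, clem, others_calls, prog) {
    rows <- c(list(chandler = chand, clem = clem),
              others_calls, as.list(prog))
    names(rows) <- c("chandler", "clem", "g1", "g2", "g3",
                     sprintf("p%02d", seq_len(n_prog)))
    gm_from_rows(lapply(rows, function(x) x))
  }
  ## C2: clean AB x AA segregation, no nulls anywhere
  gm <- build("AA", "AB", list("AA", "AB", "BB"),
              rep(c("AA", "AB"), n_prog / 2))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C2")
  ## C3: null homozygotes visible in the germplasm, discovery het
  gm <- build("AA", "AB", list("00", "AB", "BB"),
              rep(c("AA", "AB"), n_prog / 2))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C3")
  ## C3 via segregation: chandler 00, progeny A-like/B-like
  gm <- build("00", "AB", list("AA", "AB", "BB"),
              rep(c("AA", "BB"), n_prog / 2))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C3")
  ## C4: discovery null heterozygote revealed by 00 x 0A segregation
  gm <- build("00", "AA", list("AA", "00", "AA"),
              rep(c("AA", "00"), n_prog / 2))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C4")
  ## C5: no segregation, SNP polymorphism in germplasm
  gm <- build("AA", "AA", list("BB", "AB", "AA"), rep("AA", n_prog))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C5")
  ## C6: no segregation, null presence/absence polymorphism
  gm <- build("AA", "AA", list("00", "AA", "00"), rep("AA", n_prog))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C6")
  ## C8: monomorphic
  gm <- build("AA", "AA", list("AA", "AA", "AA"), rep("AA", n_prog))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C8")
  ## C1: call rate below threshold
  gm <- build("AA", "AA", list(NA, NA, NA),
              c(rep(NA, 8), rep("AA", n_prog - 8)))
  expect_equal(classify_locus(gm, "L01", scheme)$category, "C1")
})

test_that("fixed heterozygosity everywhere flags a duplicated locus", {
  scheme <- population_scheme(c("a", "b", "c"), c("g1", "g1", "g2"))
  gm <- gm_from_rows(list(a = "AB", b = "AB", c = "AB", hap = "AB"))
  expect_equal(
    classify_locus(gm, "L01", scheme, discovery = "a",
                   haploid_control = "hap")$category, "C7")
  ## a homozygous haploid control contradicts duplication
  gm2 <- gm_from_rows(list(a = "AB", b = "AB", c = "AB", hap = "AA"))
  res <- classify_locus(gm2, "L01", scheme, discovery = "a",
                        haploid_control = "hap")
  expect_equal(res$category, "unassigned")
  expect_match(res$diagnostic, "haploid")
})

test_that("truth categories are recovered on the noise-free default scenario", {
  sim <- default_sim()
  mk <- classify_markers(sim$observed, sim$scheme,
                         haploid_control = "haploid_control")
  hit <- mk$category == sim$truth_table$true_category
  expect_gt(mean(hit), 0.95)
  ## exact recovery for the categories that need no segregation inference
  for (cat in c("C5", "C7", "C8")) {
    idx <- sim$truth_table$true_category == cat
    expect_true(all(mk$category[idx] == cat), label = cat)
  }
  ## near-exact for C2 (a small chi-square rejection rate is inherent)
  idx <- sim$truth_table$true_category == "C2"
  expect_gt(mean(mk$category[idx] == "C2"), 0.95)
})

test_that("null-category recovery improves with progeny size", {
  rec <- vapply(c(12, 52), function(np) {
    sim <- simulate_dataset(sim_config(n_loci = 300, progeny_size = np,
                                       seed = 31))
    mk <- classify_markers(sim$observed, sim$scheme,
                           haploid_control = "haploid_control")
    idx <- sim$truth_table$true_category %in% c("C3", "C4")
    mean(mk$category[idx] == sim$truth_table$true_category[idx])
  }, numeric(1))
  expect_gte(rec[2], rec[1])
})

test_that("valid-set selection applies the missing-data filter", {
  mk <- marker_table(c("a", "b", "c", "d"),
                     category = c("C2", "C3", "C5", "C8"))
  calls <- matrix("AA", 50, 4, dimnames = list(sprintf("s%02d", 1:50),
                                               c("a", "b", "c", "d")))
  calls[1:3, "b"] <- NA  # 6% missing
  gm <- genotype_matrix(calls)
  sel <- select_valid(mk, gm, max_missing = 0.05)
  expect_equal(sel$valid_set, c("WONA", "excluded", "WONA", "excluded"))
  sel2 <- select_valid(mk, gm, max_missing = 1.0)
  expect_equal(sel2$valid_set, c("WONA", "WNA", "WONA", "excluded"))
})
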