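test_that("allele counting contributes two alleles per non-missing call", {
  d <- matrix(c(2L, 2L, 2L, 2L, 2L,   # 5 cases all homozygous minor
                0L, 1L, 2L, NA, 0L), 10, 1,
              dimnames = list(sprintf("i%02d", 1:10), "s1"))
  g <- make_g(d)
  ct <- allele_counts(g, "s1", sprintf("i%02d", 1:5), sprintf("i%02d", 6:10))
  expect_identical(c(ct$a, ct$b), c(10, 0))

  ct2 <- allele_counts(g, "s1", sprintf("i%02d", 6:8), sprintf("i%02d", 1:2))
  expect_identical(c(ct2$a, ct2$b), c(3, 3))

  # missing genotype contributes nothing
  ct3 <- allele_counts(g, "s1", sprintf("i%02d", 8:9), sprintf("i%02d", 1:2))
  expect_identical(ct3$a + ct3$b, 2)

  expect_error(allele_counts(g, "s1", "i01", c("i01", "i02")), "overlap")
})

test_that("allelic chi-square matches its closed form and an oracle", {
  r <- allelic_test(10, 10, 10, 10)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  r2 <- allelic_test(30, 10, 10, 30)
  expect_equal(r2$chi2, 20.0)
  expect_equal(r2$p, 7.7e-6, tolerance = 1e-2)

  r3 <- allelic_test(0, 20, 0, 20)
  expect_true(r3$untestable)
  expect_equal(r3$p, 1)

  set.seed(71)
  for (i in 1:1000) {
    tb <- matrix(sample(0:50, 4, TRUE), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    mine <- allelic_test(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    ref <- suppressWarnings(chisq.test(tb, correct = FALSE))
    expect_lt(abs(mine$chi2 - unname(ref$statistic)), 1e-10)
    expect_lt(abs(mine$p - ref$p.value), 1e-10)
  }
})

test_that("case/control label swap inverts the OR and keeps the test", {
  set.seed(72)
  for (i in 1:200) {
    x <- sample(1:40, 4, TRUE)
    a <- allelic_test(x[1], x[2], x[3], x[4])
    b <- allelic_test(x[3], x[4], x[1], x[2])
    expect_equal(a$chi2, b$chi2)
    expect_equal(odds_ratio(x[1], x[2], x[3], x[4], zero_cell = "none"),
                 1 / odds_ratio(x[3], x[4], x[1], x[2], zero_cell = "none"))
  }
})

test_that("odds ratios report minor-allele enrichment with zero-cell care", {
  expect_equal(odds_ratio(30, 10, 10, 30), 9.0)
  expect_equal(odds_ratio(15, 25, 15, 25), 1.0)  # equal MAF
  expect_equal(odds_ratio(5, 0, 5, 5), 11.0)     # Haldane-corrected
  expect_error(odds_ratio(5, 0, 5, 5, zero_cell = "none"), "zero")

  # OR > 1 iff case MAF exceeds control MAF (no zero cells)
  set.seed(73)
  for (i in 1:200) {
    x <- sample(1:40, 4, TRUE)
    or <- odds_ratio(x[1], x[2], x[3], x[4])
    maf_case <- x[1] / (x[1] + x[2]); maf_ctrl <- x[3] / (x[3] + x[4])
    if (maf_case != maf_ctrl)
      expect_identical(or > 1, maf_case > maf_ctrl)
  }
})

test_that("multiple-testing adjustments match the reference step-up", {
  expect_equal(bonferroni(0.01, m = 10), 0.10)
  expect_equal(bonferroni(0.5, m = 10), 1.0)
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m")

  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(74)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_true(all(bonferroni(p) - q >= -1e-15))  # Bonferroni >= BH
  }
})

test_that("stratified case-control builds contrasts for shared hits", {
  # deterministic construction: one SNP enriched in Q4, depleted in Q1
  set.seed(75)
  n_ctrl <- 200
  d <- cbind(
    c(rep(0L, 30), rep(2L, 30), rbinom(n_ctrl, 2, 0.25)),  # associated
    rbinom(30 + 30 + n_ctrl, 2, 0.25))                     # null
  rownames(d) <- c(sprintf("q1_%02d", 1:30), sprintf("q4_%02d", 1:30),
                   sprintf("c%03d", 1:n_ctrl))
  g <- make_g(d)
  qtns <- data.frame(snp = c("s001", "s002"), stringsAsFactors = FALSE)
  cc <- run_stratified_cc(g, qtns, q1_ids = sprintf("q1_%02d", 1:30),
                          q4_ids = sprintf("q4_%02d", 1:30),
                          control_ids = sprintf("c%03d", 1:n_ctrl))
  expect_identical(nrow(cc$results), 4L)
  expect_true(all(cc$results$q_bh >= cc$results$p))
  s1 <- cc$results[cc$results$snp == "s001", ]
  expect_gt(s1$odds_ratio[s1$stratum == "Q4"], 1)
  expect_lt(s1$odds_ratio[s1$stratum == "Q1"], 1)
  expect_identical(cc$contrasts$snp, "s001")
  expect_identical(cc$contrasts$direction, "discordant")

  # fdr = 0 disables significance and hence contrasts
  cc0 <- run_stratified_cc(g, qtns, sprintf("q1_%02d", 1:30),
                           sprintf("q4_%02d", 1:30),
                           sprintf("c%03d", 1:n_ctrl), fdr = 0)
  expect_identical(nrow(cc0$contrasts), 0L)

  expect_warning(
    run_stratified_cc(g, qtns, character(), sprintf("q4_%02d", 1:30),
                      sprintf("c%03d", 1:n_ctrl)),
    "empty")
})

test_that("MZ co-twin substitution copies genotype rows exactly", {
  set.seed(76)
  d <- matrix(rbinom(40, 2, 0.3), 4, 10,
              dimnames = list(c("dA1", "dA2", "dNA1", "other"), NULL))
  g <- make_g(d)
  pm <- data.frame(target_id = c("dNA1", "dNA2"),
                   source_id = c("dA1", "dA2"), stringsAsFactors = FALSE)
  sub <- substitute_mz_cotwin_genotypes(g, pm)
  expect_identical(sub$dosage["dNA1", ], sub$dosage["dA1", ])
  expect_identical(sub$dosage["dNA2", ], sub$dosage["dA2", ])
  # allele counts over substituted twins equal counts over their sources
  ct_na <- allele_counts(sub, "s001", c("dNA1", "dNA2"), "other")
  ct_a <- allele_counts(sub, "s001", c("dA1", "dA2"), "other")
  expect_identical(ct_na[c("a", "b")], ct_a[c("a", "b")])

  # empty map is the identity; missing source warns and is excluded
  expect_identical(substitute_mz_cotwin_genotypes(g, pm[0, ]), g)
  expect_warning(
    sub2 <- substitute_mz_cotwin_genotypes(
      g, data.frame(target_id = "x", source_id = "absent")),
    "lack")
  expect_identical(sub2$dosage, g$dosage)
})

test_that("discordant-DZ filter applies both nominal cuts inclusively", {
  set.seed(77)
  n <- 40
  d <- cbind(c(rep(2L, 20), rep(0L, 20)),      # strong case enrichment
             rbinom(n, 2, 0.3))                # null
  rownames(d) <- c(sprintf("a%02d", 1:20), sprintf("u%02d", 1:20))
  g <- make_g(d)
  res <- dz_discordant_cc(g, sprintf("a%02d", 1:20), sprintf("u%02d", 1:20))
  expect_true("s001" %in% res$snp)
  expect_true(all(res$p <= 0.05 & res$odds_ratio >= 3))
  expect_identical(attr(res, "n_tested"), 2L)

  # boundary inclusivity: cuts set exactly at an observed (p, OR) retain it
  one <- dz_discordant_cc(g, sprintf("a%02d", 1:20), sprintf("u%02d", 1:20),
                          p_cut = 1, or_cut = 0)
  s2 <- one[one$snp == "s002", ]
  kept <- dz_discordant_cc(g, sprintf("a%02d", 1:20),
                           sprintf("u%02d", 1:20),
                           p_cut = s2$p, or_cut = s2$odds_ratio)
  expect_true("s002" %in% kept$snp)
  # conjunction: tightening either cut past the value excludes it
  gone <- dz_discordant_cc(g, sprintf("a%02d", 1:20), sprintf("u%02d", 1:20),
                           p_cut = s2$p * 0.99, or_cut = s2$odds_ratio + 0.01)
  expect_false("s002" %in% gone$snp)
})
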