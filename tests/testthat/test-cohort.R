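test_that("founder genotypes follow Hardy-Weinberg expectations", {
  n <- 10000
  g <- simulate_founder_genotypes(n, rep(0.5, 20), seed = 11)
  se_mean <- sqrt(2 * 0.25 / n)
  expect_true(all(abs(colMeans(g$dosage) - 1.0) < 3 * se_mean))

  g2 <- simulate_founder_genotypes(n, 0.05, seed = 12)
  het <- mean(g2$dosage == 1L)
  p_het <- 2 * 0.05 * 0.95
  expect_lt(abs(het - p_het), 3 * sqrt(p_het * (1 - p_het) / n))

  expect_error(simulate_founder_genotypes(0, 0.2), "positive integer")
  expect_error(simulate_founder_genotypes(10, c(0.2, 0.6)), "0, 0.5")
  expect_error(simulate_founder_genotypes(10, 0), "0, 0.5")
})

test_that("MZ pairs share identical genomes and DZ pairs share ~half IBD", {
  set.seed(20)
  founders <- simulate_founder_genotypes(2 * 520, runif(1000, 0.1, 0.5),
                                         seed = 21)
  tw <- simulate_twin_genotypes(founders, n_mz = 20, n_dz = 500, seed = 22)
  mz <- tw$pairs[tw$pairs$zygosity == "MZ", ]
  for (k in seq_len(nrow(mz)))
    expect_identical(tw$genotypes$dosage[mz$id1[k], ],
                     tw$genotypes$dosage[mz$id2[k], ])
  dz_ibd <- mean(tw$pairs$ibd[tw$pairs$zygosity == "DZ"])
  expect_lt(abs(dz_ibd - 0.5), 0.02)

  expect_error(simulate_twin_genotypes(founders, 600, 600), "founders")
})

test_that("homozygous-major parents always transmit dosage 0", {
  d <- matrix(0L, 2, 5, dimnames = list(c("p1", "p2"), NULL))
  founders <- make_g(d)
  tw <- simulate_twin_genotypes(founders, n_mz = 0, n_dz = 1, seed = 3)
  expect_true(all(tw$genotypes$dosage == 0L))
})

test_that("liability correlations recover the variance decomposition", {
  n_pairs <- 1000
  set.seed(30)
  founders <- simulate_founder_genotypes(2 * 2 * n_pairs,
                                         runif(200, 0.2, 0.5), seed = 31)
  tw <- simulate_twin_genotypes(founders, n_mz = n_pairs, n_dz = n_pairs,
                                seed = 32)
  pair_ids <- rep(tw$pairs$pair_id, each = 2)
  qtn <- data.frame(snp = tw$genotypes$snps$snp[1:20],
                    trait = rep(asd_traits(), each = 4),
                    effect = rnorm(20), stringsAsFactors = FALSE)
  pair_cor <- function(liab, zyg) {
    sel <- tw$pairs$zygosity == zyg
    cor(liab[tw$pairs$id1[sel], 1], liab[tw$pairs$id2[sel], 1])
  }

  # null model: no genetics, no shared environment
  l0 <- simulate_trait_liabilities(tw$genotypes, qtn, h2 = 0, c2 = 0,
                                   pair_ids, seed = 33)
  expect_lt(abs(pair_cor(l0, "MZ")), 0.05)
  expect_lt(abs(mean(l0[, 1])), 0.05)
  expect_lt(abs(var(l0[, 1]) - 1), 0.1)

  # additive expectation: MZ r = h2, DZ r = h2/2 + c2
  l1 <- simulate_trait_liabilities(tw$genotypes, qtn, h2 = 0.8, c2 = 0,
                                   pair_ids, seed = 34)
  expect_lt(abs(pair_cor(l1, "MZ") - 0.8), 0.05)
  expect_lt(abs(pair_cor(l1, "DZ") - 0.4), 0.05)

  l2 <- simulate_trait_liabilities(tw$genotypes, qtn, h2 = 0.4, c2 = 0.4,
                                   pair_ids, seed = 35)
  expect_lt(abs(pair_cor(l2, "DZ") - 0.6), 0.05)

  expect_error(simulate_trait_liabilities(tw$genotypes, qtn, 0.7, 0.3,
                                          pair_ids), "h2 \\+ c2")
})

test_that("item scores threshold the liability monotonically", {
  tm <- default_trait_map()
  liab <- matrix(c(-10, 10, 0.5, 1.5), 4, 5,
                 dimnames = list(sprintf("I%d", 1:4), asd_traits()))
  sc <- liabilities_to_item_scores(liab, tm, cut_points = c(-1, 0, 1),
                                   noise_sd = 0, seed = 1)
  expect_true(all(sc["I1", ] == 0L))   # floor of the scale
  expect_true(all(sc["I2", ] == 3L))   # ceiling
  expect_true(all(sc["I3", ] == 2L))
  expect_true(all(sc["I4", ] == 3L))
  # zero-noise cumulative score is non-decreasing in liability
  cum <- rowSums(sc)
  expect_true(all(diff(cum[order(liab[, 1])]) >= 0))

  expect_error(
    liabilities_to_item_scores(liab, tm, cut_points = c(1, 0, -1)),
    "strictly increasing")
})

test_that("subgroup labels are a pure function of zygosity and diagnoses", {
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 30, n_controls = 100,
                    n_snps = 60, n_qtns_per_trait = 2, rng_seed = 5)
  co <- simulate_cohort(cfg)
  ped <- co$pedigree
  for (i in which(!is.na(ped$pair_id))) {
    mate <- which(ped$pair_id == ped$pair_id[i] &
                  ped$individual_id != ped$individual_id[i])
    own <- ped$diagnosis[i]; co_dx <- ped$diagnosis[mate]
    expected <- if (own && co_dx) paste0("c", ped$zygosity[i])
      else if (own) paste0("dA.", ped$zygosity[i])
      else if (co_dx) paste0("dNA.", ped$zygosity[i])
      else NA_character_
    expect_identical(ped$subgroup[i], expected)
  }
  expect_true(all(is.na(ped$subgroup[ped$zygosity == "control"])))
})

test_that("a discordant MZ pair gets dA.MZ and dNA.MZ labels", {
  liab <- matrix(c(2, -2), 2, 5,
                 dimnames = list(c("a", "b"), asd_traits()))
  res <- assign_diagnosis_and_subgroups(liab, 0.5, c("MZ", "MZ"),
                                        c("p1", "p1"))
  expect_identical(res$subgroup, c("dA.MZ", "dNA.MZ"))
})

test_that("diagnosed fraction tracks the quantile threshold", {
  liab <- matrix(rnorm(10000 * 5), 10000, 5,
                 dimnames = list(sprintf("I%05d", 1:10000), asd_traits()))
  res <- assign_diagnosis_and_subgroups(liab, 0.9,
                                        rep("control", 10000),
                                        sprintf("I%05d", 1:10000))
  expect_lt(abs(mean(res$diagnosis) - 0.10), 0.01)
  expect_error(
    assign_diagnosis_and_subgroups(liab, 1.2, rep("control", 10000),
                                   sprintf("I%05d", 1:10000)),
    "diagnosis_quantile")
})
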