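test_that("item adjustment recodes special codes and caps severity", {
  raw <- data.frame(individual_id = "i1", item_01 = 8, item_02 = 3,
                    item_03 = 0, item_04 = 4, item_05 = 9, item_06 = 1)
  adj <- adjust_item_scores(raw)
  expect_identical(unlist(adj[grep("^item_", names(adj))], use.names = FALSE),
                   c(0, 3, 0, 3, 0, 1))
  expect_error(adjust_item_scores(data.frame(item_01 = -1)), "negative")
  # configurable cap and special codes
  adj2 <- adjust_item_scores(data.frame(item_01 = 5), cap = 2,
                             special_codes = 9)
  expect_identical(adj2$item_01, 2)
})

test_that("cumulative trait scores sum adjusted items per trait", {
  tm <- tiny_trait_map()
  tab <- data.frame(individual_id = c("a", "b"), subgroup = "cMZ",
                    item_01 = c(2, 0), item_02 = c(3, 0),
                    item_03 = c(1, 0), stringsAsFactors = FALSE)
  sc <- cumulative_trait_scores(tab, tm)
  expect_identical(sc$spoken_language, c(6L, 0L))

  # saturated case over the full instrument: 3 per item, 264 total
  full <- default_trait_map()
  sat <- as.data.frame(as.list(setNames(rep(3, 88), full$item)))
  sat$individual_id <- "x"
  sc_full <- cumulative_trait_scores(sat, full)
  per_trait <- table(full$trait) * 3
  for (tr in unique(full$trait))
    expect_identical(sc_full[[tr]], as.integer(per_trait[[tr]]))
  expect_identical(sum(unlist(sc_full[unique(full$trait)])), 264L)

  expect_error(cumulative_trait_scores(tab[-3], tm), "item_01")
})

test_that("trait totals always reconcile with the item totals", {
  tab <- make_item_table(list(g1 = 0.3, g2 = -0.5), n_per_group = 20,
                         seed = 7)
  sc <- cumulative_trait_scores(adjust_item_scores(tab))
  items <- tab[grep("^item_", names(tab))]
  expect_identical(rowSums(sc[asd_traits()]), rowSums(items))
})

test_that("severity profiles sort scores onto a normalized rank axis", {
  sc <- data.frame(individual_id = c("a", "b", "c"), subgroup = "cMZ",
                   spoken_language = c(3L, 1L, 2L), stringsAsFactors = FALSE)
  pr <- build_trait_profile(sc, "spoken_language", "cMZ")
  expect_equal(pr$score, c(1L, 2L, 3L))
  expect_equal(pr$rank, c(100 / 3, 200 / 3, 100))

  one <- build_trait_profile(sc[1, ], "spoken_language", "cMZ")
  expect_equal(one, data.frame(rank = 100, score = 3L))

  # invariant under row reordering
  pr2 <- build_trait_profile(sc[c(3, 1, 2), ], "spoken_language", "cMZ")
  expect_identical(pr, pr2)

  expect_error(build_trait_profile(sc, "spoken_language", "cDZ"), "empty")
})

test_that("quartile thresholds follow the Tukey hinge convention", {
  t1 <- quartile_thresholds(c(1, 2, 3, 4))
  expect_equal(t1, list(q1_threshold = 1.5, q4_threshold = 3.5))
  t2 <- quartile_thresholds(c(1, 2, 3, 4, 5))
  expect_equal(t2, list(q1_threshold = 2, q4_threshold = 4))
  t3 <- quartile_thresholds(c(5, 5, 5, 5))
  expect_equal(t3, list(q1_threshold = 5, q4_threshold = 5))
  expect_error(quartile_thresholds(c(1, 2, 3)), "at least 4")

  x <- rexp(101)
  tl <- quartile_thresholds(x, method = "linear_interpolation")
  expect_equal(tl$q1_threshold, unname(quantile(x, 0.25)))
  expect_equal(tl$q4_threshold, unname(quantile(x, 0.75)))
})

test_that("extreme selection is inclusive and flags tie overlap", {
  sc <- data.frame(individual_id = c("a", "b", "c", "d"), subgroup = "cMZ",
                   spoken_language = c(1L, 2L, 3L, 4L),
                   stringsAsFactors = FALSE)
  ext <- select_extremes(sc, "spoken_language",
                         list(q1_threshold = 1.5, q4_threshold = 3.5))
  expect_identical(ext$q1_ids, "a")
  expect_identical(ext$q4_ids, "d")
  # boundary equality is included
  ext2 <- select_extremes(sc, "spoken_language",
                          list(q1_threshold = 1, q4_threshold = 4))
  expect_identical(ext2$q1_ids, "a")

  sc$spoken_language <- rep(2L, 4)
  expect_warning(
    ext3 <- select_extremes(sc, "spoken_language",
                            list(q1_threshold = 2, q4_threshold = 2)),
    "both Q1 and Q4")
  expect_identical(ext3$q1_ids, ext3$q4_ids)

  # continuous scores: each tail captures at least a quarter minus one
  set.seed(88)
  n <- 41
  scn <- data.frame(individual_id = sprintf("i%02d", 1:n), subgroup = "x",
                    spoken_language = rnorm(n), stringsAsFactors = FALSE)
  thr <- quartile_thresholds(scn$spoken_language)
  extn <- select_extremes(scn, "spoken_language", thr)
  expect_gte(length(extn$q1_ids), n / 4 - 1)
  expect_gte(length(extn$q4_ids), n / 4 - 1)
})

test_that("pooled t test matches its closed form and reference", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- two_sample_t(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r2$t, -2 / sqrt(2 / 3))   # -2.449 under pooled variance 1
  expect_equal(r2$t, -2.449, tolerance = 1e-3)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 0.0705, tolerance = 1e-3)

  expect_warning(r3 <- two_sample_t(c(0, 0), c(0, 0)), "zero variance")
  expect_equal(r3$p, 1)

  # 1000 random Gaussian pairs against stats::t.test, both variants
  set.seed(99)
  for (i in 1:1000) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    mine <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(mine$p - ref$p.value), 1e-10)
    mine_w <- two_sample_t(a, b, equal_variance = FALSE)
    ref_w <- t.test(a, b)
    expect_lt(abs(mine_w$p - ref_w$p.value), 1e-10)
  }
})

test_that("subgroup comparison flags shifted items and respects alpha", {
  tab <- make_item_table(list(dNA.MZ = 0.8, dNA.DZ = -0.2),
                         n_per_group = 30, seed = 13)
  adj <- adjust_item_scores(tab)
  sc <- cumulative_trait_scores(adj)
  cmp <- compare_subgroups(sc, adj, "dNA.MZ", "dNA.DZ")
  items <- cmp[cmp$level == "item", ]
  expect_gt(mean(items$significant), 0.5)   # majority of items
  expect_true(all(cmp$significant[cmp$level == "trait"]))

  # identical subgroups: nothing significant
  tab0 <- make_item_table(list(a = 0.2, b = 0.2), n_per_group = 25, seed = 14)
  adj0 <- adjust_item_scores(tab0)
  sc0 <- cumulative_trait_scores(adj0)
  cmp0 <- compare_subgroups(sc0, adj0, "a", "b")
  expect_lt(mean(cmp0$significant), 0.15)

  # alpha = 0 disables every flag
  cmp_zero <- compare_subgroups(sc, adj, "dNA.MZ", "dNA.DZ", alpha = 0)
  expect_false(any(cmp_zero$significant))

  expect_error(compare_subgroups(sc, adj, "dNA.MZ", "nope"), "nope")
})
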