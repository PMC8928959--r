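test_that("generation is reproducible and matches the requested shape", {
  d1 <- generate_proteins(n_pos = 20, n_neg = 120, length_range = c(50, 100),
                          seed = 5)
  d2 <- generate_proteins(n_pos = 20, n_neg = 120, length_range = c(50, 100),
                          seed = 5)
  expect_identical(d1, d2)
  expect_equal(as.vector(table(d1$label)), c(120L, 20L))
  expect_false(anyDuplicated(d1$id) > 0)

  lens <- nchar(d1$sequence)
  expect_true(all(lens >= 50 & lens <= 100))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", d1$sequence)))

  d3 <- generate_proteins(n_pos = 20, n_neg = 120, length_range = c(50, 100),
                          seed = 6)
  expect_false(identical(d1$sequence, d3$sequence))
})

test_that("effect size zero yields statistically indistinguishable classes", {
  d <- generate_proteins(n_pos = 150, n_neg = 150, length_range = c(80, 120),
                         effect_size = 0, seed = 21)
  x <- cksaap_encode(d, k = 2)
  pos <- x[d$label == 1, ]; neg <- x[d$label == 0, ]
  delta <- colMeans(pos) - colMeans(neg)
  se <- sqrt(apply(pos, 2, var) / nrow(pos) + apply(neg, 2, var) / nrow(neg))
  z <- abs(delta[se > 0] / se[se > 0])
  expect_gte(mean(z <= 4), 0.99)
})

test_that("planted motifs enrich exactly the targeted pair-gap coordinates", {
  motifs <- data.frame(first = "C", second = "C", gap = 2L, weight = 1)
  d <- generate_proteins(n_pos = 80, n_neg = 80, length_range = c(60, 120),
                         motif_pairs = motifs, effect_size = 5, seed = 9)
  x <- cksaap_encode(d, k = 3)
  mean_cc2_pos <- mean(x[d$label == 1, "j2_CC"])
  mean_cc2_neg <- mean(x[d$label == 0, "j2_CC"])
  expect_gt(mean_cc2_pos, mean_cc2_neg)
  expect_gt(mean_cc2_pos, 5 * mean_cc2_neg)  # strong, not marginal

  # direct count oracle on one positive sequence: every planted CC at gap 2
  # is counted by the encoder
  s <- d$sequence[1]
  chars <- strsplit(s, "")[[1]]
  n_cc2 <- sum(chars[seq_len(length(chars) - 3)] == "C" &
               chars[seq_len(length(chars) - 3) + 3] == "C")
  expect_equal(x[1, "j2_CC"] * (nchar(s) - 3), n_cc2, ignore_attr = TRUE)

  # the targeted gap is enriched beyond the marginal C-frequency leakage
  # that planting necessarily induces at neighboring gaps
  expect_gt(mean_cc2_pos, mean(x[d$label == 1, "j1_CC"]))
})

test_that("length range incompatible with motif gaps is rejected", {
  motifs <- data.frame(first = "W", second = "Y", gap = 10L, weight = 1)
  expect_error(generate_proteins(n_pos = 5, n_neg = 5, length_range = c(8, 20),
                                 motif_pairs = motifs), "gap")
  expect_error(generate_proteins(n_pos = 5, n_neg = 5,
                                 background = rep(1, 20)), "sum to 1")
})

test_that("benchmark splits are exact, stratified, and disjoint", {
  d <- generate_proteins(n_pos = 253, n_neg = 1552, length_range = c(50, 80),
                         effect_size = 0, seed = 2)
  sp <- make_benchmark_splits(d, 200, 1240, seed = 3)
  expect_equal(as.vector(table(sp$train$label)), c(1240L, 200L))
  expect_equal(as.vector(table(sp$test$label)), c(312L, 53L))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  expect_setequal(c(sp$train$id, sp$test$id), d$id)

  sp2 <- make_benchmark_splits(d, 200, 1240, seed = 4)
  expect_false(identical(sort(sp$train$id), sort(sp2$train$id)))
  expect_equal(nrow(sp2$train), nrow(sp$train))

  expect_error(make_benchmark_splits(d, 300, 10, seed = 1), "exceed")
})

test_that("held-out accuracy grows monotonically with the planted effect size", {
  # full-pipeline learnability: chance at effect 0, non-decreasing through
  # effect 2 and 5 (3 seeds each, sampling tolerance 0.05)
  mean_bacc <- vapply(c(0, 2, 5), function(es) {
    d <- generate_proteins(n_pos = 60, n_neg = 180, length_range = c(50, 100),
                           effect_size = es, seed = 700 + es)
    sp <- make_benchmark_splits(d, 45, 135, seed = 701)
    xtr <- cksaap_encode(sp$train, k = 1)
    xte <- cksaap_encode(sp$test, k = 1)
    mean(vapply(1:3, function(s) {
      fit <- deeplse(xtr, sp$train$label, N = 5, latent_dim = 4, epochs = 80,
                     patience = 80, batch_size = 16, seed = 710 + s)
      cc <- confusion_counts(sp$test$label, predict(fit, xte, type = "class"))
      classification_metrics(cc)$balanced_accuracy
    }, numeric(1)))
  }, numeric(1))

  expect_lt(abs(mean_bacc[1] - 0.5), 0.1)       # null generator is chance
  expect_gte(mean_bacc[2], mean_bacc[1] - 0.05) # monotone within tolerance
  expect_gte(mean_bacc[3], mean_bacc[2] - 0.05)
  expect_gt(mean_bacc[3], 0.8)                  # strong signal is recovered
})

test_that("fixture writer emits readable FASTA pairs plus a label table", {
  dir <- tempfile()
  paths <- write_synthetic_fixtures(dir, n_pos = 6, n_neg = 10,
                                    length_range = c(50, 60), seed = 8)
  dat <- read_labeled_fasta(paths[["positive"]], paths[["negative"]])
  expect_equal(sum(dat$label == 1), 6L)
  expect_equal(sum(dat$label == 0), 10L)
  labs <- read_label_table(paths[["labels"]])
  relabeled <- label_records(dat, labs)
  expect_equal(relabeled$label, dat$label)
})
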