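# Generator contracts: determinism, retention/tandem statistics,
# truth-table consistency, coalescent and age simulators, coverage/labels.

test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(class_proportions = c(drought_up = 0.5,
                                                       background = 0.6)),
               "sum to 1")
  expect_error(simulation_config(
    class_proportions = c(foo = 0.5, bar = 0.5)), "drought_up")
  expect_error(simulation_config(wgd_ks = 1.2, outgroup_ks = 1.0),
               "smaller than outgroup_ks")
  expect_error(simulation_config(
    retention_prob = c(drought_up = 1.4, background = 0.5)),
    "probabilities")
})

test_that("a fixed seed reproduces the dataset byte for byte", {
  cfg <- simulation_config(seed = 77, n_ancestral_genes = 60)
  s1 <- simulate_wgd_dataset(cfg)
  s2 <- simulate_wgd_dataset(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_wgd_dataset(simulation_config(seed = 78,
                                               n_ancestral_genes = 60))
  expect_false(identical(s1$cds, s3$cds))
})

test_that("retention edge cases map outgroup genes to 2 or 1 focal genes", {
  full <- simulate_wgd_dataset(simulation_config(
    seed = 3, n_ancestral_genes = 80,
    retention_prob = c(drought_up = 1, background = 1), tandem_rate = 0))
  per_anc <- table(full$truth$genes$ancestor)
  expect_true(all(per_anc == 2))
  expect_equal(nrow(full$truth$pairs), 80L)
  none <- simulate_wgd_dataset(simulation_config(
    seed = 3, n_ancestral_genes = 80,
    retention_prob = c(drought_up = 0, background = 0), tandem_rate = 0))
  expect_true(all(table(none$truth$genes$ancestor) == 1))
  expect_equal(nrow(none$truth$pairs), 0L)
})

test_that("realized retention fractions track the class probabilities", {
  cfg <- simulation_config(seed = 13, n_ancestral_genes = 2000,
                           retention_prob = c(drought_up = 0.8,
                                              background = 0.5),
                           tandem_rate = 0)
  sim <- simulate_wgd_dataset(cfg)
  tg <- sim$truth$genes
  anc <- tg[!duplicated(tg$ancestor), ]
  for (cl in c("drought_up", "background")) {
    p <- cfg$retention_prob[[cl]]
    sub <- anc[anc$class == cl, ]
    frac <- mean(sub$retained_duplicate)
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / nrow(sub)))
  }
})

test_that("truth tables are internally consistent", {
  sim <- simulate_wgd_dataset(simulation_config(seed = 21,
                                                n_ancestral_genes = 150))
  tg <- sim$truth$genes
  expect_false(any(duplicated(tg$gene_id)))
  expect_setequal(tg$gene_id, sim$genes_in$gene_id)
  # retained pairs reference two existing genes
  expect_true(all(sim$truth$pairs$gene_a %in% tg$gene_id))
  expect_true(all(sim$truth$pairs$gene_b %in% tg$gene_id))
  # every true homolog pair appears in the hits table
  true_hits <- paste(tg$gene_id,
                     paste0("out_", tg$ancestor))
  expect_true(all(true_hits %in% paste(sim$hits$query, sim$hits$subject)))
  # ranks are contiguous 0-based within each scaffold
  for (sc in unique(sim$genes_in$scaffold)) {
    r <- sort(sim$genes_in$rank[sim$genes_in$scaffold == sc])
    expect_identical(r, seq_along(r) - 1L)
  }
})

test_that("duplicate pairs recover the target Ks in distribution", {
  cfg <- simulation_config(seed = 41, n_ancestral_genes = 250,
                           retention_prob = c(drought_up = 1, background = 1),
                           tandem_rate = 0)
  sim <- simulate_wgd_dataset(cfg)
  ks <- estimate_ka_ks_pairs(sim$cds, sim$truth$pairs)
  m <- ks_distribution_mode(ks$Ks[is.finite(ks$Ks)])$mode
  expect_lt(abs(m - cfg$wgd_ks), 0.05)
  # orthologs are considerably more diverged than duplicates
  anc <- sub("^in[AB]_", "", sim$truth$pairs$gene_a)
  op <- data.frame(gene_a = sim$truth$pairs$gene_a,
                   gene_b = paste0("out_", anc))
  oks <- estimate_ka_ks_pairs(sim$cds, op[1:100, ])
  expect_gt(mean(oks$Ks, na.rm = TRUE), mean(ks$Ks, na.rm = TRUE) + 0.3)
})

test_that("family ages center on the true age and respect sd = 0", {
  set.seed(51)
  expect_equal(simulate_family_ages(66, 10, 0), rep(66, 10))
  ages <- simulate_family_ages(66, 204, 3)
  expect_length(ages, 204L)
  expect_true(all(ages > 0))
  expect_lt(abs(mean(ages) - 66), 3 * 3 / sqrt(204))
  expect_error(simulate_family_ages(66, 1, 3), "n_families")
})

test_that("coalescent sample matches Watterson expectations and determinism", {
  set.seed(61)
  h <- simulate_coalescent_sample(20, 5, 2000)
  expect_true(all(h %in% c(0L, 1L)))
  expect_true(all(colSums(h) > 0 & colSums(h) < 20))
  set.seed(61)
  h2 <- simulate_coalescent_sample(20, 5, 2000)
  expect_identical(h, h2)
  expect_error(simulate_coalescent_sample(1, 5), "at least 2")
  # E[S] = theta * a1 over replicates
  set.seed(62)
  a1 <- sum(1 / 1:19)
  S <- replicate(400, ncol(simulate_coalescent_sample(20, 5, 2000)))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) / a1 - 5), 3 * se / a1)
})

test_that("coverage fractions and DE labels follow the configured rates", {
  cfg <- simulation_config(seed = 71)
  set.seed(71)
  genes <- sprintf("g%04d", 1:3000)
  classes <- rep(c("drought_up", "background"), length.out = 3000)
  cl <- simulate_coverage_and_labels(genes, classes, cfg)
  expect_true(all(cl$coverage >= 0 & cl$coverage <= 1))
  expect_equal(dim(cl$coverage), c(3000L, cfg$coverage_model$n_samples))
  up_rate <- tapply(cl$labels$direction == "up", classes, mean)
  expect_lt(abs(up_rate[["drought_up"]] - 0.3), 0.04)
  expect_lt(abs(up_rate[["background"]] - 0.04), 0.02)
  # degenerate ambiguity at 0 means every gene present everywhere
  cfg0 <- simulation_config(seed = 72,
                            coverage_model = list(mean_depth = 16,
                                                  ambiguity_beta = c(1, 1e6),
                                                  n_samples = 5L))
  set.seed(72)
  cl0 <- simulate_coverage_and_labels(genes[1:50], classes[1:50], cfg0)
  pres <- gene_presence_filter(cl0$coverage)
  expect_setequal(pres$conserved, genes[1:50])
})
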