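# Dating-family assembly windows, ESS estimation, trace summaries,
# consensus age, and the ranked-bootstrap CI.

fam_fixture <- function() {
  dup <- data.frame(gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"),
                    ks = c(0.3, 0.19, 0.45))
  og <- data.frame(focal_gene = c("a1", "b1", "a3"),
                   partner_gene = c("T1", "T2", "T3"),
                   ks = c(0.8, 0.9, 1.5), ka = c(0.2, 0.1, 0.3))
  clades <- list(
    X = data.frame(focal_gene = c("a1", "b1", "a3", "b3"),
                   partner_gene = c("X1", "X2", "X3", "X4"),
                   ks = c(0.1, 0.2, 0.15, 0.12),
                   ka = c(0.05, 0.04, 0.02, 0.03)),
    Y = data.frame(focal_gene = c("a1", "b1", "a3", "b3"),
                   partner_gene = c("Y1", "Y2", "Y3", "Y4"),
                   ks = c(0.25, 0.28, 0.4, 0.1),
                   ka = c(0.06, 0.07, 0.02, 0.01)))
  list(dup = dup, og = og, clades = clades)
}

test_that("family assembly enforces every Ks window and logs drops", {
  f <- fam_fixture()
  fam <- assemble_dating_families(f$dup, f$og, f$clades)
  # a2/b2 fails the duplicate window (0.19 < 0.2); a3/b3 has its outgroup
  # ortholog at Ks 1.5 outside 0.5-1.2 and clade-X Ks 0.4 outside the
  # clade window for a3; only a1/b1 survives
  expect_equal(nrow(fam), 1L)
  expect_identical(fam$gene_a, "a1")
  expect_identical(fam$outgroup_gene, "T2")  # lowest Ka among candidates
  log <- attr(fam, "log")
  expect_true(any(grepl("a2\\|b2.*outside window", log)))
  expect_true(any(grepl("a3\\|b3", log)))
})

test_that("candidate ties break by lowest Ka then gene id", {
  dup <- data.frame(gene_a = "a1", gene_b = "b1", ks = 0.3)
  og <- data.frame(focal_gene = c("a1", "a1", "a1"),
                   partner_gene = c("T3", "T1", "T2"),
                   ks = c(0.8, 0.8, 0.8), ka = c(0.1, 0.1, 0.2))
  fam <- assemble_dating_families(dup, og)
  expect_identical(fam$outgroup_gene, "T1")
})

test_that("alignment-length gate drops short families when lengths given", {
  f <- fam_fixture()
  al <- data.frame(gene_a = "a1", gene_b = "b1", len_aa = 99)
  fam <- assemble_dating_families(f$dup, f$og, f$clades, aln_len = al)
  expect_equal(nrow(fam), 0L)
  al$len_aa <- 100
  fam2 <- assemble_dating_families(f$dup, f$og, f$clades, aln_len = al)
  expect_equal(nrow(fam2), 1L)
})

test_that("ESS matches the iid limit and the AR(1) closed form", {
  set.seed(81)
  iid <- rnorm(9000)
  expect_lt(abs(effective_sample_size(iid)$ess - 9000) / 9000, 0.10)
  rho <- 0.5
  x <- as.numeric(stats::arima.sim(list(ar = rho), 9000))
  ess <- effective_sample_size(x)$ess
  expect_lt(abs(ess - 9000 * (1 - rho) / (1 + rho)) / 3000, 0.15)
  cst <- effective_sample_size(rep(5, 100))
  expect_equal(cst$ess, 0)
  expect_true(cst$constant)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("trace summaries use exactly the post-burn-in samples", {
  tr <- data.frame(node3 = c(rep(1000, 1000), rep(66, 9000)))
  expect_equal(unname(summarize_family_trace(tr, 1000)), 66)
  known <- data.frame(a = c(rep(0, 1000), 1:9000))
  expect_equal(unname(summarize_family_trace(known, 1000)),
               stats::median(1:9000))
  expect_error(summarize_family_trace(data.frame(a = 1:1000), 1000),
               "not more than burn-in")
})

test_that("ESS screening excludes sticky traces without touching the rest", {
  set.seed(82)
  good <- data.frame(age = rnorm(2000, 66, 2))
  sticky <- data.frame(age = as.numeric(
    stats::arima.sim(list(ar = 0.999), 2000) + 66))
  res <- screen_families(list(f1 = good, f2 = sticky), burn_in = 500,
                         ess_min = 200)
  expect_identical(rownames(res$medians), "f1")
  expect_named(res$excluded, "f2")
  expect_equal(res$medians["f1", "age"],
               stats::median(good$age[501:2000]))
})

test_that("consensus age and CI are order invariant and exact on constants", {
  expect_equal(consensus_age(rep(42.5, 50)), 42.5)
  set.seed(83)
  ages <- rnorm(204, 66, 3)
  m1 <- consensus_age(ages)
  m2 <- consensus_age(rev(ages))
  expect_equal(m1, m2)
  expect_lt(abs(m1 - 66), 1.5)
  ci_c <- bootstrap_ci(rep(42.5, 50), B = 100)
  expect_equal(unname(ci_c), c(42.5, 42.5))
})

test_that("bootstrap CI uses the 26th/974th ranked modes and is seeded", {
  set.seed(84)
  ages <- rnorm(204, 66, 3)
  set.seed(85)
  ci <- bootstrap_ci(ages, B = 1000)
  # independent sort-oracle replay of the same resamples
  set.seed(85)
  modes <- sort(replicate(1000, {
    res <- sample(ages, length(ages), replace = TRUE)
    d <- stats::density(res, bw = stats::bw.nrd0(res), n = 512,
                        from = min(res) - 3 * stats::bw.nrd0(res),
                        to = max(res) + 3 * stats::bw.nrd0(res))
    d$x[which.max(d$y)]
  }))
  expect_equal(unname(ci), c(modes[26], modes[974]))
  expect_lte(ci[["lo"]], consensus_age(ages))
  expect_lte(consensus_age(ages), ci[["hi"]])
  # seeded reproducibility
  set.seed(85)
  expect_identical(ci, bootstrap_ci(ages, B = 1000))
})

test_that("CI width shrinks to zero as the family scatter vanishes", {
  set.seed(86)
  widths <- vapply(c(3, 0.5, 0.05), function(s) {
    ages <- simulate_family_ages(66, 204, s)
    ci <- bootstrap_ci(ages, B = 200)
    ci[["hi"]] - ci[["lo"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 0.1)
})

test_that("trace logs round-trip through the reader", {
  tmp <- tempfile(fileext = ".log")
  writeLines(c("# sampler v0", "state\tnode1\tnode3",
               paste(seq(0, 9000, by = 1000),
                     round(rnorm(10, 80, 2), 3),
                     round(rnorm(10, 66, 2), 3), sep = "\t")), tmp)
  tr <- read_mcmc_trace(tmp)
  expect_named(tr, c("node1", "node3"))
  expect_equal(nrow(tr), 10L)
})
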