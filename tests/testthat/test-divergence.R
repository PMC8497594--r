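# NG86 counting, Jukes-Cantor correction, duplication-event clustering,
# Ks KDE mode, and rate-distribution comparisons.

test_that("jc_correct matches the closed form and flags the domain boundary", {
  expect_equal(jc_correct(0)$d, 0)
  expect_equal(jc_correct(0.3)$d, -0.75 * log(0.6), tolerance = 1e-12)
  expect_true(jc_correct(0.75)$saturated)
  expect_true(is.na(jc_correct(0.9)$d))
})

test_that("single-codon pair AAA/AAG reproduces the hand enumeration", {
  est <- estimate_ka_ks(codon_alignment("AAA", "AAG"))
  expect_equal(est$S, 1 / 3)
  expect_equal(est$N, 8 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 3)
  expect_true(est$saturated)
})

test_that("identical sequences give zero distances", {
  cds <- random_sense_cds(30)
  est <- estimate_ka_ks(codon_alignment(cds, cds))
  expect_equal(est$Ks, 0)
  expect_equal(est$Ka, 0)
  expect_equal(est$Sd + est$Nd, 0)
})

test_that("NG86 counts agree with recursive path enumeration on random pairs", {
  tab <- wgdkit:::codon_tables()
  sense <- which(!tab$is_stop)
  set.seed(31)
  # random subset here; the full 61 x 61 sweep runs in the acceptance suite
  for (rep in 1:200) {
    ca <- sample(sense, 1)
    cb <- sample(sense, 1)
    expected <- oracle_path_counts(tab$codons[ca], tab$codons[cb])
    got_sd <- tab$sd[ca, cb]
    if (is.null(expected)) {
      expect_true(is.na(got_sd))
    } else {
      expect_equal(got_sd, expected[1], tolerance = 1e-12)
      expect_equal(tab$nd[ca, cb], expected[2], tolerance = 1e-12)
    }
    expect_equal(tab$syn_sites[ca], oracle_syn_sites(tab$codons[ca]),
                 tolerance = 1e-12)
  }
})

test_that("S + N equals three sites per codon on random alignments", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(20:80, 1)
    a <- random_sense_cds(n)
    b <- evolve_codon_sequence(a, 0.2, 0.3)
    est <- estimate_ka_ks(codon_alignment(a, b))
    expect_equal(est$S + est$N, 3 * est$n_codons, tolerance = 1e-6)
    expect_lte(est$Sd, est$S)
    expect_lte(est$Nd, est$N)
  }
})

test_that("the estimator recovers the evolver's target Ks and omega", {
  set.seed(33)
  cds <- random_sense_cds(10000)
  ev <- evolve_codon_sequence(cds, 0.3, 0.2)
  est <- estimate_ka_ks(codon_alignment(cds, ev))
  expect_lt(abs(est$Ks - 0.3), 0.03)
  expect_lt(abs(est$omega - 0.2), 0.05)
})

test_that("Ks increases with simulation time over replicates", {
  set.seed(34)
  ks_at <- function(t) {
    mean(replicate(5, {
      a <- random_sense_cds(300)
      estimate_ka_ks(codon_alignment(a, evolve_codon_sequence(a, t, 0.2)))$Ks
    }))
  }
  expect_lt(ks_at(0.1), ks_at(0.4))
  expect_lt(ks_at(0.4), ks_at(0.8))
})

test_that("evolver limits: zero time is identity, omega 0 is purifying", {
  cds <- random_sense_cds(50)
  expect_identical(evolve_codon_sequence(cds, 0, 0.2), cds)
  set.seed(35)
  ev <- evolve_codon_sequence(cds, 0.4, 0)
  expect_identical(translate_cds(ev), translate_cds(cds))
  expect_error(evolve_codon_sequence("ATGTAAGTT", 0.1, 0.2), "stop codon")
})

test_that("duplication-event clustering emits family size minus one events", {
  ev <- cluster_duplication_events(
    data.frame(gene_a = "A", gene_b = "B", ks = 0.3))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ks, 0.3)
  # average linkage: A,B at 0.1 then C joins at (0.4 + 0.42) / 2
  ev3 <- cluster_duplication_events(
    data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
               ks = c(0.1, 0.4, 0.42)))
  expect_equal(sort(ev3$ks), c(0.1, 0.41))
  expect_equal(nrow(cluster_duplication_events(
    data.frame(gene_a = character(0), gene_b = character(0),
               ks = numeric(0)))), 0L)
  # two families: events per family = size - 1
  set.seed(36)
  pk <- rbind(
    data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"),
               ks = c(0.1, 0.2, 0.3)),
    data.frame(gene_a = "X", gene_b = "Y", ks = 0.5))
  ev2 <- cluster_duplication_events(pk)
  expect_equal(as.vector(table(ev2$family)), c(2L, 1L))
  # pairs above max_ks do not join families
  evt <- cluster_duplication_events(
    data.frame(gene_a = "A", gene_b = "B", ks = 6), max_ks = 5)
  expect_equal(nrow(evt), 0L)
})

test_that("Ks KDE mode finds the dominant peak", {
  expect_equal(ks_distribution_mode(rep(0.3, 10))$mode, 0.3)
  set.seed(37)
  x <- c(rnorm(3000, 0.1, 0.03), rnorm(800, 0.8, 0.05))
  m <- ks_distribution_mode(pmax(x, 0.001))$mode
  expect_lt(abs(m - 0.1), 0.05)
  expect_error(ks_distribution_mode(0.3), "at least 2")
})

test_that("rate comparison matches the exact U enumeration and detects shifts", {
  r <- compare_rate_distributions(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 6, tolerance = 1e-12)
  same <- compare_rate_distributions(1:20, 1:20, alternative = "less")
  expect_gt(same$p, 0.4)
  set.seed(38)
  lo <- rbeta(300, 2, 8)        # stochastically lower Ka/Ks
  hi <- rbeta(300, 3, 7)
  shift <- compare_rate_distributions(lo, hi, alternative = "less", m = 3)
  expect_lt(shift$p_adjusted, 0.05)
  expect_error(compare_rate_distributions(numeric(0), 1:3), "empty")
})

test_that("bonferroni and BH behave as step rules", {
  expect_equal(bonferroni(0.5, m = 2), 1)
  expect_equal(bonferroni(0.0002, m = 2), 0.0004)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # order invariance of BH (up to reordering)
  p <- c(0.04, 0.001, 0.2, 0.03)
  expect_equal(sort(bh_fdr(p)), sort(bh_fdr(rev(p))))
})
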