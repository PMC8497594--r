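# Synthetic-data generator: genomes carrying one WGD with class-dependent
# duplicate retention, codon sequences diverged at chosen Ka/Ks, tandem
# copies, per-family age estimates, neutral coalescent haplotypes, and
# coverage/expression-label tables, plus truth tables for
# parameter-recovery testing.

#' Simulation configuration
#'
#' Collects the scenario constants of the simulated study system: a diploid
#' outgroup genome and a descendant genome carrying one whole-genome
#' duplication with synonymous divergence `wgd_ks` between retained
#' duplicates and `outgroup_ks` to outgroup orthologs, class-dependent
#' retention (the `drought_up` class retains duplicates more often than
#' `background`), tandem duplicates, differential-expression labels, and a
#' per-family node-age distribution around `wgd_age_ma`. Defaults are the
#' study conditions: duplicate Ks peak at 0.3, ortholog Ks near 1, WGD age
#' 66 Ma with 204 dated families, and retention probabilities placing
#' about 62% of syntenic focal genes in retained duplicate pairs.
#'
#' @param seed integer RNG seed; all outputs are byte-identical given it.
#' @param n_ancestral_genes genes in the pre-WGD ancestor (default 500,
#'   a scaled-down genome that keeps full runs fast).
#' @param n_chromosomes outgroup chromosomes (default 10).
#' @param class_proportions named proportions over gene classes (must
#'   include `drought_up` and `background`; sum to 1).
#' @param retention_prob named per-class probability that a WGD duplicate
#'   pair keeps both copies.
#' @param wgd_ks target synonymous divergence between retained duplicates.
#' @param outgroup_ks target synonymous divergence to outgroup orthologs
#'   (must exceed `wgd_ks`).
#' @param omega named per-class Ka/Ks used in codon evolution.
#' @param tandem_rate probability a focal gene acquires an adjacent tandem
#'   copy.
#' @param tandem_ks synonymous divergence of tandem copies from their
#'   source.
#' @param de_rates list with named vectors `up` and `down`: per-class
#'   probabilities of an up/downregulated label.
#' @param wgd_age_ma true WGD age in Ma.
#' @param family_age_sd dispersion (Ma) of per-family median ages.
#' @param n_families number of dated families.
#' @param coalescent list `(n_haplotypes, theta_per_locus, locus_length)`.
#' @param coverage_model list `(mean_depth, ambiguity_beta, n_samples)`;
#'   `ambiguity_beta` are the Beta shape parameters of the per-gene
#'   per-sample ambiguous fraction.
#' @param decoy_rate decoy (non-homologous) hits as a fraction of true
#'   hits.
#' @param n_codon_range integer(2), CDS length range in codons.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(
    seed = 1L,
    n_ancestral_genes = 500L,
    n_chromosomes = 10L,
    class_proportions = c(drought_up = 0.08, background = 0.92),
    retention_prob = c(drought_up = 0.65, background = 0.43),
    wgd_ks = 0.3,
    outgroup_ks = 1.0,
    omega = c(drought_up = 0.15, background = 0.25),
    tandem_rate = 0.03,
    tandem_ks = 0.05,
    de_rates = list(up = c(drought_up = 0.3, background = 0.04),
                    down = c(drought_up = 0.04, background = 0.04)),
    wgd_age_ma = 66,
    family_age_sd = 3,
    n_families = 204L,
    coalescent = list(n_haplotypes = 20L, theta_per_locus = 5,
                      locus_length = 2000L),
    coverage_model = list(mean_depth = 16, ambiguity_beta = c(0.5, 10.3),
                          n_samples = 19L),
    decoy_rate = 0.01,
    n_codon_range = c(150L, 300L)) {
  cfg <- list(seed = as.integer(seed),
              n_ancestral_genes = as.integer(n_ancestral_genes),
              n_chromosomes = as.integer(n_chromosomes),
              class_proportions = class_proportions,
              retention_prob = retention_prob, wgd_ks = wgd_ks,
              outgroup_ks = outgroup_ks, omega = omega,
              tandem_rate = tandem_rate, tandem_ks = tandem_ks,
              de_rates = de_rates, wgd_age_ma = wgd_age_ma,
              family_age_sd = family_age_sd,
              n_families = as.integer(n_families),
              coalescent = coalescent, coverage_model = coverage_model,
              decoy_rate = decoy_rate, n_codon_range = n_codon_range)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Internal: configuration invariants
#' @noRd
validate_sim_config <- function(cfg) {
  cls <- names(cfg$class_proportions)
  if (!all(c("drought_up", "background") %in% cls))
    stop("class_proportions must include 'drought_up' and 'background'")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  probs <- c(cfg$class_proportions, cfg$retention_prob, cfg$tandem_rate,
             cfg$de_rates$up, cfg$de_rates$down, cfg$omega, cfg$decoy_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!all(cls %in% names(cfg$retention_prob)) ||
      !all(cls %in% names(cfg$omega)))
    stop("retention_prob and omega must cover every class")
  if (cfg$wgd_ks >= cfg$outgroup_ks)
    stop("wgd_ks must be smaller than outgroup_ks")
  if (cfg$n_ancestral_genes < 1L || cfg$n_chromosomes < 1L ||
      cfg$n_families < 2L)
    stop("invalid size parameter")
  invisible(cfg)
}

#' Internal: deterministic child seed for a named component stream
#' @noRd
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Internal: one random sense-codon CDS of n codons
#' @noRd
random_cds <- function(n_codons) {
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  codon_idx_to_cds(sample(sense, n_codons, replace = TRUE))
}

#' Simulate a WGD dataset with truth tables
#'
#' Generates an outgroup genome and a focal (ingroup) genome descended from
#' a common ancestor through one whole-genome duplication. Both subgenomes
#' inherit the ancestral gene order; non-retained duplicates delete their
#' slot and ranks are re-indexed, which produces the clean 2:1 dotplot on
#' recovery. Coding sequences evolve along the species branches so that
#' retained duplicate pairs have expected synonymous divergence
#' `wgd_ks` and ortholog pairs `outgroup_ks`, with per-class Ka/Ks. Tandem
#' copies are inserted adjacent to their source. The hits table contains
#' every true homolog pair plus `decoy_rate` random decoys (lower bitscore,
#' e-value passing the default cutoff, to exercise anchor filtering).
#'
#' @param config a `sim_config` from [simulation_config()].
#' @return list with `genes_out`, `genes_in` (gene tables:
#'   `gene_id`, `genome`, `scaffold`, `rank`, `strand`), `cds` (named
#'   vector over all genes), `proteins`, `hits` (`query`, `subject`,
#'   `bitscore`, `evalue`), and `truth` (list: `genes` with class /
#'   retained / tandem / DE flags, `pairs` with true duplicate-pair
#'   divergence).
#' @export
simulate_wgd_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_ancestral_genes
  classes <- names(config$class_proportions)
  cls <- sample(classes, n, replace = TRUE,
                prob = config$class_proportions)
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), n))
  anc_id <- sprintf("anc%04d", seq_len(n))
  n_cod <- sample(config$n_codon_range[1]:config$n_codon_range[2], n,
                  replace = TRUE)
  anc_cds <- vapply(n_cod, random_cds, character(1))

  retained <- stats::runif(n) < config$retention_prob[cls]
  keep_a <- retained | (stats::runif(n) < 0.5)
  keep_b <- retained | !keep_a

  out_genes <- list()
  in_genes <- list()
  cds <- character(0)
  truth_genes <- list()
  truth_pairs <- list()
  hits <- list()
  pre_branch <- (config$outgroup_ks - config$wgd_ks) / 2
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(chrom == ci)
    out_rank <- 0L
    rank_a <- 0L
    rank_b <- 0L
    for (g in idx) {
      om <- config$omega[[cls[g]]]
      out_id <- sprintf("out_%s", anc_id[g])
      out_cds <- evolve_codon_sequence(anc_cds[g], config$outgroup_ks / 2, om)
      out_genes[[length(out_genes) + 1L]] <- data.frame(
        gene_id = out_id, genome = "outgroup",
        scaffold = sprintf("chr%02d", ci), rank = out_rank,
        strand = sample(c("+", "-"), 1L))
      out_rank <- out_rank + 1L
      cds[out_id] <- out_cds
      pre_cds <- evolve_codon_sequence(anc_cds[g], pre_branch, om)
      copies <- character(0)
      for (sub in c("A", "B")) {
        if ((sub == "A" && !keep_a[g]) || (sub == "B" && !keep_b[g])) next
        in_id <- sprintf("in%s_%s", sub, anc_id[g])
        in_cds <- evolve_codon_sequence(pre_cds, config$wgd_ks / 2, om)
        rk <- if (sub == "A") rank_a else rank_b
        in_genes[[length(in_genes) + 1L]] <- data.frame(
          gene_id = in_id, genome = "ingroup",
          scaffold = sprintf("sc%s%02d", sub, ci), rank = rk,
          strand = sample(c("+", "-"), 1L))
        if (sub == "A") rank_a <- rank_a + 1L else rank_b <- rank_b + 1L
        cds[in_id] <- in_cds
        copies <- c(copies, in_id)
        hits[[length(hits) + 1L]] <- data.frame(
          query = in_id, subject = out_id,
          bitscore = round(stats::runif(1, 400, 600), 1),
          evalue = 10^(-stats::runif(1, 50, 180)))
        is_tandem <- stats::runif(1) < config$tandem_rate
        if (is_tandem) {
          td_id <- paste0(in_id, "t")
          td_cds <- evolve_codon_sequence(in_cds, config$tandem_ks, om)
          rk2 <- if (sub == "A") rank_a else rank_b
          in_genes[[length(in_genes) + 1L]] <- data.frame(
            gene_id = td_id, genome = "ingroup",
            scaffold = sprintf("sc%s%02d", sub, ci), rank = rk2,
            strand = sample(c("+", "-"), 1L))
          if (sub == "A") rank_a <- rank_a + 1L else rank_b <- rank_b + 1L
          cds[td_id] <- td_cds
          hits[[length(hits) + 1L]] <- data.frame(
            query = td_id, subject = out_id,
            bitscore = round(stats::runif(1, 300, 395), 1),
            evalue = 10^(-stats::runif(1, 40, 120)))
          truth_genes[[length(truth_genes) + 1L]] <- data.frame(
            gene_id = td_id, class = cls[g], retained_duplicate = FALSE,
            tandem = TRUE, source_gene = in_id, ancestor = anc_id[g])
        }
        truth_genes[[length(truth_genes) + 1L]] <- data.frame(
          gene_id = in_id, class = cls[g], retained_duplicate = retained[g],
          tandem = is_tandem, source_gene = NA_character_,
          ancestor = anc_id[g])
      }
      if (length(copies) == 2L) {
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          gene_a = copies[1], gene_b = copies[2],
          true_ks = config$wgd_ks, ancestor = anc_id[g])
      }
    }
  }
  genes_out <- do.call(rbind, out_genes)
  genes_in <- do.call(rbind, in_genes)
  hits <- do.call(rbind, hits)
  truth_genes <- do.call(rbind, truth_genes)
  truth_pairs <- if (length(truth_pairs)) do.call(rbind, truth_pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               true_ks = numeric(0), ancestor = character(0))

  # decoy hits: random non-homologous pairs, weaker than any true hit
  n_decoy <- round(config$decoy_rate * nrow(hits))
  if (n_decoy > 0L) {
    decoys <- data.frame(
      query = sample(genes_in$gene_id, n_decoy, replace = TRUE),
      subject = sample(genes_out$gene_id, n_decoy, replace = TRUE),
      bitscore = round(stats::runif(n_decoy, 50, 120), 1),
      evalue = 10^(-stats::runif(n_decoy, 11, 25)))
    same_anc <- sub("^out_", "", decoys$subject) ==
      sub("t$", "", sub("^in[AB]_", "", decoys$query))
    hits <- rbind(hits, decoys[!same_anc, , drop = FALSE])
  }
  rownames(hits) <- NULL

  # DE labels on focal genes
  set.seed(child_seed(config$seed, 2L))
  up_p <- config$de_rates$up[truth_genes$class]
  down_p <- config$de_rates$down[truth_genes$class]
  u <- stats::runif(nrow(truth_genes))
  truth_genes$de_up <- u < up_p
  truth_genes$de_down <- !truth_genes$de_up & (u < up_p + down_p)

  proteins <- vapply(cds, translate_cds, character(1))
  list(genes_out = genes_out, genes_in = genes_in, cds = cds,
       proteins = proteins, hits = hits,
       truth = list(genes = truth_genes, pairs = truth_pairs))
}

#' Simulate per-family node-age estimates
#'
#' Draws `n_families` per-family median ages from a normal distribution
#' centered on the true age (truncated at zero), emulating the scatter of
#' per-family dating estimates around a single WGD age. Uses the current
#' RNG stream.
#'
#' @param true_age true node age in Ma.
#' @param n_families number of families (>= 2).
#' @param sd between-family dispersion in Ma (>= 0).
#' @return numeric vector of `n_families` positive ages.
#' @export
simulate_family_ages <- function(true_age, n_families, sd) {
  stopifnot(n_families >= 2L, sd >= 0, true_age > 0)
  ages <- stats::rnorm(n_families, true_age, sd)
  while (any(ages <= 0))
    ages[ages <= 0] <- stats::rnorm(sum(ages <= 0), true_age, sd)
  ages
}

#' Simulate a neutral coalescent haplotype sample
#'
#' Standard neutral coalescent with infinite sites: exponential waiting
#' times between coalescences, Poisson mutations with rate theta/2 per
#' (coalescent-unit) branch length, each mutation a new biallelic 0/1
#' column assigned a distinct position on the locus. Uses the current RNG
#' stream.
#'
#' @param n number of haplotypes (>= 2).
#' @param theta population-scaled mutation rate per locus (> 0).
#' @param L locus length in sites (positions are drawn from `1:L`).
#' @return object of class `haplotype_matrix`: 0/1 matrix (n x S) with
#'   attributes `positions` and `L`.
#' @export
simulate_coalescent_sample <- function(n, theta, L = 1000L) {
  if (n < 2L) stop("need at least 2 haplotypes")
  stopifnot(theta > 0, L >= 1L)
  lineages <- lapply(seq_len(n), identity)  # tip sets
  branches <- list()  # list of (tips, length)
  k <- n
  active_len <- rep(0, n)
  while (k > 1L) {
    dt <- stats::rexp(1L, rate = k * (k - 1) / 2)
    active_len <- active_len + dt
    pick <- sample.int(k, 2L)
    for (p in sort(pick, decreasing = TRUE)) {
      branches[[length(branches) + 1L]] <- list(tips = lineages[[p]],
                                                len = active_len[p])
    }
    merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
    lineages[[pick[1]]] <- merged
    lineages[[pick[2]]] <- NULL
    active_len[pick[1]] <- 0
    active_len <- active_len[-pick[2]]
    k <- k - 1L
  }
  S_per_branch <- vapply(branches, function(b)
    stats::rpois(1L, theta / 2 * b$len), integer(1))
  S <- sum(S_per_branch)
  mat <- matrix(0L, nrow = n, ncol = S)
  col <- 1L
  for (bi in seq_along(branches)) {
    if (S_per_branch[bi] == 0L) next
    for (j in seq_len(S_per_branch[bi])) {
      mat[branches[[bi]]$tips, col] <- 1L
      col <- col + 1L
    }
  }
  if (S > L) stop("more segregating sites than locus length; increase L")
  pos <- sort(sample.int(L, S))
  # order columns by position for a tidy matrix
  structure(mat, positions = pos, L = L, class = "haplotype_matrix")
}

#' Simulate coverage/ambiguity tables and DE label tables
#'
#' Per-gene, per-sample ambiguous fractions are Beta-distributed
#' (`coverage_model$ambiguity_beta`), emulating missing data and
#' low-coverage regions; DE labels are drawn per gene class with
#' `de_rates`. Uses the current RNG stream.
#'
#' @param genes character vector of gene ids.
#' @param classes character vector of gene classes aligned with `genes`.
#' @param config a `sim_config`.
#' @return list with `coverage` (matrix genes x samples of ambiguous
#'   fractions) and `labels` (data.frame: `gene_id`, `direction`
#'   in up/down/none).
#' @export
simulate_coverage_and_labels <- function(genes, classes, config) {
  ns <- config$coverage_model$n_samples
  ab <- config$coverage_model$ambiguity_beta
  cov <- matrix(stats::rbeta(length(genes) * ns, ab[1], ab[2]),
                nrow = length(genes), ncol = ns,
                dimnames = list(genes, sprintf("sample%02d", seq_len(ns))))
  up_p <- config$de_rates$up[classes]
  down_p <- config$de_rates$down[classes]
  u <- stats::runif(length(genes))
  direction <- ifelse(u < up_p, "up",
                      ifelse(u < up_p + down_p, "down", "none"))
  list(coverage = cov,
       labels = data.frame(gene_id = genes, direction = direction))
}
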