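# File-format readers/writers, analysis configuration, and the end-to-end
# orchestrator reproducing the analysis graph on simulated or user data.

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings returning plain named character
#' vectors; write-read round-trips are identity.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector to write.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read / write a gene-position table
#'
#' TSV columns: `gene_id`, `genome`, `scaffold`, `rank` (0-based gene
#' order per scaffold), `strand`. A GFF3 subset is also accepted
#' (`format = "gff3"`): `gene` features are ranked by start position per
#' scaffold and the `ID` attribute names the gene.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @param genome genome label used when reading GFF3.
#' @return gene table data.frame.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3"),
                            genome = NA_character_) {
  format <- match.arg(format)
  if (format == "tsv") {
    g <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
    need <- c("gene_id", "genome", "scaffold", "rank", "strand")
    if (!all(need %in% names(g)))
      stop("gene table missing columns: ",
           paste(setdiff(need, names(g)), collapse = ","))
    return(g)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) != 9L)
  if (length(bad) > 0L)
    stop("malformed GFF3 record at line ", bad[1])
  f <- do.call(rbind, f)
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", f[, 9])
  g <- data.frame(gene_id = ids, genome = genome, scaffold = f[, 1],
                  start = as.integer(f[, 4]), strand = f[, 7])
  g <- g[order(g$scaffold, g$start), , drop = FALSE]
  g$rank <- stats::ave(g$start, g$scaffold,
                       FUN = function(x) seq_along(x) - 1L)
  g$start <- NULL
  g[, c("gene_id", "genome", "scaffold", "rank", "strand")]
}

#' @rdname read_gene_table
#' @param genes gene table to write.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a homology hits table
#'
#' TSV columns `query`, `subject`, `bitscore`, `evalue`.
#'
#' @param path file path.
#' @return hits data.frame.
#' @export
read_hits <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("query", "subject", "bitscore", "evalue")
  if (!all(need %in% names(h)))
    stop("hits table missing columns: ",
         paste(setdiff(need, names(h)), collapse = ","))
  h
}

#' @rdname read_hits
#' @param hits hits table to write.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an MCMC trace log
#'
#' Tab-separated log with `#` comment lines, a header row of statistic
#' names, and one row per sample (the common Bayesian-phylogenetics log
#' dialect). The first column (sample state) is dropped when named
#' `state` or `Sample`.
#'
#' @param path file path.
#' @return data.frame, one column per statistic.
#' @export
read_mcmc_trace <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (tolower(names(tr)[1]) %in% c("state", "sample"))
    tr <- tr[, -1, drop = FALSE]
  tr
}

#' Read haplotypes from a minimal VCF
#'
#' Biallelic phased SNPs only; each sample contributes two haplotypes
#' (GT `x|y`). Returns a `haplotype_matrix` usable with the diversity
#' estimators; the `L` attribute is set to `locus_length` (defaults to
#' the largest POS).
#'
#' @param path VCF file path (uncompressed).
#' @param locus_length effective locus length for per-site estimates.
#' @return `haplotype_matrix` (haplotypes x sites).
#' @export
read_haplotypes_vcf <- function(path, locus_length = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) == 0L || !startsWith(lines[1], "#CHROM"))
    stop("malformed VCF: missing #CHROM header")
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- header[-(1:9)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(structure(matrix(0L, 2 * length(samples), 0),
                     positions = integer(0),
                     L = if (is.null(locus_length)) 0L else locus_length,
                     class = "haplotype_matrix"))
  f <- strsplit(body, "\t")
  bad <- which(lengths(f) != length(header))
  if (length(bad) > 0L) stop("malformed VCF record at data line ", bad[1])
  f <- do.call(rbind, f)
  pos <- as.integer(f[, 2])
  gts <- f[, -(1:9), drop = FALSE]
  hap <- matrix(NA_integer_, nrow = 2L * length(samples),
                ncol = nrow(f))
  for (s in seq_along(samples)) {
    gt <- sub(":.*", "", gts[, s])
    parts <- strsplit(gt, "|", fixed = TRUE)
    a1 <- vapply(parts, function(x) x[1], character(1))
    a2 <- vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_,
                 character(1))
    hap[2L * s - 1L, ] <- suppressWarnings(as.integer(a1))
    hap[2L * s, ] <- suppressWarnings(as.integer(a2))
  }
  structure(hap, positions = pos,
            L = if (is.null(locus_length)) max(pos) else locus_length,
            class = "haplotype_matrix")
}

#' Write a haplotype matrix as a minimal VCF
#'
#' @param h `haplotype_matrix` with an even number of rows.
#' @param path output path.
#' @param chrom chromosome label.
#' @export
write_haplotypes_vcf <- function(h, path, chrom = "locus1") {
  n <- nrow(h)
  stopifnot(n %% 2L == 0L)
  pos <- attr(h, "positions")
  if (is.null(pos)) pos <- seq_len(ncol(h))
  ns <- n %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                      "\tFORMAT\t",
                      paste(sprintf("s%02d", seq_len(ns)), collapse = "\t"))),
             con)
  for (j in seq_len(ncol(h))) {
    gts <- vapply(seq_len(ns), function(s)
      paste0(h[2L * s - 1L, j], "|", h[2L * s, j]), character(1))
    writeLines(paste(c(chrom, pos[j], ".", "A", "T", ".", "PASS", ".",
                       "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Analysis configuration with the study thresholds
#'
#' Defaults equal the stated thresholds of the analysis: best-hit e-value
#' 1e-10; blocks of >= 5 anchors with gaps <= 25; alignment cleaning flank
#' 3; alignments > 150 aa covering >= half of both proteins; dating
#' windows 0.2-0.6 (duplicates), 0.5-1.2 (outgroup orthologs), 0.05-0.30
#' (clade orthologs) with >= 100 aa; burn-in 1000 samples; ESS >= 200;
#' 1000 bootstrap replicates; presence < 30% ambiguity at 5x depth;
#' FDR 0.05.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param sim a `sim_config` for the simulate stage.
#' @param ... overrides for individual threshold fields.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, sim = simulation_config(seed = seed),
                            ...) {
  cfg <- list(seed = as.integer(seed), sim = sim,
              evalue_cutoff = 1e-10, min_block = 5L, max_gap = 25L,
              clean_flank = 3L, min_aln_aa = 150L, min_cov = 0.5,
              dup_ks_window = c(0.2, 0.6),
              outgroup_ks_window = c(0.5, 1.2),
              clade_ks_window = c(0.05, 0.30), min_dating_aln_aa = 100L,
              burn_in = 1000L, ess_min = 200, bootstrap_B = 1000L,
              max_ambiguous = 0.30, min_depth = 5L, fdr = 0.05,
              max_family_ks = 5.0)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

#' Internal: stable config digest for provenance headers
#' @noRd
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967296)
}

#' Write a TSV with a provenance header
#'
#' Prepends `# config=<hash> seed=<seed>` so every output records its
#' provenance; [read_result_tsv()] skips the header.
#'
#' @param x data.frame.
#' @param path output path.
#' @param cfg the `analysis_config` (for hash and seed).
#' @export
write_result_tsv <- function(x, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(sprintf("# config=%s seed=%d", config_hash(cfg), cfg$seed),
               con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Percentage report over the pipeline's count fields
#'
#' Integer-rounded percentages as reported alongside the raw counts
#' (e.g. retained duplicates over syntenic genes).
#'
#' @param numerator,denominator non-negative counts.
#' @return integer percentage `round(100 * numerator / denominator)`.
#' @export
pct_of <- function(numerator, denominator) {
  stopifnot(denominator > 0)
  as.integer(round(100 * numerator / denominator))
}

#' Run the full analysis graph on simulated data
#'
#' Executes simulate -> anchors -> collinear blocks -> orthology/retention
#' -> tandem calls -> duplicate Ks -> Ks KDE mode -> duplication events ->
#' rate comparison (retained vs non-retained Ka/Ks) -> family-age
#' meta-analysis (consensus age + bootstrap CI) -> retention x response
#' enrichment -> coalescent diversity -> presence/conservation filter.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg an `analysis_config`.
#' @param outdir optional directory; when given, stage outputs are written
#'   as provenance-stamped TSVs.
#' @return a run report: list of per-stage results and counts.
#' @export
run_full_analysis <- function(cfg = analysis_config(), outdir = NULL) {
  sim <- simulate_wgd_dataset(cfg$sim)

  anchors <- find_homolog_anchors(sim$hits, sim$genes_out, sim$genes_in,
                                  evalue_cutoff = cfg$evalue_cutoff)
  blocks <- chain_collinear_blocks(anchors, min_block = cfg$min_block,
                                   max_gap = cfg$max_gap)
  orth <- classify_orthology(blocks, sim$genes_in, anchors = anchors)
  retention <- detect_tandem_duplicates(sim$genes_in, anchors,
                                        orth$retention)

  dup_genes <- orth$retention$gene_id[orth$retention$retained]
  groups2 <- orth$groups[orth$groups$class == "one_to_two", , drop = FALSE]
  dup_pairs <- do.call(rbind, lapply(strsplit(groups2$in_genes, ";"),
                                     function(g) data.frame(gene_a = g[1],
                                                            gene_b = g[2])))
  ks_tab <- if (!is.null(dup_pairs) && nrow(dup_pairs) > 0L)
    estimate_ka_ks_pairs(sim$cds, dup_pairs) else NULL
  ks_ok <- ks_tab$Ks[!ks_tab$saturated & is.finite(ks_tab$Ks)]
  ks_mode <- if (length(ks_ok) >= 2L) ks_distribution_mode(ks_ok)$mode
             else NA_real_
  pw <- data.frame(gene_a = ks_tab$gene_a, gene_b = ks_tab$gene_b,
                   ks = ks_tab$Ks)
  events <- cluster_duplication_events(pw, max_ks = cfg$max_family_ks)

  # ortholog Ka/Ks: retained vs non-retained focal genes vs the outgroup
  ortho_pairs <- data.frame(gene_a = anchors$in_gene,
                            gene_b = anchors$out_gene)
  ortho_pairs <- ortho_pairs[ortho_pairs$gene_a %in%
                               retention$gene_id[retention$retained |
                                                   retention$non_retained], ,
                             drop = FALSE]
  ortho_ks <- estimate_ka_ks_pairs(sim$cds, ortho_pairs)
  is_ret <- stats::setNames(retention$retained, retention$gene_id)
  om_ret <- ortho_ks$omega[is_ret[ortho_ks$gene_a] %in% TRUE &
                             is.finite(ortho_ks$omega)]
  om_non <- ortho_ks$omega[!(is_ret[ortho_ks$gene_a] %in% TRUE) &
                             is.finite(ortho_ks$omega)]
  rate_cmp <- if (length(om_ret) > 0L && length(om_non) > 0L)
    compare_rate_distributions(om_ret, om_non, alternative = "less",
                               m = 3L) else NULL

  set.seed(child_seed(cfg$seed, 3L))
  ages <- simulate_family_ages(cfg$sim$wgd_age_ma, cfg$sim$n_families,
                               cfg$sim$family_age_sd)
  age_mode <- consensus_age(ages)
  age_ci <- bootstrap_ci(ages, B = cfg$bootstrap_B)

  labels <- data.frame(gene_id = sim$truth$genes$gene_id,
                       direction = ifelse(sim$truth$genes$de_up, "up",
                                    ifelse(sim$truth$genes$de_down,
                                           "down", "none")))
  enrich <- retention_enrichment_test(retention, labels)

  set.seed(child_seed(cfg$seed, 4L))
  hap <- simulate_coalescent_sample(cfg$sim$coalescent$n_haplotypes,
                                    cfg$sim$coalescent$theta_per_locus,
                                    cfg$sim$coalescent$locus_length)
  diversity <- diversity_summary(hap)

  set.seed(child_seed(cfg$seed, 5L))
  covlab <- simulate_coverage_and_labels(sim$truth$genes$gene_id,
                                         sim$truth$genes$class, cfg$sim)
  presence <- gene_presence_filter(covlab$coverage,
                                   max_ambiguous = cfg$max_ambiguous,
                                   min_depth = cfg$min_depth)
  conserved_dups <- intersect(presence$conserved, dup_genes)

  n_syntenic <- sum(retention$category == "A")
  report <- list(
    config = cfg,
    config_hash = config_hash(cfg),
    counts = list(
      genes_out = nrow(sim$genes_out), genes_in = nrow(sim$genes_in),
      anchors = nrow(anchors), blocks = length(unique(blocks$block_id)),
      syntenic = n_syntenic, retained = length(dup_genes),
      retained_pct = pct_of(length(dup_genes), n_syntenic),
      conserved_retained = length(conserved_dups),
      conserved_retained_pct = if (length(dup_genes) > 0L)
        pct_of(length(conserved_dups), length(dup_genes)) else NA_integer_,
      tandem = sum(retention$tandem),
      families_dated = length(ages),
      events = nrow(events)),
    ks_mode = ks_mode, ks_table = ks_tab, events = events,
    rate_comparison = rate_cmp,
    consensus_age = age_mode, age_ci = age_ci,
    enrichment = enrich, diversity = diversity,
    retention = retention, blocks = blocks, groups = orth$groups)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(dotplot_table(blocks),
                     file.path(outdir, "dotplot.tsv"), cfg)
    write_result_tsv(ks_tab, file.path(outdir, "ks_pairs.tsv"), cfg)
    write_result_tsv(events, file.path(outdir, "events.tsv"), cfg)
    write_result_tsv(retention, file.path(outdir, "retention.tsv"), cfg)
    write_result_tsv(enrich, file.path(outdir, "enrichment.tsv"), cfg)
    write_result_tsv(diversity, file.path(outdir, "diversity.tsv"), cfg)
    jsonlite::write_json(
      list(config_hash = report$config_hash, seed = cfg$seed,
           counts = report$counts, ks_mode = ks_mode,
           consensus_age = age_mode,
           age_ci = as.list(age_ci)),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
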