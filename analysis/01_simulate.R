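#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system - an outgroup genome and a
# WGD-bearing focal genome with class-dependent duplicate retention,
# tandem copies, homology hits (with decoys), DE labels, and per-gene
# coverage profiles - and write everything as plain-text tables under
# results/simdata/.

library(wgdkit)

outdir <- "results/simdata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 1L)
sim <- simulate_wgd_dataset(cfg)

write_fasta(sim$cds, file.path(outdir, "cds.fasta"))
write_fasta(sim$proteins, file.path(outdir, "proteins.fasta"))
write_gene_table(sim$genes_out, file.path(outdir, "genes_outgroup.tsv"))
write_gene_table(sim$genes_in, file.path(outdir, "genes_focal.tsv"))
write_hits(sim$hits, file.path(outdir, "hits.tsv"))
utils::write.table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

set.seed(2025L)
covlab <- simulate_coverage_and_labels(sim$truth$genes$gene_id,
                                       sim$truth$genes$class, cfg)
utils::write.table(
  data.frame(gene_id = rownames(covlab$coverage), covlab$coverage),
  file.path(outdir, "coverage.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(covlab$labels, file.path(outdir, "de_labels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tg <- sim$truth$genes
cat(sprintf("simulated %d outgroup genes on %d chromosomes\n",
            nrow(sim$genes_out), cfg$n_chromosomes))
cat(sprintf("focal genome: %d genes (%d retained duplicates, %d tandem)\n",
            nrow(sim$genes_in), sum(tg$retained_duplicate), sum(tg$tandem)))
cat(sprintf("true duplicate pairs: %d at target Ks %.2f\n",
            nrow(sim$truth$pairs), cfg$wgd_ks))
cat(sprintf("hits: %d (incl. ~%.0f%% decoys)\n", nrow(sim$hits),
            100 * cfg$decoy_rate))
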