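#!/usr/bin/env Rscript
# Stage 2: anchor filtering (best hit, e-value 1e-10), collinear-block
# chaining, 1:1/1:2 orthology classification, WGD-retention calls, and
# tandem-duplicate detection. Reads stage-1 tables, writes block/orthology
# tables and the dotplot export.

library(wgdkit)

ind <- "results/simdata"
outdir <- "results/synteny"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

genes_out <- read_gene_table(file.path(ind, "genes_outgroup.tsv"))
genes_in <- read_gene_table(file.path(ind, "genes_focal.tsv"))
hits <- read_hits(file.path(ind, "hits.tsv"))

anchors <- find_homolog_anchors(hits, genes_out, genes_in,
                                evalue_cutoff = 1e-10,
                                best_per_query = TRUE)
blocks <- chain_collinear_blocks(anchors, min_block = 5L, max_gap = 25L)
orth <- classify_orthology(blocks, genes_in, anchors = anchors)
retention <- detect_tandem_duplicates(genes_in, anchors, orth$retention)

utils::write.table(dotplot_table(blocks),
                   file.path(outdir, "dotplot.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(orth$groups, file.path(outdir, "orthology_groups.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(retention, file.path(outdir, "retention.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n_syn <- sum(retention$category == "A")
n_ret <- sum(retention$retained)
cat(sprintf("%d anchors -> %d collinear blocks\n", nrow(anchors),
            length(unique(blocks$block_id))))
cat(sprintf("orthology groups: %d (1:2 %d, 1:1 %d; %d outgroup genes in >2 blocks excluded)\n",
            nrow(orth$groups), sum(orth$groups$class == "one_to_two"),
            sum(orth$groups$class == "one_to_one"), length(orth$excluded)))
cat(sprintf("syntenic focal genes (category A): %d, of which %d (%d%%) are WGD-retained duplicates\n",
            n_syn, n_ret, pct_of(n_ret, n_syn)))
cat(sprintf("tandem-flagged genes: %d\n", sum(retention$tandem)))
blocks_per_out <- table(table(blocks$out_gene))
cat("blocks per anchored outgroup gene:",
    paste(names(blocks_per_out), blocks_per_out, sep = "x", collapse = ", "),
    "\n")
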