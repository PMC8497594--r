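#!/usr/bin/env Rscript
# Stage 7: collate the per-stage outputs into one run report with the
# count fields and integer-rounded percentages the analysis prints.

library(wgdkit)

retention <- utils::read.table("results/synteny/retention.tsv",
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
conserved <- utils::read.table("results/popgen/conserved_genes.tsv",
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
consensus <- jsonlite::read_json("results/dating/consensus_age.json")
ksdup <- read_result_tsv("results/kaks/ks_duplicates.tsv")

n_focal <- nrow(retention)
n_syn <- sum(retention$category == "A")
n_ret <- sum(retention$retained)
n_cons_ret <- length(intersect(conserved$gene_id,
                               retention$gene_id[retention$retained]))
n_cons_all <- length(intersect(conserved$gene_id, retention$gene_id))

report <- list(
  focal_genes = n_focal,
  syntenic_genes = n_syn,
  retained_duplicates = n_ret,
  retained_pct = pct_of(n_ret, n_syn),
  conserved_retained = n_cons_ret,
  conserved_retained_pct = pct_of(n_cons_ret, n_ret),
  conserved_all = n_cons_all,
  conserved_all_pct = pct_of(n_cons_all, n_focal),
  tandem_genes = sum(retention$tandem),
  duplicate_pairs = nrow(ksdup),
  consensus_age_ma = consensus$consensus_age_ma,
  consensus_ci95 = c(consensus$ci95_lo, consensus$ci95_hi))

jsonlite::write_json(report, "results/run_report.json",
                     auto_unbox = TRUE, digits = NA)

cat("run report (results/run_report.json):\n")
cat(sprintf("  syntenic %d of %d focal genes; retained duplicates %d (%d%%)\n",
            n_syn, n_focal, n_ret, report$retained_pct))
cat(sprintf("  conserved retained duplicates %d (%d%%); conserved overall %d (%d%%)\n",
            n_cons_ret, report$conserved_retained_pct, n_cons_all,
            report$conserved_all_pct))
cat(sprintf("  consensus WGD age %.1f Ma (95%% CI %.1f-%.1f)\n",
            report$consensus_age_ma, consensus$ci95_lo, consensus$ci95_hi))
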