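# Anchor filtering, collinear-block chaining, orthology classification,
# tandem detection, and the dotplot export.

toy_genes <- function(ids, scaffold, genome = "g") {
  data.frame(gene_id = ids, genome = genome, scaffold = scaffold,
             rank = seq_along(ids) - 1L, strand = "+")
}

test_that("anchor filtering applies the e-value cutoff and best-per-query", {
  gout <- toy_genes(paste0("o", 1:5), "c1")
  gin <- toy_genes(paste0("i", 1:5), "s1")
  hits <- data.frame(query = c("i1", "i1", "i2", "i3"),
                     subject = c("o1", "o2", "o2", "o3"),
                     bitscore = c(500, 300, 400, 200),
                     evalue = c(1e-20, 1e-12, 1e-30, 1e-9))
  a <- find_homolog_anchors(hits, gout, gin)
  expect_identical(a$in_gene, c("i1", "i2"))   # i3 fails the 1e-10 cutoff
  expect_identical(a$out_gene, c("o1", "o2"))  # i1 keeps only its best hit
  expect_equal(nrow(find_homolog_anchors(hits[0, ], gout, gin)), 0L)
  bad <- data.frame(query = "zz", subject = "o1", bitscore = 1, evalue = 0)
  expect_error(find_homolog_anchors(bad, gout, gin), "unknown gene")
})

test_that("perfectly collinear anchors form one block; short runs are dropped", {
  anc <- data.frame(out_gene = paste0("o", 1:6), out_scaffold = "c1",
                    out_rank = 0:5, in_gene = paste0("i", 1:6),
                    in_scaffold = "s1", in_rank = 0:5, score = 100)
  b <- chain_collinear_blocks(anc)
  expect_equal(length(unique(b$block_id)), 1L)
  expect_equal(nrow(b), 6L)
  expect_identical(unique(b$orientation), "same")
  expect_equal(nrow(chain_collinear_blocks(anc[1:4, ])), 0L)
  # inverted diagonal is chained with decreasing focal ranks
  anc_inv <- anc
  anc_inv$in_rank <- 5:0
  binv <- chain_collinear_blocks(anc_inv)
  expect_identical(unique(binv$orientation), "inverted")
  expect_equal(nrow(binv), 6L)
})

test_that("chaining equals the exhaustive oracle on random small instances", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    anc <- data.frame(out_gene = paste0("o", 1:n), out_scaffold = "c1",
                      out_rank = sample(0:(3 * n), n),
                      in_gene = paste0("i", 1:n), in_scaffold = "s1",
                      in_rank = sample(0:(3 * n), n), score = 100)
    b <- chain_collinear_blocks(anc, min_block = 1L, max_gap = 5L)
    got <- if (nrow(b) == 0L) -Inf else {
      first <- b[b$block_id == 1L, , drop = FALSE]
      gaps <- sum(diff(sort(first$out_rank)) - 1L) +
        sum(abs(diff(first$in_rank[order(first$out_rank)])) - 1L)
      nrow(first) - 0.05 * gaps
    }
    expect_equal(got,
                 oracle_best_chain_score(anc$out_rank, anc$in_rank,
                                         max_gap = 5L),
                 tolerance = 1e-9, info = paste("instance", rep))
  }
})

test_that("blocks never share anchors and ranks are strictly monotone", {
  set.seed(42)
  sim <- simulate_wgd_dataset(simulation_config(seed = 5,
                                                n_ancestral_genes = 120))
  anchors <- find_homolog_anchors(sim$hits, sim$genes_out, sim$genes_in)
  blocks <- chain_collinear_blocks(anchors)
  key <- paste(blocks$out_gene, blocks$in_gene)
  expect_false(any(duplicated(key)))
  for (bid in unique(blocks$block_id)) {
    blk <- blocks[blocks$block_id == bid, , drop = FALSE]
    expect_true(all(diff(blk$out_rank) > 0))
    d_in <- diff(blk$in_rank)
    if (blk$orientation[1] == "same") expect_true(all(d_in > 0))
    else expect_true(all(d_in < 0))
  }
})

test_that("full retention yields the 2:1 dotplot property and 1:2 calls", {
  cfg <- simulation_config(seed = 9, n_ancestral_genes = 150,
                           retention_prob = c(drought_up = 1, background = 1),
                           tandem_rate = 0, decoy_rate = 0)
  sim <- simulate_wgd_dataset(cfg)
  anchors <- find_homolog_anchors(sim$hits, sim$genes_out, sim$genes_in,
                                  best_per_query = FALSE)
  blocks <- chain_collinear_blocks(anchors)
  per_out <- table(blocks$out_gene)
  expect_true(all(per_out == 2))
  orth <- classify_orthology(blocks, sim$genes_in, anchors = anchors)
  expect_true(all(orth$groups$class == "one_to_two"))
  expect_true(all(orth$retention$retained))
  dp <- dotplot_table(blocks)
  # every outgroup scaffold is covered by exactly two block colors
  for (sc in unique(dp$out_scaffold))
    expect_equal(length(unique(dp$block_id[dp$out_scaffold == sc])), 2L)
})

test_that("zero retention yields only 1:1 groups", {
  cfg <- simulation_config(seed = 10, n_ancestral_genes = 150,
                           retention_prob = c(drought_up = 0, background = 0),
                           tandem_rate = 0, decoy_rate = 0)
  sim <- simulate_wgd_dataset(cfg)
  anchors <- find_homolog_anchors(sim$hits, sim$genes_out, sim$genes_in)
  blocks <- chain_collinear_blocks(anchors)
  orth <- classify_orthology(blocks, sim$genes_in, anchors = anchors)
  expect_true(all(orth$groups$class == "one_to_one"))
  expect_false(any(orth$retention$retained))
})

test_that("retention recovery tracks the configured probability", {
  cfg <- simulation_config(seed = 11, n_ancestral_genes = 600,
                           retention_prob = c(drought_up = 0.6,
                                              background = 0.6),
                           tandem_rate = 0, decoy_rate = 0)
  sim <- simulate_wgd_dataset(cfg)
  anchors <- find_homolog_anchors(sim$hits, sim$genes_out, sim$genes_in)
  blocks <- chain_collinear_blocks(anchors)
  orth <- classify_orthology(blocks, sim$genes_in, anchors = anchors)
  frac <- mean(orth$groups$class == "one_to_two")
  se <- sqrt(0.6 * 0.4 / nrow(orth$groups))
  expect_lt(abs(frac - 0.6), 3 * se + 0.02)
})

test_that("tandem runs sharing a best hit are flagged when syntenic", {
  gin <- data.frame(gene_id = c("i1", "i2", "i3", "i4"), genome = "in",
                    scaffold = "s1", rank = 0:3, strand = "+")
  best <- data.frame(out_gene = c("X", "X", "Y", "Z"),
                     out_scaffold = "c1", out_rank = c(0, 0, 1, 2),
                     in_gene = c("i1", "i2", "i3", "i4"),
                     in_scaffold = "s1", in_rank = 0:3, score = 100)
  retention <- data.frame(gene_id = gin$gene_id,
                          retained = c(FALSE, FALSE, FALSE, FALSE),
                          non_retained = c(TRUE, FALSE, TRUE, TRUE),
                          tandem = NA, category = "A")
  out <- detect_tandem_duplicates(gin, best, retention)
  expect_identical(out$tandem, c(TRUE, TRUE, FALSE, FALSE))
  # without a syntenic member the run is not flagged
  retention$non_retained <- c(FALSE, FALSE, TRUE, TRUE)
  out2 <- detect_tandem_duplicates(gin, best, retention)
  expect_false(any(out2$tandem[1:2]))
})

test_that("dotplot table round-trips through the TSV writer", {
  empty <- dotplot_table(chain_collinear_blocks(
    find_homolog_anchors(data.frame(query = character(0),
                                    subject = character(0),
                                    bitscore = numeric(0),
                                    evalue = numeric(0)),
                         toy_genes("o1", "c1"), toy_genes("i1", "s1"))))
  expect_equal(nrow(empty), 0L)
  tmp <- tempfile(fileext = ".tsv")
  anc <- data.frame(out_gene = paste0("o", 1:6), out_scaffold = "c1",
                    out_rank = 0:5, in_gene = paste0("i", 1:6),
                    in_scaffold = "s1", in_rank = 0:5, score = 100)
  dp <- dotplot_table(chain_collinear_blocks(anc))
  write_result_tsv(dp, tmp)
  back <- read_result_tsv(tmp)
  expect_equal(back, dp, ignore_attr = TRUE)
})
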