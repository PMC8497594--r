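# Collinear-block detection between an outgroup and the focal genome,
# 1:1 / 1:2 orthology classification, WGD-retention calls, and
# tandem-duplicate detection.

#' Filter homology hits into candidate anchors
#'
#' Keeps hits at or below the e-value cutoff and (optionally) only the
#' best hit per query (highest bitscore; ties by lower e-value, then by
#' subject id). Each retained hit is annotated with scaffold and rank on
#' both genomes, giving the anchor set chained into collinear blocks.
#'
#' @param hits data.frame with columns `query` (focal-genome gene),
#'   `subject` (outgroup gene), `bitscore`, `evalue`.
#' @param genes_out,genes_in gene tables (data.frames with `gene_id`,
#'   `scaffold`, `rank`, `strand`) for the outgroup and focal genome.
#' @param evalue_cutoff maximum e-value (default 1e-10, inclusive).
#' @param best_per_query keep only the best hit per query (default TRUE).
#' @return data.frame of anchors: `out_gene`, `out_scaffold`, `out_rank`,
#'   `in_gene`, `in_scaffold`, `in_rank`, `score`, ordered by outgroup
#'   scaffold and rank.
#' @export
find_homolog_anchors <- function(hits, genes_out, genes_in,
                                 evalue_cutoff = 1e-10,
                                 best_per_query = TRUE) {
  if (nrow(hits) == 0L)
    return(data.frame(out_gene = character(0), out_scaffold = character(0),
                      out_rank = integer(0), in_gene = character(0),
                      in_scaffold = character(0), in_rank = integer(0),
                      score = numeric(0)))
  unknown_q <- setdiff(hits$query, genes_in$gene_id)
  unknown_s <- setdiff(hits$subject, genes_out$gene_id)
  if (length(unknown_q) > 0L || length(unknown_s) > 0L)
    stop("hits reference unknown gene ids: ",
         paste(utils::head(c(unknown_q, unknown_s), 5), collapse = ","))
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (best_per_query && nrow(h) > 0L) {
    o <- order(h$query, -h$bitscore, h$evalue, h$subject)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$query), , drop = FALSE]
  }
  io <- match(h$subject, genes_out$gene_id)
  ii <- match(h$query, genes_in$gene_id)
  a <- data.frame(out_gene = h$subject,
                  out_scaffold = genes_out$scaffold[io],
                  out_rank = genes_out$rank[io],
                  in_gene = h$query,
                  in_scaffold = genes_in$scaffold[ii],
                  in_rank = genes_in$rank[ii],
                  score = h$bitscore)
  a[order(a$out_scaffold, a$out_rank, a$in_scaffold, a$in_rank), ,
    drop = FALSE]
}

#' Internal: best chain by DP on one scaffold pair and orientation
#'
#' Anchors must be rows of the anchor frame restricted to one scaffold
#' pair. Returns list(score, idx) where idx are row indices of the chain,
#' or NULL if no chain exists. Chain score = anchors - gap_penalty * total
#' rank gap; ranks strictly monotone, per-step rank gaps <= max_gap on
#' both genomes. Tie-break: earlier outgroup rank.
#' @noRd
.best_chain <- function(anc, orientation, max_gap, gap_penalty) {
  n <- nrow(anc)
  if (n == 0L) return(NULL)
  o <- order(anc$out_rank, if (orientation == "same") anc$in_rank
             else -anc$in_rank)
  a <- anc[o, , drop = FALSE]
  dp <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      go <- a$out_rank[i] - a$out_rank[j] - 1L
      if (go < 0L || go > max_gap) next
      gi <- if (orientation == "same") a$in_rank[i] - a$in_rank[j] - 1L
            else a$in_rank[j] - a$in_rank[i] - 1L
      if (gi < 0L || gi > max_gap) next
      cand <- dp[j] + 1 - gap_penalty * (go + gi)
      if (cand > dp[i] + 1e-12 ||
          (abs(cand - dp[i]) <= 1e-12 && !is.na(prev[i]) &&
           a$out_rank[j] < a$out_rank[prev[i]])) {
        dp[i] <- cand
        prev[i] <- j
      }
    }
  }
  best_i <- which(dp == max(dp))
  best_i <- best_i[which.min(a$out_rank[best_i])]
  idx <- integer(0)
  i <- best_i
  while (!is.na(i)) {
    idx <- c(i, idx)
    i <- prev[i]
  }
  list(score = dp[best_i], idx = o[idx])
}

#' Chain anchors into collinear blocks
#'
#' Within each (outgroup scaffold, focal scaffold) pair and orientation,
#' maximal-scoring chains are found by dynamic programming over
#' rank-sorted anchors (score = anchors - `gap_penalty` x total rank gap;
#' ranks strictly monotone on both genomes, increasing on the focal genome
#' for `same` orientation and decreasing for `inverted`; per-step rank
#' gaps at most `max_gap`). Chains are extracted greedily by score, each
#' anchor joins at most one block, and blocks with fewer than `min_block`
#' anchors are discarded.
#'
#' @param anchors anchor frame from [find_homolog_anchors()].
#' @param min_block minimum anchors per block (default 5).
#' @param max_gap maximum intervening gene ranks between consecutive
#'   anchors (default 25).
#' @param gap_penalty score deduction per unit rank gap (default 0.05).
#' @return data.frame of anchors in blocks, with `block_id`,
#'   `orientation`, and the anchor columns; one row per anchor.
#' @export
chain_collinear_blocks <- function(anchors, min_block = 5L, max_gap = 25L,
                                   gap_penalty = 0.05) {
  cols <- c("block_id", "orientation", names(anchors))
  empty <- stats::setNames(
    data.frame(integer(0), character(0), anchors[0, , drop = FALSE]),
    cols)
  if (nrow(anchors) == 0L) return(empty)
  anchors$.row <- seq_len(nrow(anchors))
  out <- list()
  block_id <- 0L
  sp <- split(anchors, list(anchors$out_scaffold, anchors$in_scaffold),
              drop = TRUE)
  for (key in sort(names(sp))) {
    rem <- sp[[key]]
    repeat {
      ch_s <- .best_chain(rem, "same", max_gap, gap_penalty)
      ch_i <- .best_chain(rem, "inverted", max_gap, gap_penalty)
      sc_s <- if (is.null(ch_s)) -Inf else ch_s$score
      sc_i <- if (is.null(ch_i)) -Inf else ch_i$score
      if (max(sc_s, sc_i) == -Inf) break
      if (sc_s >= sc_i) {
        ch <- ch_s
        ori <- "same"
      } else {
        ch <- ch_i
        ori <- "inverted"
      }
      if (length(ch$idx) < min_block) break
      block_id <- block_id + 1L
      blk <- rem[ch$idx, , drop = FALSE]
      blk$block_id <- block_id
      blk$orientation <- ori
      out[[length(out) + 1L]] <- blk
      rem <- rem[-ch$idx, , drop = FALSE]
      if (nrow(rem) == 0L) break
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$block_id, res$out_rank), , drop = FALSE]
  res$.row <- NULL
  rownames(res) <- NULL
  res[, cols]
}

#' Classify 1:1 / 1:2 orthology and call WGD retention
#'
#' An outgroup gene anchored in exactly one collinear block yields a
#' one-to-one group (its focal partner is a non-retained gene); anchored in
#' exactly two blocks with two distinct focal partners it yields a
#' one-to-two group (both partners are WGD-retained duplicates); anchored
#' in three or more blocks it is excluded and logged. Focal genes are
#' categorized A (syntenic: in a block), B (homologous only: hit but not in
#' a block), or C (no homology).
#'
#' @param blocks block frame from [chain_collinear_blocks()].
#' @param genes_in focal-genome gene table.
#' @param anchors optional full anchor frame (pre-chaining) used to
#'   distinguish category B from C; if NULL, non-syntenic genes with any
#'   hit cannot be identified and all non-syntenic genes fall in C.
#' @return list with `groups` (data.frame: `out_gene`, `in_genes`
#'   (`;`-separated), `class`), `retention` (data.frame per focal gene:
#'   `gene_id`, `retained`, `non_retained`, `tandem` (NA, filled by
#'   [detect_tandem_duplicates()]), `category`), and `excluded`
#'   (outgroup genes in >= 3 blocks).
#' @export
classify_orthology <- function(blocks, genes_in, anchors = NULL) {
  groups <- list()
  excluded <- character(0)
  retained <- character(0)
  non_retained <- character(0)
  if (nrow(blocks) > 0L) {
    per_out <- split(blocks, blocks$out_gene)
    for (og in names(per_out)) {
      bl <- per_out[[og]]
      nb <- length(unique(bl$block_id))
      partners <- unique(bl$in_gene)
      if (nb == 1L && length(partners) == 1L) {
        groups[[length(groups) + 1L]] <- data.frame(
          out_gene = og, in_genes = partners, class = "one_to_one")
        non_retained <- c(non_retained, partners)
      } else if (nb == 2L && length(partners) == 2L) {
        groups[[length(groups) + 1L]] <- data.frame(
          out_gene = og, in_genes = paste(sort(partners), collapse = ";"),
          class = "one_to_two")
        retained <- c(retained, partners)
      } else {
        excluded <- c(excluded, og)
      }
    }
  }
  groups <- if (length(groups)) do.call(rbind, groups) else
    data.frame(out_gene = character(0), in_genes = character(0),
               class = character(0))
  syntenic <- unique(blocks$in_gene)
  with_hit <- if (is.null(anchors)) character(0) else unique(anchors$in_gene)
  category <- ifelse(genes_in$gene_id %in% syntenic, "A",
                     ifelse(genes_in$gene_id %in% with_hit, "B", "C"))
  retention <- data.frame(
    gene_id = genes_in$gene_id,
    retained = genes_in$gene_id %in% retained,
    non_retained = genes_in$gene_id %in% non_retained,
    tandem = NA,
    category = category)
  list(groups = groups, retention = retention, excluded = excluded)
}

#' Detect tandemly duplicated genes
#'
#' Runs of adjacent-rank genes on the same focal scaffold whose best hits
#' point to the same outgroup gene, where at least one run member is
#' syntenic (WGD-retained or non-retained), are flagged tandem.
#'
#' @param genes_in focal-genome gene table.
#' @param best_hits anchor frame from [find_homolog_anchors()] with
#'   `best_per_query = TRUE` (per-gene best outgroup hit).
#' @param retention retention table from [classify_orthology()].
#' @return the retention table with the `tandem` column filled
#'   (logical).
#' @export
detect_tandem_duplicates <- function(genes_in, best_hits, retention) {
  best_of <- stats::setNames(best_hits$out_gene, best_hits$in_gene)
  syntenic_ok <- stats::setNames(retention$retained | retention$non_retained,
                                 retention$gene_id)
  tandem <- character(0)
  for (sc in unique(genes_in$scaffold)) {
    g <- genes_in[genes_in$scaffold == sc, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    hit <- unname(best_of[g$gene_id])
    n <- nrow(g)
    if (n < 2L) next
    run_start <- 1L
    flush_run <- function(s, e) {
      if (e > s) {
        ids <- g$gene_id[s:e]
        if (any(syntenic_ok[ids], na.rm = TRUE)) tandem <<- c(tandem, ids)
      }
    }
    for (i in 2L:n) {
      same <- !is.na(hit[i]) && !is.na(hit[i - 1L]) &&
        hit[i] == hit[i - 1L] && g$rank[i] == g$rank[i - 1L] + 1L
      if (!same) {
        flush_run(run_start, i - 1L)
        run_start <- i
      }
    }
    flush_run(run_start, n)
  }
  retention$tandem <- retention$gene_id %in% tandem
  retention
}

#' Export a dotplot table of block anchors
#'
#' One row per anchor with its block id and orientation, suitable for
#' plotting collinearity dotplots.
#'
#' @param blocks block frame from [chain_collinear_blocks()].
#' @return data.frame with `out_scaffold`, `out_rank`, `in_scaffold`,
#'   `in_rank`, `block_id`, `orientation`.
#' @export
dotplot_table <- function(blocks) {
  cols <- c("out_scaffold", "out_rank", "in_scaffold", "in_rank",
            "block_id", "orientation")
  if (nrow(blocks) == 0L)
    return(stats::setNames(data.frame(character(0), integer(0),
                                      character(0), integer(0),
                                      integer(0), character(0)), cols))
  blocks[, cols]
}
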