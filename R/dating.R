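# Assembly of dating gene families by Ks-window rules and the consensus-age
# meta-analysis over per-family MCMC node-age traces: burn-in, ESS
# screening, per-family medians, KDE mode, ranked-bootstrap 95% CI.
# MCMC sampling itself is out of scope; traces are inputs.

#' Assemble dating families from Ks/Ka tables
#'
#' Starting from focal-genome WGD duplicate pairs with Ks inside
#' `dup_ks_window`, an outgroup ortholog is added if its Ks to a focal gene
#' lies in `outgroup_ks_window`, and one ortholog per clade table (for each
#' focal duplicate) if its Ks lies in `clade_ks_window`. Among multiple
#' candidates the gene with the lowest amino-acid divergence (Ka) is
#' chosen, ties broken by lexicographic gene id. Families missing any
#' required member are dropped and logged. An optional cleaned-alignment
#' length gate (`min_aln_len`, in aa) is applied when `aln_len` is given.
#'
#' @param dup_pairs data.frame `gene_a`, `gene_b`, `ks` of focal duplicate
#'   pairs.
#' @param outgroup_orthologs data.frame `focal_gene`, `partner_gene`,
#'   `ks`, `ka`.
#' @param clade_orthologs named list of data.frames (one per clade, same
#'   columns as `outgroup_orthologs`).
#' @param dup_ks_window,outgroup_ks_window,clade_ks_window numeric(2)
#'   inclusive Ks windows (defaults 0.2-0.6, 0.5-1.2, 0.05-0.30).
#' @param aln_len optional data.frame `gene_a`, `gene_b`, `len_aa` of
#'   cleaned alignment lengths per duplicate pair.
#' @param min_aln_len minimum cleaned alignment length in aa (default
#'   100), applied only when `aln_len` is supplied.
#' @return data.frame with one row per family: the duplicate pair, the
#'   chosen outgroup gene, and one chosen gene per clade and focal
#'   duplicate; attribute `log` records drop reasons.
#' @export
assemble_dating_families <- function(dup_pairs, outgroup_orthologs,
                                     clade_orthologs = list(),
                                     dup_ks_window = c(0.2, 0.6),
                                     outgroup_ks_window = c(0.5, 1.2),
                                     clade_ks_window = c(0.05, 0.30),
                                     aln_len = NULL, min_aln_len = 100) {
  pick_best <- function(cand) {
    cand <- cand[order(cand$ka, cand$partner_gene), , drop = FALSE]
    cand$partner_gene[1]
  }
  in_window <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  log <- character(0)
  rows <- list()
  for (i in seq_len(nrow(dup_pairs))) {
    ga <- dup_pairs$gene_a[i]
    gb <- dup_pairs$gene_b[i]
    pair_id <- paste(ga, gb, sep = "|")
    if (!in_window(dup_pairs$ks[i], dup_ks_window)) {
      log <- c(log, sprintf("%s: duplicate Ks %.3f outside window", pair_id,
                            dup_pairs$ks[i]))
      next
    }
    if (!is.null(aln_len)) {
      m <- aln_len$len_aa[(aln_len$gene_a == ga & aln_len$gene_b == gb) |
                          (aln_len$gene_a == gb & aln_len$gene_b == ga)]
      if (length(m) == 0L || m[1] < min_aln_len) {
        log <- c(log, sprintf("%s: cleaned alignment below %d aa", pair_id,
                              min_aln_len))
        next
      }
    }
    og <- outgroup_orthologs[outgroup_orthologs$focal_gene %in% c(ga, gb) &
            in_window(outgroup_orthologs$ks, outgroup_ks_window), ,
            drop = FALSE]
    if (nrow(og) == 0L) {
      log <- c(log, sprintf("%s: no outgroup ortholog in Ks window",
                            pair_id))
      next
    }
    out_gene <- pick_best(og)
    clade_cols <- list()
    ok <- TRUE
    for (cl in names(clade_orthologs)) {
      tab <- clade_orthologs[[cl]]
      for (fg in c(ga, gb)) {
        cand <- tab[tab$focal_gene == fg &
                      in_window(tab$ks, clade_ks_window), , drop = FALSE]
        if (nrow(cand) == 0L) {
          log <- c(log, sprintf("%s: no %s ortholog for %s in Ks window",
                                pair_id, cl, fg))
          ok <- FALSE
          break
        }
        clade_cols[[paste0(cl, "_", if (fg == ga) "a" else "b")]] <-
          pick_best(cand)
      }
      if (!ok) break
    }
    if (!ok) next
    rows[[length(rows) + 1L]] <- c(list(gene_a = ga, gene_b = gb,
                                        dup_ks = dup_pairs$ks[i],
                                        outgroup_gene = out_gene),
                                   clade_cols)
  }
  fam <- if (length(rows)) do.call(rbind, lapply(rows, as.data.frame)) else
    data.frame(gene_a = character(0), gene_b = character(0),
               dup_ks = numeric(0), outgroup_gene = character(0))
  attr(fam, "log") <- log
  fam
}

#' Effective sample size of an MCMC trace
#'
#' ESS = N / ACT where the autocorrelation time ACT = 1 + 2 * sum of the
#' sample autocorrelations up to (excluding) the first negative lag
#' (initial positive sequence convention). Capped at N. A constant trace
#' returns ESS 0 with `constant = TRUE`.
#'
#' @param x numeric vector of post-burn-in samples (>= 10).
#' @return list with `ess` and `constant`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 post-burn-in samples")
  if (stats::var(x) == 0) return(list(ess = 0, constant = TRUE))
  rho <- stats::acf(x, lag.max = n - 1L, plot = FALSE,
                    demean = TRUE)$acf[-1]
  first_neg <- which(rho < 0)[1]
  keep <- if (is.na(first_neg)) rho else rho[seq_len(first_neg - 1L)]
  act <- 1 + 2 * sum(keep)
  list(ess = min(n, n / max(act, 1e-12)), constant = FALSE)
}

#' Per-node median ages of one family trace
#'
#' Discards the first `burn_in` samples and returns the column medians.
#'
#' @param trace data.frame or matrix, one column per node statistic, one
#'   row per MCMC sample.
#' @param burn_in number of initial samples to discard (default 1000).
#' @return named numeric vector of post-burn-in medians.
#' @export
summarize_family_trace <- function(trace, burn_in = 1000L) {
  trace <- as.matrix(trace)
  if (nrow(trace) <= burn_in)
    stop("trace has ", nrow(trace), " samples, not more than burn-in ",
         burn_in)
  apply(trace[(burn_in + 1L):nrow(trace), , drop = FALSE], 2L,
        stats::median)
}

#' Screen family traces by ESS and summarize retained ones
#'
#' A family is retained iff every statistic of its post-burn-in trace has
#' ESS >= `ess_min`; retained families contribute their per-node medians.
#'
#' @param traces named list of per-family traces (data.frame/matrix).
#' @param burn_in samples to discard per trace (default 1000).
#' @param ess_min minimum ESS for every statistic (default 200).
#' @return list with `medians` (data.frame: family x node medians) and
#'   `excluded` (named vector of reasons).
#' @export
screen_families <- function(traces, burn_in = 1000L, ess_min = 200) {
  med <- list()
  excluded <- character(0)
  for (fam in names(traces)) {
    tr <- as.matrix(traces[[fam]])
    post <- tr[(burn_in + 1L):nrow(tr), , drop = FALSE]
    ess <- apply(post, 2L, function(col) effective_sample_size(col)$ess)
    if (any(ess < ess_min)) {
      excluded[fam] <- sprintf("ESS %.0f < %s for %s", min(ess), ess_min,
                               colnames(tr)[which.min(ess)])
      next
    }
    med[[fam]] <- apply(post, 2L, stats::median)
  }
  list(medians = if (length(med)) as.data.frame(do.call(rbind, med)) else
         data.frame(),
       excluded = excluded)
}

#' Consensus age as the KDE mode of per-family medians
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth, regular
#' grid) over the per-family median ages; the consensus age is the grid
#' argmax. Invariant to input order and deterministic.
#'
#' @param ages numeric vector of per-family median ages (>= 2).
#' @param n_grid grid size (default 512).
#' @return the consensus age (Ma).
#' @export
consensus_age <- function(ages, n_grid = 512L) {
  if (length(ages) < 2L) stop("need at least 2 family ages")
  kde_mode(ages, n_grid = n_grid)
}

#' Ranked-bootstrap confidence interval of the consensus age
#'
#' Draws `B` bootstrap resamples (with replacement) of the family ages,
#' computes the KDE mode of each, ranks the `B` modes in increasing order,
#' and returns the modes at ranks `ceiling(0.025 B) + 1` and
#' `B - ceiling(0.025 B) - 1` as the lower and upper 95% bounds - the
#' 26th and 974th ranked modes for B = 1000.
#'
#' @param ages numeric vector of per-family median ages (>= 2).
#' @param B bootstrap replicates (default 1000).
#' @param n_grid KDE grid size (default 512).
#' @return numeric(2): lower and upper CI bounds.
#' @export
bootstrap_ci <- function(ages, B = 1000L, n_grid = 512L) {
  if (length(ages) < 2L) stop("need at least 2 family ages")
  modes <- vapply(seq_len(B), function(b) {
    kde_mode(sample(ages, length(ages), replace = TRUE), n_grid = n_grid)
  }, numeric(1))
  modes <- sort(modes)
  lo_rank <- min(B, ceiling(0.025 * B) + 1L)
  hi_rank <- max(1L, B - ceiling(0.025 * B) - 1L)
  c(lo = modes[lo_rank], hi = modes[hi_rank])
}
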