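# Ka/Ks estimation (NG86 counting + Jukes-Cantor correction), duplication
# event deduplication by Ks clustering, Ks-distribution peak detection, and
# rate-distribution comparisons.

#' Jukes-Cantor multiple-hit correction
#'
#' d = -(3/4) ln(1 - (4/3) p). For p >= 3/4 the correction is undefined
#' and `NA` is returned with `saturated = TRUE` (flag, not error).
#'
#' @param p observed proportion of differences per site (>= 0).
#' @return list with `d` (distance or `NA`) and `saturated` (logical).
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0)
  if (p >= 0.75) return(list(d = NA_real_, saturated = TRUE))
  if (p == 0) return(list(d = 0, saturated = FALSE))  # avoid IEEE -0
  list(d = -0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

#' NG86 Ka/Ks estimate for a cleaned codon alignment
#'
#' Synonymous/nonsynonymous site counts are computed per codon as the
#' fraction of the nine single-nucleotide changes that are synonymous
#' (changes creating a stop codon count as nonsynonymous), averaged over
#' both sequences, so S + N = 3 x codons. Difference counts Sd/Nd average
#' with equal weights over all minimal mutational paths between differing
#' codons, excluding paths through stop codons; codon pairs with no valid
#' path are skipped and counted in `n_skipped`. Distances use the
#' Jukes-Cantor correction; when pS or pN >= 3/4 the `saturated` flag is
#' set instead of raising.
#'
#' @param caln a gap-free `codon_alignment` (e.g. after
#'   [clean_alignment_columns()]), with no stop codons.
#' @return object of class `ks_estimate`: list with fields `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`, `n_codons`, `n_skipped`,
#'   `saturated`.
#' @export
estimate_ka_ks <- function(caln) {
  if (any(caln$a == "---" | caln$b == "---"))
    stop("alignment contains gap columns; clean it first")
  tab <- codon_tables()
  ia <- match(caln$a, tab$codons)
  ib <- match(caln$b, tab$codons)
  if (anyNA(ia) || anyNA(ib)) stop("invalid codon in alignment")
  if (any(tab$is_stop[ia]) || any(tab$is_stop[ib]))
    stop("stop codon in alignment")
  sd_v <- tab$sd[cbind(ia, ib)]
  skip <- is.na(sd_v)
  if (all(skip)) stop("no scorable codon pairs in alignment")
  ia2 <- ia[!skip]
  ib2 <- ib[!skip]
  S <- sum((tab$syn_sites[ia2] + tab$syn_sites[ib2]) / 2)
  n_codons <- length(ia2)
  N <- 3 * n_codons - S
  Sd <- sum(tab$sd[cbind(ia2, ib2)])
  Nd <- sum(tab$nd[cbind(ia2, ib2)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc_correct(min(pS, 0.75))
  ka <- jc_correct(min(pN, 0.75))
  saturated <- pS >= 0.75 || pN >= 0.75
  Ks <- if (pS >= 0.75) NA_real_ else ks$d
  Ka <- if (pN >= 0.75) NA_real_ else ka$d
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka,
                 omega = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks
                         else NA_real_,
                 n_codons = n_codons, n_skipped = sum(skip),
                 saturated = saturated),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf(
    "NG86 estimate over %d codons: Ks = %.4f, Ka = %.4f, Ka/Ks = %.4f%s\n",
    x$n_codons, x$Ks, x$Ka, x$omega,
    if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Ka/Ks for many pre-aligned CDS pairs
#'
#' Applies [estimate_ka_ks()] to equal-length gap-free CDS pairs (the
#' simulator's output) and returns one row per pair.
#'
#' @param cds named character vector of coding sequences.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return data.frame with gene ids and the `ks_estimate` fields.
#' @export
estimate_ka_ks_pairs <- function(cds, pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    est <- estimate_ka_ks(codon_alignment(cds[[ga]], cds[[gb]],
                                          genes = c(ga, gb)))
    data.frame(gene_a = ga, gene_b = gb, S = est$S, N = est$N,
               Sd = est$Sd, Nd = est$Nd, Ka = est$Ka, Ks = est$Ks,
               omega = est$omega, saturated = est$saturated)
  })
  do.call(rbind, rows)
}

#' Deduplicate pairwise Ks into per-duplication events
#'
#' Genes are joined into families as connected components of pairs with
#' Ks <= `max_ks`; within each family, average-linkage hierarchical
#' clustering on the pairwise Ks emits one duplication event per internal
#' merge, at the merge height. A family of n genes yields exactly n - 1
#' events. Dissimilarities missing within a family (pairs above the
#' threshold or never estimated) are ignored in the cluster-pair average.
#'
#' @param pairwise_ks data.frame with columns `gene_a`, `gene_b`, `ks`.
#' @param max_ks family-joining threshold (default 5).
#' @return data.frame with columns `family`, `ks` (merge height), and
#'   `members` (gene ids at the merge, `;`-separated).
#' @export
cluster_duplication_events <- function(pairwise_ks, max_ks = 5.0) {
  empty <- data.frame(family = integer(0), ks = numeric(0),
                      members = character(0))
  if (nrow(pairwise_ks) == 0L) return(empty)
  keep <- !is.na(pairwise_ks$ks) & pairwise_ks$ks <= max_ks
  pk <- pairwise_ks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)
  genes <- sort(unique(c(pk$gene_a, pk$gene_b)))
  gi <- stats::setNames(seq_along(genes), genes)
  # connected components by union-find
  parent <- seq_along(genes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(pk))) {
    a <- find(gi[[pk$gene_a[r]]])
    b <- find(gi[[pk$gene_b[r]]])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(genes), find, integer(1))
  fam_ids <- match(comp, unique(comp))
  dmat <- matrix(NA_real_, length(genes), length(genes))
  dmat[cbind(gi[pk$gene_a], gi[pk$gene_b])] <- pk$ks
  dmat[cbind(gi[pk$gene_b], gi[pk$gene_a])] <- pk$ks
  out <- list()
  for (f in sort(unique(fam_ids))) {
    idx <- which(fam_ids == f)
    if (length(idx) < 2L) next
    # average-linkage agglomeration with missing-aware averages
    clusters <- lapply(idx, identity)
    while (length(clusters) > 1L) {
      best <- c(NA, NA)
      best_d <- Inf
      for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
        vals <- dmat[clusters[[i]], clusters[[j]], drop = FALSE]
        m <- mean(vals, na.rm = TRUE)
        if (is.finite(m) && m < best_d) {
          best_d <- m
          best <- c(j, i)
        }
      }
      if (!is.finite(best_d)) {
        # disconnected within component cannot happen, but guard anyway
        best <- c(1L, 2L)
        best_d <- max(dmat[unlist(clusters), unlist(clusters)], na.rm = TRUE)
      }
      merged <- c(clusters[[best[1]]], clusters[[best[2]]])
      out[[length(out) + 1L]] <- data.frame(
        family = f, ks = best_d,
        members = paste(genes[merged], collapse = ";"))
      clusters[[best[2]]] <- NULL
      clusters[[best[1]]] <- merged
    }
  }
  do.call(rbind, out)
}

#' Internal: KDE mode with a degenerate-input guard
#' @noRd
kde_mode <- function(x, n_grid = 512L, from = NULL, to = NULL) {
  if (length(unique(x)) == 1L) return(unique(x))
  bw <- stats::bw.nrd0(x)
  if (is.null(from)) from <- min(x) - 3 * bw
  if (is.null(to)) to <- max(x) + 3 * bw
  d <- stats::density(x, bw = bw, n = n_grid, from = from, to = to)
  d$x[which.max(d$y)]
}

#' Mode of a Ks distribution by Gaussian KDE
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth on a
#' regular grid spanning `[0, max(ks) + 3 bandwidths]`; the mode is the
#' grid argmax. Deterministic given its inputs.
#'
#' @param ks_values numeric vector of finite Ks values (>= 2 of them).
#' @param n_grid grid size (default 512).
#' @return list with `mode`, and `density` (data.frame with `x`, `y`).
#' @export
ks_distribution_mode <- function(ks_values, n_grid = 512L) {
  x <- ks_values[is.finite(ks_values)]
  if (length(x) < 2L) stop("need at least 2 finite Ks values")
  if (length(unique(x)) == 1L)
    return(list(mode = x[1],
                density = data.frame(x = x[1], y = Inf)))
  bw <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = n_grid, from = 0, to = max(x) + 3 * bw)
  list(mode = d$x[which.max(d$y)], density = data.frame(x = d$x, y = d$y))
}

#' One-sided Mann-Whitney U comparison of two rate distributions
#'
#' Wraps the Wilcoxon rank-sum test (exact U distribution when both groups
#' have <= 10 observations and no ties, normal approximation with tie
#' correction otherwise) with a Bonferroni adjustment over `m` planned
#' comparisons.
#'
#' @param a,b numeric vectors (e.g. Ka/Ks of two gene classes).
#' @param alternative `"less"` tests the alternative that `a` is
#'   stochastically smaller than `b`.
#' @param m Bonferroni family size (default 1).
#' @return list with `U`, `p`, `p_adjusted`, `n_a`, `n_b`.
#' @export
compare_rate_distributions <- function(a, b, alternative = "less", m = 1L) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  exact <- length(a) <= 10L && length(b) <= 10L
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       p_adjusted = min(1, m * wt$p.value),
       n_a = length(a), n_b = length(b))
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param m family size (>= number of tests).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
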