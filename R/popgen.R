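# Sequence-diversity summaries (pi, Watterson's theta, Tajima's D) and the
# gene presence/conservation filter.

#' Internal: validate a haplotype matrix
#' @noRd
.check_hap <- function(h) {
  h <- as.matrix(h)
  if (nrow(h) < 2L) stop("need at least 2 haplotypes")
  vals <- unique(as.vector(h))
  if (!all(vals %in% c(0L, 1L, NA)))
    stop("haplotype matrix must be 0/1 with optional NA")
  h
}

#' Internal: mean pairwise difference count (per pair, pairwise deletion)
#' @noRd
.pairwise_diffs <- function(h, per_site = FALSE, whole_site = FALSE) {
  n <- nrow(h)
  L <- attr(h, "L")
  if (whole_site) {
    keep <- colSums(is.na(h)) == 0L
    L <- L - sum(!keep)
    h <- h[, keep, drop = FALSE]
  }
  tot <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(h[i, ]) & !is.na(h[j, ])
    d <- sum(h[i, ok] != h[j, ok])
    if (per_site) {
      # per-pair effective length: locus length minus this pair's
      # unusable columns
      tot <- tot + d / (L - sum(!ok))
    } else {
      tot <- tot + d
    }
    npair <- npair + 1L
  }
  tot / npair
}

#' Nucleotide diversity (pi)
#'
#' Average number of pairwise differences per site:
#' mean over haplotype pairs of d_ij / L_ij, where sites missing in either
#' member of a pair are excluded from that pair only (pairwise deletion;
#' `whole_site = TRUE` drops any column with missing data for all pairs
#' instead). Monomorphic positions of the locus count toward L via the
#' matrix's `L` attribute (defaults to the number of columns).
#'
#' @param h `haplotype_matrix` or plain 0/1 matrix (rows = haplotypes).
#' @param whole_site use complete-column deletion instead of pairwise.
#' @return pi per site.
#' @export
nucleotide_diversity <- function(h, whole_site = FALSE) {
  h <- .check_hap(h)
  if (is.null(attr(h, "L"))) attr(h, "L") <- ncol(h)
  if (ncol(h) == 0L) return(0)
  .pairwise_diffs(h, per_site = TRUE, whole_site = whole_site)
}

#' Watterson's theta
#'
#' S / (a1 L) with S the number of segregating sites, a1 the harmonic
#' number sum(1/i, i = 1..n-1), and L the locus length.
#'
#' @param h `haplotype_matrix` or plain 0/1 matrix.
#' @return theta per site.
#' @export
wattersons_theta <- function(h) {
  h <- .check_hap(h)
  L <- attr(h, "L")
  if (is.null(L)) L <- ncol(h)
  if (ncol(h) == 0L) return(0)
  seg <- vapply(seq_len(ncol(h)), function(j) {
    v <- h[, j]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  S <- sum(seg)
  a1 <- sum(1 / seq_len(nrow(h) - 1L))
  S / (a1 * L)
}

#' Tajima's D
#'
#' D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1)) with the standard
#' constants: a1 = sum 1/i, a2 = sum 1/i^2 (i = 1..n-1),
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#' pi_total is the mean pairwise difference count (not per site).
#' Undefined (flagged) when S = 0.
#'
#' @param h `haplotype_matrix` or plain 0/1 matrix.
#' @return list with `d` (or NA) and `defined`.
#' @export
tajimas_d <- function(h) {
  h <- .check_hap(h)
  n <- nrow(h)
  if (ncol(h) == 0L) return(list(d = NA_real_, defined = FALSE))
  seg <- vapply(seq_len(ncol(h)), function(j) {
    v <- h[, j]
    length(unique(v[!is.na(v)])) > 1L
  }, logical(1))
  S <- sum(seg)
  if (S == 0L) return(list(d = NA_real_, defined = FALSE))
  pi_total <- .pairwise_diffs(h, per_site = FALSE)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(d = d, defined = TRUE)
}

#' Full diversity summary for one locus
#'
#' @param h `haplotype_matrix` or plain 0/1 matrix.
#' @return data.frame with `n`, `L`, `S`, `pi`, `theta_w`, `tajimas_d`.
#' @export
diversity_summary <- function(h) {
  h2 <- .check_hap(h)
  L <- attr(h2, "L")
  if (is.null(L)) L <- ncol(h2)
  seg <- if (ncol(h2) == 0L) logical(0) else
    vapply(seq_len(ncol(h2)), function(j) {
      v <- h2[, j]
      length(unique(v[!is.na(v)])) > 1L
    }, logical(1))
  td <- tajimas_d(h2)
  data.frame(n = nrow(h2), L = L, S = sum(seg),
             pi = nucleotide_diversity(h2),
             theta_w = wattersons_theta(h2),
             tajimas_d = if (td$defined) td$d else NA_real_)
}

#' Gene presence and conservation filter
#'
#' A gene is present in a sample iff its ambiguous fraction (missing data
#' or sites below the depth threshold) is strictly below `max_ambiguous`;
#' it is conserved iff present in every sample.
#'
#' @param cov matrix of ambiguous fractions (genes x samples), as from
#'   the simulator or computed upstream from depth profiles with
#'   `min_depth` applied before the fraction.
#' @param max_ambiguous presence cutoff, strict (default 0.30).
#' @param min_depth depth threshold recorded for provenance (default 5);
#'   not applied here because `cov` is already a fraction.
#' @return list with `present` (logical matrix) and `conserved`
#'   (character vector of gene ids present in all samples).
#' @export
gene_presence_filter <- function(cov, max_ambiguous = 0.30, min_depth = 5) {
  stopifnot(all(cov >= 0 & cov <= 1))
  present <- cov < max_ambiguous
  conserved <- rownames(cov)[rowSums(present) == ncol(cov)]
  list(present = present, conserved = conserved)
}

#' Ambiguous fraction from a per-site depth profile
#'
#' Fraction of positions that are missing (NA) or covered below
#' `min_depth`.
#'
#' @param depth numeric vector of per-position depths (NA = missing).
#' @param min_depth minimum acceptable depth (default 5).
#' @return fraction in \[0, 1\].
#' @export
ambiguous_fraction <- function(depth, min_depth = 5) {
  mean(is.na(depth) | depth < min_depth)
}
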