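# Independent oracles kept deliberately separate from the package
# implementations: recursive path enumeration for codon difference counts,
# a memoized recursive affine-gap alignment scorer, a literal window check
# for column cleaning, bitmask enumeration for collinear chains, and a
# site-frequency route to pairwise diversity.

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_nt <- c("T", "C", "A", "G")

oracle_translate <- function(codon) unname(.oracle_gc[codon])

# per-codon synonymous site count; stop-creating changes nonsynonymous
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    for (alt in setdiff(.oracle_nt, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      if (oracle_translate(mut) == aa) s <- s + 1
    }
  }
  s / 3
}

# recursive enumeration of all minimal mutational paths between two sense
# codons, skipping paths through stops; returns average (syn, nonsyn)
# step counts or NULL if no valid path exists
oracle_path_counts <- function(ca, cb) {
  paths <- list()
  walk <- function(cur, s, n) {
    diffpos <- which(strsplit(cur, "")[[1]] != strsplit(cb, "")[[1]])
    if (length(diffpos) == 0L) {
      paths[[length(paths) + 1L]] <<- c(s, n)
      return(invisible())
    }
    for (p in diffpos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (oracle_translate(nxt) == "*") next
      if (oracle_translate(nxt) == oracle_translate(cur))
        walk(nxt, s + 1, n) else walk(nxt, s, n + 1)
    }
  }
  walk(ca, 0, 0)
  if (length(paths) == 0L) return(NULL)
  colMeans(do.call(rbind, paths))
}

# memoized recursive affine alignment score (max over end states);
# gap of length k costs open + k * extend
oracle_align_score <- function(a, b, submat, open = 10, extend = 1) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0L && j == 0L) {
      if (state == "m") 0 else -Inf
    } else if (state == "m") {
      if (i == 0L || j == 0L) -Inf else
        submat[ra[i], rb[j]] + max(rec(i - 1L, j - 1L, "m"),
                                   rec(i - 1L, j - 1L, "e"),
                                   rec(i - 1L, j - 1L, "f"))
    } else if (state == "e") {  # gap in b, consumes a[i]
      if (i == 0L) -Inf else
        max(rec(i - 1L, j, "m") - open - extend,
            rec(i - 1L, j, "e") - extend,
            rec(i - 1L, j, "f") - open - extend)
    } else {  # gap in a, consumes b[j]
      if (j == 0L) -Inf else
        max(rec(i, j - 1L, "m") - open - extend,
            rec(i, j - 1L, "e") - open - extend,
            rec(i, j - 1L, "f") - extend)
    }
    memo[[key]] <- val
    val
  }
  max(rec(length(ra), length(rb), "m"),
      rec(length(ra), length(rb), "e"),
      rec(length(ra), length(rb), "f"))
}

# literal per-column window check for the gap-flank cleaning rule
oracle_clean_keep <- function(gapfree, flank = 3L) {
  L <- length(gapfree)
  vapply(seq_len(L), function(i) {
    win <- max(1L, i - flank):min(L, i + flank)
    all(gapfree[win])
  }, logical(1))
}

# exhaustive best collinear chain over all anchor subsets (bitmask);
# validity: one orientation, strictly monotone ranks, per-step gaps
# within max_gap; score = k - gap_penalty * total rank gap
oracle_best_chain_score <- function(out_rank, in_rank, max_gap = 25L,
                                    gap_penalty = 0.05) {
  n <- length(out_rank)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    o <- order(out_rank[idx])
    orr <- out_rank[idx][o]
    irr <- in_rank[idx][o]
    k <- length(idx)
    if (anyDuplicated(orr)) next
    valid_dir <- function(ir) {
      if (k == 1L) return(TRUE)
      d_out <- diff(orr) - 1L
      d_in <- diff(ir) - 1L
      all(d_in >= 0L) && all(d_out <= max_gap) && all(d_in <= max_gap)
    }
    for (ir in list(irr, -irr)) {
      if (k > 1L && !valid_dir(ir)) next
      gaps <- if (k == 1L) 0 else sum(diff(orr) - 1L) + sum(diff(ir) - 1L)
      sc <- k - gap_penalty * gaps
      if (sc > best) best <- sc
      if (k == 1L) break
    }
  }
  best
}

# hypergeometric right tail by direct enumeration with dhyper
oracle_fisher_tail <- function(a, b, c, d) {
  sum(stats::dhyper(a:min(a + b, a + c), a + c, b + d, a + b))
}

# pairwise diversity through the site-frequency spectrum:
# sum over sites of x (n - x) / choose(n, 2); requires complete data
oracle_pi_total <- function(h) {
  n <- nrow(h)
  x <- colSums(h)
  sum(x * (n - x)) / choose(n, 2)
}

# Tajima's D from the SFS route, constants written out independently
oracle_tajimas_d <- function(h) {
  n <- nrow(h)
  S <- sum(apply(h, 2, function(v) length(unique(v)) > 1L))
  if (S == 0L) return(NA_real_)
  a1 <- sum(1 / 1:(n - 1))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (oracle_pi_total(h) - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# random sense-codon CDS for fixtures
random_sense_cds <- function(n_codons) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
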