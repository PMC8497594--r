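# Exact 2x2 enrichment tests with Bonferroni correction (retention x
# drought response) and GO term enrichment with classic Fisher and the
# elim decorrelation algorithm plus BH FDR.

#' One-sided Fisher's exact test for a 2x2 table
#'
#' P(X >= a) under the hypergeometric null fixing the table margins
#' (enrichment alternative), computed with log-factorials. A zero margin
#' gives the degenerate p = 1 with a flag.
#'
#' @param a,b,c,d non-negative integer cells: a = retained & responsive,
#'   b = retained & non-responsive, c = non-retained & responsive,
#'   d = non-retained & non-responsive.
#' @return list with `p` and `degenerate`.
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n_total <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  if (row1 == 0L || col1 == 0L || row1 == n_total || col1 == n_total)
    return(list(p = 1, degenerate = TRUE))
  x_max <- min(row1, col1)
  xs <- a:x_max
  logp <- lgamma(col1 + 1) - lgamma(xs + 1) - lgamma(col1 - xs + 1) +
    lgamma(n_total - col1 + 1) - lgamma(row1 - xs + 1) -
    lgamma(n_total - col1 - row1 + xs + 1) -
    (lgamma(n_total + 1) - lgamma(row1 + 1) - lgamma(n_total - row1 + 1))
  m <- max(logp)
  list(p = min(1, exp(m + log(sum(exp(logp - m))))), degenerate = FALSE)
}

#' Retention-by-response enrichment tests
#'
#' Builds one 2x2 table per response direction (responsive in that
#' direction vs not, among genes with a retention call), applies the
#' one-sided enrichment test of [fisher_exact_one_sided()], and
#' Bonferroni-corrects across the directions tested. Genes without a
#' retained/non-retained call (e.g. category C) are excluded.
#'
#' @param retention retention table (data.frame with `gene_id`,
#'   `retained`, `non_retained`).
#' @param labels data.frame with `gene_id` and `direction`
#'   (`up`/`down`/`none`); every labeled gene that has a retention call is
#'   used.
#' @param directions directions to test (default `c("up", "down")`).
#' @param alternative `"greater"` (default) tests enrichment of responsive
#'   genes among retained duplicates; `"two.sided"` uses the two-sided
#'   exact test from `stats::fisher.test`.
#' @return data.frame with one row per direction: cells `a`-`d`, `p`,
#'   `p_adjusted`.
#' @export
retention_enrichment_test <- function(retention, labels,
                                      directions = c("up", "down"),
                                      alternative = "greater") {
  called <- retention[retention$retained | retention$non_retained, ,
                      drop = FALSE]
  lab <- labels[labels$gene_id %in% called$gene_id, , drop = FALSE]
  missing_ret <- setdiff(labels$gene_id, retention$gene_id)
  if (length(missing_ret) > 0L)
    stop("labels reference genes absent from the retention table: ",
         paste(utils::head(missing_ret, 5), collapse = ","))
  is_ret <- stats::setNames(called$retained, called$gene_id)
  rows <- lapply(directions, function(dir) {
    resp <- stats::setNames(lab$direction == dir, lab$gene_id)
    genes <- called$gene_id[called$gene_id %in% lab$gene_id]
    r <- is_ret[genes]
    s <- resp[genes]
    a <- sum(r & s)
    b <- sum(r & !s)
    c_ <- sum(!r & s)
    d <- sum(!r & !s)
    p <- if (alternative == "greater")
      fisher_exact_one_sided(a, b, c_, d)$p
    else
      stats::fisher.test(matrix(c(a, c_, b, d), 2L),
                         alternative = "two.sided")$p.value
    data.frame(direction = dir, a = a, b = b, c = c_, d = d, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m = length(directions))
  out
}

#' Retention enrichment from pre-tabulated counts
#'
#' Applies the one-sided test and Bonferroni correction directly to
#' printed 2x2 counts, one row per direction.
#'
#' @param counts data.frame (or matrix) with columns `a`, `b`, `c`, `d`
#'   and one row per direction.
#' @param digits rounding applied to the adjusted p (default 4, the
#'   reporting convention).
#' @return data.frame with `p`, `p_adjusted`, `p_adjusted_rounded`.
#' @export
retention_enrichment_from_counts <- function(counts, digits = 4L) {
  counts <- as.data.frame(counts)
  p <- vapply(seq_len(nrow(counts)), function(i)
    fisher_exact_one_sided(counts$a[i], counts$b[i], counts$c[i],
                           counts$d[i])$p, numeric(1))
  adj <- bonferroni(p, m = nrow(counts))
  cbind(counts, p = p, p_adjusted = adj,
        p_adjusted_rounded = round(adj, digits))
}

#' Build a GO DAG with propagated annotations
#'
#' Validates acyclicity of the is_a edges and propagates gene-term
#' annotations to all ancestors, so a term's gene set contains the union
#' of its descendants' sets.
#'
#' @param edges data.frame with columns `child`, `parent` (is_a edges).
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return object of class `go_dag`: list with `terms`, `parents` (named
#'   list), `ann` (named list of gene sets per term, propagated), and
#'   `order` (children-before-parents term order).
#' @export
go_dag <- function(edges, annotations) {
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  # topological order, leaves (no children) first; detects cycles
  n_children <- vapply(children, length, integer(1))
  remaining <- stats::setNames(n_children, terms)
  queue <- terms[remaining == 0L]
  topo <- character(0)
  while (length(queue) > 0L) {
    t <- queue[1]
    queue <- queue[-1]
    topo <- c(topo, t)
    for (p in parents[[t]]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(topo) != length(terms)) stop("GO edge set contains a cycle")
  ann <- stats::setNames(
    lapply(terms, function(t)
      unique(annotations$gene[annotations$term == t])), terms)
  for (t in topo) {  # children first: push annotations upward
    for (p in parents[[t]]) ann[[p]] <- union(ann[[p]], ann[[t]])
  }
  structure(list(terms = terms, parents = parents, ann = ann,
                 order = topo),
            class = "go_dag")
}

#' GO enrichment with the elim decorrelation algorithm
#'
#' Terms are tested from the bottom of the DAG upward (children before
#' parents) with the one-sided Fisher test on annotated-in-study vs rest.
#' When a term's elim p falls below `elim_threshold`, its study genes
#' annotated to it are removed from all ancestors' annotation sets before
#' those are tested, decorrelating the DAG. Classic (non-elim) p-values
#' and their BH adjustment are also reported. With `elim_threshold = 0`
#' elim reduces exactly to classic Fisher.
#'
#' @param dag a `go_dag`.
#' @param study character vector of study genes (subset of population).
#' @param population character vector of population genes.
#' @param elim_threshold elimination p cutoff (default 0.05).
#' @param top_k rows to return, sorted by elim p (default 40).
#' @return data.frame with `term`, `annotated`, `study_count`,
#'   `expected`, `p_classic`, `p_elim`, `p_bh` (BH over classic).
#' @export
go_enrichment_elim <- function(dag, study, population,
                               elim_threshold = 0.05, top_k = 40L) {
  if (!all(study %in% population)) stop("study must be a subset of population")
  n_pop <- length(population)
  n_study <- length(study)
  test_term <- function(genes) {
    genes <- intersect(genes, population)
    a <- length(intersect(genes, study))
    b <- length(genes) - a
    c_ <- n_study - a
    d <- n_pop - n_study - b
    list(a = a, ann = length(genes),
         p = fisher_exact_one_sided(a, b, c_, d)$p)
  }
  # classic pass (no elimination)
  classic <- lapply(dag$ann, test_term)
  # ancestors closure for elimination
  anc_of <- function(t) {
    seen <- character(0)
    stack <- dag$parents[[t]]
    while (length(stack) > 0L) {
      p <- stack[1]
      stack <- stack[-1]
      if (p %in% seen) next
      seen <- c(seen, p)
      stack <- c(stack, dag$parents[[p]])
    }
    seen
  }
  ann_elim <- dag$ann
  p_elim <- stats::setNames(rep(NA_real_, length(dag$terms)), dag$terms)
  for (t in dag$order) {
    res <- test_term(ann_elim[[t]])
    p_elim[t] <- res$p
    if (elim_threshold > 0 && res$p < elim_threshold) {
      drop <- intersect(intersect(dag$ann[[t]], study), population)
      for (aT in anc_of(t))
        ann_elim[[aT]] <- setdiff(ann_elim[[aT]], drop)
    }
  }
  out <- data.frame(
    term = dag$terms,
    annotated = vapply(classic, `[[`, integer(1), "ann")[dag$terms],
    study_count = vapply(classic, `[[`, integer(1), "a")[dag$terms],
    p_classic = vapply(classic, `[[`, numeric(1), "p")[dag$terms],
    p_elim = p_elim[dag$terms])
  out$expected <- out$annotated * n_study / n_pop
  out$p_bh <- bh_fdr(out$p_classic)
  out <- out[order(out$p_elim, out$term), ,
             drop = FALSE][seq_len(min(top_k, nrow(out))), ]
  rownames(out) <- NULL
  out[, c("term", "annotated", "study_count", "expected", "p_classic",
          "p_elim", "p_bh")]
}
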