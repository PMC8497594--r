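# Protein-guided codon alignment and the gap-flank column-cleaning and
# length/coverage filters applied before Ka/Ks estimation.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Global protein alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment maximizing the summed substitution
#' score minus affine gap costs (a gap of length k costs
#' `gap_open + k * gap_extend`). Tie-breaking during traceback prefers the
#' diagonal move, then a gap in `b` (consuming `a`), then a gap in `a`, so
#' scores and paths are reproducible.
#'
#' @param a,b character scalars over the 20 amino acids plus `X`.
#' @param submat substitution matrix with residue dimnames; defaults to
#'   BLOSUM62 from Biostrings.
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return object of class `protein_alignment`: list with gapped strings
#'   `a` and `b`, `score`, and ungapped lengths `len_a`, `len_b`.
#' @export
global_protein_align <- function(a, b, submat = NULL,
                                 gap_open = 10, gap_extend = 1) {
  if (is.null(submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    submat <- e$BLOSUM62
  }
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  if (length(ra) == 0L || length(rb) == 0L)
    stop("empty protein sequence")
  bad <- setdiff(unique(c(ra, rb)), .AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue(s): ", paste(bad, collapse = ","))
  n <- length(ra)
  m <- length(rb)
  ia <- match(ra, rownames(submat))
  ib <- match(rb, colnames(submat))
  neg <- -Inf
  # M: a[i] aligned to b[j]; E: gap in b ending at (i,j) (a consumed);
  # F: gap in a ending at (i,j) (b consumed)
  M <- matrix(neg, n + 1L, m + 1L)
  E <- matrix(neg, n + 1L, m + 1L)
  F_ <- matrix(neg, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) E[i, 1] <- -gap_open - (i - 1L) * gap_extend
  if (m >= 1L) for (j in 2:(m + 1L)) F_[1, j] <- -gap_open - (j - 1L) * gap_extend
  for (i in 2:(n + 1L)) {
    srow <- submat[ia[i - 1L], ib]
    for (j in 2:(m + 1L)) {
      best_prev <- max(M[i - 1L, j - 1L], E[i - 1L, j - 1L], F_[i - 1L, j - 1L])
      M[i, j] <- best_prev + srow[j - 1L]
      E[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     E[i - 1L, j] - gap_extend,
                     F_[i - 1L, j] - gap_open - gap_extend)
      F_[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                      F_[i, j - 1L] - gap_extend,
                      E[i, j - 1L] - gap_open - gap_extend)
    }
  }
  score <- max(M[n + 1L, m + 1L], E[n + 1L, m + 1L], F_[n + 1L, m + 1L])
  # traceback with diagonal > up (gap in b) > left (gap in a) preference
  ga <- character(0)
  gb <- character(0)
  i <- n + 1L
  j <- m + 1L
  state <- which.max(c(M[i, j], E[i, j], F_[i, j]))
  eps <- 1e-9
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      ga <- c(ra[i - 1L], ga)
      gb <- c(rb[j - 1L], gb)
      s <- submat[ia[i - 1L], ib[j - 1L]]
      prev <- c(M[i - 1L, j - 1L], E[i - 1L, j - 1L], F_[i - 1L, j - 1L])
      state <- which(abs(prev + s - M[i, j]) < eps)[1]
      i <- i - 1L
      j <- j - 1L
    } else if (state == 2L) {
      ga <- c(ra[i - 1L], ga)
      gb <- c("-", gb)
      cand <- c(M[i - 1L, j] - gap_open - gap_extend,
                E[i - 1L, j] - gap_extend,
                F_[i - 1L, j] - gap_open - gap_extend)
      state <- which(abs(cand - E[i, j]) < eps)[1]
      i <- i - 1L
    } else {
      ga <- c("-", ga)
      gb <- c(rb[j - 1L], gb)
      cand <- c(M[i, j - 1L] - gap_open - gap_extend,
                E[i, j - 1L] - gap_open - gap_extend,
                F_[i, j - 1L] - gap_extend)
      state <- which(abs(cand - F_[i, j]) < eps)[1]
      j <- j - 1L
    }
  }
  structure(list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
                 score = score, len_a = n, len_b = m),
            class = "protein_alignment")
}

#' Construct a codon alignment from two equal-length in-frame CDS
#'
#' Convenience constructor for homolog pairs that are already column
#' compatible (no indels), as produced by the simulator: each codon becomes
#' one gap-free column.
#'
#' @param cds_a,cds_b in-frame coding sequences of equal length.
#' @param genes optional character(2) of source gene ids.
#' @return object of class `codon_alignment`: codon-column vectors `a`,
#'   `b` (triplets or `---`), ungapped lengths `len_a`, `len_b` (codons),
#'   and `genes`.
#' @export
codon_alignment <- function(cds_a, cds_b, genes = c(NA, NA)) {
  if (nchar(cds_a) != nchar(cds_b))
    stop("CDS lengths differ; align proteins first")
  ia <- cds_to_codon_idx(cds_a)
  ib <- cds_to_codon_idx(cds_b)
  tab <- codon_tables()
  structure(list(a = tab$codons[ia], b = tab$codons[ib],
                 len_a = length(ia), len_b = length(ib),
                 genes = genes),
            class = "codon_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each amino-acid column of the protein alignment to the matching
#' codon (or a 3-base gap), using the amino-acid alignment as a guide.
#' Each CDS must translate exactly to its protein under the standard code.
#'
#' @param paln a `protein_alignment`.
#' @param cds_a,cds_b the coding sequences behind the two proteins.
#' @param genes optional character(2) of source gene ids.
#' @return a `codon_alignment` with one codon column per protein column.
#' @export
backtranslate_alignment <- function(paln, cds_a, cds_b, genes = c(NA, NA)) {
  ga <- strsplit(paln$a, "")[[1]]
  gb <- strsplit(paln$b, "")[[1]]
  pa <- gsub("-", "", paln$a)
  pb <- gsub("-", "", paln$b)
  if (translate_cds(cds_a) != pa)
    stop("cds_a does not translate to the aligned protein")
  if (translate_cds(cds_b) != pb)
    stop("cds_b does not translate to the aligned protein")
  cod_a <- codon_tables()$codons[cds_to_codon_idx(cds_a)]
  cod_b <- codon_tables()$codons[cds_to_codon_idx(cds_b)]
  col_a <- character(length(ga))
  col_b <- character(length(gb))
  ka <- 0L
  kb <- 0L
  for (i in seq_along(ga)) {
    if (ga[i] == "-") col_a[i] <- "---" else {
      ka <- ka + 1L
      col_a[i] <- cod_a[ka]
    }
    if (gb[i] == "-") col_b[i] <- "---" else {
      kb <- kb + 1L
      col_b[i] <- cod_b[kb]
    }
  }
  structure(list(a = col_a, b = col_b,
                 len_a = length(cod_a), len_b = length(cod_b),
                 genes = genes),
            class = "codon_alignment")
}

#' Remove alignment columns near gaps
#'
#' A column is retained iff it is gap-free and every existing column within
#' `flank` positions on each side is also gap-free. With
#' `drop_ends = FALSE` (default) the window is clipped at the alignment
#' ends, so a gap-free alignment is returned intact; with
#' `drop_ends = TRUE` positions beyond the ends are treated as gaps and the
#' first/last `flank` columns are always removed. Idempotent.
#'
#' @param caln a `codon_alignment`.
#' @param flank window half-width in columns (default 3).
#' @param drop_ends end-handling variant, see above.
#' @return a `codon_alignment` with only the retained columns, in order.
#' @export
clean_alignment_columns <- function(caln, flank = 3L, drop_ends = FALSE) {
  L <- length(caln$a)
  if (L == 0L) return(caln)
  gapfree <- caln$a != "---" & caln$b != "---"
  # windowed gap count via padded cumulative sums
  pad <- if (drop_ends) 0L else 1L  # pad value 1 = "gap-free" beyond ends
  ext <- c(rep(pad, flank), as.integer(gapfree), rep(pad, flank))
  cs <- c(0L, cumsum(ext))
  win <- 2L * flank + 1L
  ok <- (cs[(1:L) + win] - cs[1:L]) == win
  keep <- gapfree & ok
  out <- caln
  out$a <- caln$a[keep]
  out$b <- caln$b[keep]
  out
}

#' Length and coverage filter for cleaned alignments
#'
#' Passes iff the cleaned alignment is strictly longer than `min_len_aa`
#' columns and covers at least `min_cov` of the ungapped length of both
#' source sequences.
#'
#' @param caln a cleaned `codon_alignment` (gap-free).
#' @param min_len_aa minimum length in aa/codons, strict (default 150).
#' @param min_cov minimum coverage of each source, inclusive (default 0.5).
#' @return logical scalar.
#' @export
alignment_passes_filters <- function(caln, min_len_aa = 150, min_cov = 0.5) {
  L <- length(caln$a)
  L > min_len_aa && L / caln$len_a >= min_cov && L / caln$len_b >= min_cov
}
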