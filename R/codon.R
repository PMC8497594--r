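# Genetic-code machinery shared by the codon evolver and the NG86 estimator.
# Codons are indexed 1..64 with T,C,A,G order on each position, matching the
# layout of Biostrings::GENETIC_CODE.

.NT <- c("T", "C", "A", "G")

.codon_env <- new.env(parent = emptyenv())

#' Internal: codon lookup tables
#'
#' Builds (once per session) the amino-acid translation vector indexed by
#' codon index, the per-codon NG86 synonymous site counts, and the 64 x 64
#' matrices of path-averaged synonymous/nonsynonymous difference counts.
#' Stop-creating single-nucleotide changes are counted as nonsynonymous in
#' site counting so that S + N = 3 per codon; mutational paths passing
#' through a stop codon are excluded from the path average.
#' @noRd
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- character(64)
  for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
    idx <- 16L * (i1 - 1L) + 4L * (i2 - 1L) + i3
    codons[idx] <- paste0(.NT[i1], .NT[i2], .NT[i3])
  }
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"

  # neighbor structure: nb_idx[codon, position, alt] = index of mutated codon
  nb <- array(NA_integer_, dim = c(64, 3, 3))
  pos_mult <- c(16L, 4L, 1L)
  for (ci in 1:64) {
    d <- c((ci - 1L) %/% 16L, ((ci - 1L) %/% 4L) %% 4L, (ci - 1L) %% 4L)
    for (p in 1:3) {
      alts <- setdiff(0:3, d[p])
      for (k in 1:3) {
        dd <- d
        dd[p] <- alts[k]
        nb[ci, p, k] <- 16L * dd[1] + 4L * dd[2] + dd[3] + 1L
      }
    }
  }

  # per-codon synonymous site count: fraction of the 9 single-nt changes
  # that are synonymous (stop targets count as nonsynonymous)
  syn_sites <- rep(NA_real_, 64)
  for (ci in 1:64) {
    if (is_stop[ci]) next
    s <- 0
    for (p in 1:3) for (k in 1:3) {
      if (aa[nb[ci, p, k]] == aa[ci]) s <- s + 1
    }
    syn_sites[ci] <- s / 3
  }

  # pairwise difference counts averaged over minimal mutational paths
  sd_mat <- matrix(NA_real_, 64, 64)
  nd_mat <- matrix(NA_real_, 64, 64)
  digits <- function(ci) c((ci - 1L) %/% 16L, ((ci - 1L) %/% 4L) %% 4L,
                           (ci - 1L) %% 4L)
  for (ca in 1:64) {
    if (is_stop[ca]) next
    da <- digits(ca)
    for (cb in 1:64) {
      if (is_stop[cb]) next
      db <- digits(cb)
      diffpos <- which(da != db)
      ndiff <- length(diffpos)
      if (ndiff == 0L) {
        sd_mat[ca, cb] <- 0
        nd_mat[ca, cb] <- 0
        next
      }
      perms <- switch(ndiff,
        list(1L),
        list(c(1L, 2L), c(2L, 1L)),
        list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
      tot_s <- 0
      tot_n <- 0
      nvalid <- 0L
      for (pm in perms) {
        cur <- da
        s <- 0
        n <- 0
        ok <- TRUE
        for (step in pm) {
          p <- diffpos[step]
          nxt <- cur
          nxt[p] <- db[p]
          from_i <- 16L * cur[1] + 4L * cur[2] + cur[3] + 1L
          to_i <- 16L * nxt[1] + 4L * nxt[2] + nxt[3] + 1L
          if (is_stop[to_i]) {
            ok <- FALSE
            break
          }
          if (aa[from_i] == aa[to_i]) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        if (ok) {
          tot_s <- tot_s + s
          tot_n <- tot_n + n
          nvalid <- nvalid + 1L
        }
      }
      if (nvalid > 0L) {
        sd_mat[ca, cb] <- tot_s / nvalid
        nd_mat[ca, cb] <- tot_n / nvalid
      } # else left NA: all minimal paths pass through a stop
    }
  }

  .codon_env$tab <- list(codons = codons, aa = aa, is_stop = is_stop,
                         nb = nb, syn_sites = syn_sites,
                         sd = sd_mat, nd = nd_mat)
  .codon_env$tab
}

#' Internal: split a CDS string into codon indices
#' @noRd
cds_to_codon_idx <- function(cds) {
  cds <- toupper(gsub("U", "T", cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length is not a multiple of 3: ", n)
  nts <- strsplit(cds, "")[[1]]
  code <- match(nts, .NT)
  if (anyNA(code)) stop("invalid nucleotide in CDS: ",
                        paste(unique(nts[is.na(code)]), collapse = ","))
  m <- matrix(code - 1L, nrow = 3)
  as.integer(16L * m[1, ] + 4L * m[2, ] + m[3, ] + 1L)
}

#' Internal: codon indices back to a CDS string
#' @noRd
codon_idx_to_cds <- function(idx) {
  paste(codon_tables()$codons[idx], collapse = "")
}

#' Translate a coding sequence
#'
#' Standard-code translation of an in-frame CDS; used to check
#' CDS/protein consistency during back-translation and to derive protein
#' sequences for simulated genes.
#'
#' @param cds character scalar, in-frame coding sequence (no gaps).
#' @return character scalar amino-acid sequence (stop rendered as `*`).
#' @export
translate_cds <- function(cds) {
  idx <- cds_to_codon_idx(cds)
  paste(codon_tables()$aa[idx], collapse = "")
}

#' Evolve a codon sequence to a target synonymous divergence
#'
#' Discrete-event nucleotide mutation process with equal exchange rates.
#' Single-nucleotide changes are proposed at uniformly random positions;
#' proposals creating a stop codon are rejected, synonymous proposals are
#' always accepted, and nonsynonymous proposals are accepted with
#' probability `omega`. The process runs until the number of accepted
#' synonymous substitutions reaches a Poisson draw with mean
#' `target_ks` times the NG86 synonymous site count of the input, so the
#' expected synonymous divergence of the output equals `target_ks` and the
#' expected Ka/Ks equals `omega`. Uses the current R RNG stream.
#'
#' @param cds character scalar, in-frame CDS without internal stop codons.
#' @param target_ks target expected synonymous substitutions per synonymous
#'   site (>= 0).
#' @param omega acceptance probability for nonsynonymous changes (Ka/Ks).
#' @return character scalar, the evolved CDS (same length, no internal
#'   stops).
#' @export
evolve_codon_sequence <- function(cds, target_ks, omega) {
  stopifnot(is.numeric(target_ks), length(target_ks) == 1L, target_ks >= 0,
            is.numeric(omega), length(omega) == 1L, omega >= 0, omega <= 1)
  tab <- codon_tables()
  idx <- cds_to_codon_idx(cds)
  if (any(tab$is_stop[idx])) stop("internal stop codon in input CDS")
  if (target_ks == 0) return(cds)
  s0 <- sum(tab$syn_sites[idx])
  n_target <- stats::rpois(1L, target_ks * s0)
  if (n_target == 0L) return(cds)
  ncod <- length(idx)
  syn_done <- 0L
  while (syn_done < n_target) {
    ci <- sample.int(ncod, 1L)
    p <- sample.int(3L, 1L)
    k <- sample.int(3L, 1L)
    new_idx <- tab$nb[idx[ci], p, k]
    if (tab$is_stop[new_idx]) next
    if (tab$aa[new_idx] == tab$aa[idx[ci]]) {
      idx[ci] <- new_idx
      syn_done <- syn_done + 1L
    } else if (stats::runif(1L) < omega) {
      idx[ci] <- new_idx
    }
  }
  codon_idx_to_cds(idx)
}
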