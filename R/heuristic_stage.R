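# The heuristic-stage driver: Mendelian rules, long-range phasing and
# haplotype-library imputation over all core tilings, cross-core consensus,
# the recombination sweep, and a final segregation analysis.

# Phase one core: surrogate phasing, then general and parent-restricted
# haplotype-library imputation.  `Cb` is the 2n x Lc phase block.
phase_core <- function(G, Cb, sire_idx, dam_idx, cands, rng, min_overlap) {
  n <- nrow(G)
  Lc <- length(rng)
  Gr <- G[, rng, drop = FALSE]
  # numeric indicators once per core; conflict and overlap counts then reduce
  # to matrix-vector products over candidate rows
  G0 <- (Gr == 0L) + 0
  G2 <- (Gr == 2L) + 0
  Gn <- (Gr != MISSING) + 0
  unres <- rowSums(Cb == MISSING)

  # ---- surrogate phasing -------------------------------------------------
  for (i in seq_len(n)) {
    r1 <- 2L * i - 1L
    r2 <- 2L * i
    if (unres[r1] + unres[r2] == 0L) next
    gi <- Gr[i, ]
    het <- gi == 1L
    if (!any(het)) next
    if (!any(het & (Cb[r1, ] == MISSING | Cb[r2, ] == MISSING))) next
    gi2 <- (gi == 2L) + 0
    gi0 <- (gi == 0L) + 0
    gin <- (gi != MISSING) + 0
    need <- min(min_overlap, sum(gin))
    for (side in 1:2) {
      set <- cands[[side]][[i]]
      if (!length(set)) next
      row <- if (side == 1) r1 else r2
      open <- het & Cb[row, ] == MISSING
      if (!any(open)) next
      confl <- G0[set, , drop = FALSE] %*% gi2 + G2[set, , drop = FALSE] %*% gi0
      ov <- Gn[set, , drop = FALSE] %*% gin
      ok <- confl == 0 & ov >= need
      if (!any(ok)) next
      S <- set[ok]
      v0 <- colSums(G0[S, , drop = FALSE])
      v1 <- colSums(G2[S, , drop = FALSE])
      Cb[row, open & v0 > 0 & v1 == 0] <- 0L
      Cb[row, open & v1 > 0 & v0 == 0] <- 1L
      # the other gamete follows by subtraction at heterozygous loci
      other <- if (side == 1) r2 else r1
      sub <- het & Cb[row, ] != MISSING & Cb[other, ] == MISSING
      Cb[other, sub] <- 1L - Cb[row, sub]
    }
  }

  # ---- haplotype library over this core ----------------------------------
  resolved <- Cb[rowSums(Cb == MISSING) == 0L, , drop = FALSE]
  if (nrow(resolved)) {
    lib_hap <- unique(resolved)
    Cb <- library_impute_all(Cb, seq_len(Lc),
                             list(hap = lib_hap, count = rep(1L, nrow(lib_hap))))
  }

  # ---- parent-restricted imputation --------------------------------------
  unres <- rowSums(Cb == MISSING)
  for (i in seq_len(n)) {
    for (side in 1:2) {
      p <- if (side == 1) sire_idx[i] else dam_idx[i]
      if (is.na(p)) next
      row <- 2L * (i - 1L) + side
      if (unres[row] == 0L) next
      pr1 <- 2L * p - 1L
      pr2 <- 2L * p
      if (unres[pr1] > 0L || unres[pr2] > 0L) next
      par_h <- Cb[c(pr1, pr2), , drop = FALSE]
      Cb[row, ] <- library_impute(Cb[row, ], NULL, restrict_to = par_h)
    }
  }
  Cb
}

#' Run the heuristic imputation stage
#'
#' Iterates (default 5 times): Mendelian-inheritance fill, long-range phasing
#' and haplotype-library imputation over every core tiling, cross-core
#' consensus, and the recombination sweep; ends with a single-locus
#' segregation analysis whose confident calls fill remaining alleles.
#'
#' @param genotypes n x M genotype matrix (0/1/2/9) aligned to the pedigree.
#' @param ped a [pedigree()].
#' @param config a [hybrid_config()].
#' @return list with `genotypes`, `phase`, `gamete_dosage` (recombination
#'   -interval dosages, NA elsewhere), `freq`, and `n_conflicts`.
#' @export
run_heuristics <- function(genotypes, ped, config = hybrid_config()) {
  n <- nrow(ped)
  M <- ncol(genotypes)
  mf <- mendelian_fill(genotypes, ped)
  G <- mf$genotypes
  P <- mf$phase
  n_conflicts <- mf$n_conflicts
  cands <- surrogate_candidates(ped)
  cands <- list(cands$paternal, cands$maternal)
  tilings <- build_cores(M, config$core_lengths)
  gdos <- matrix(NA_real_, nrow = 2L * n, ncol = M)
  pr <- pat_rows(n)
  mr <- mat_rows(n)

  sire_idx <- ped$sire_idx
  dam_idx <- ped$dam_idx
  for (it in seq_len(config$n_heuristic_iterations)) {
    calls <- vector("list", length(tilings))
    for (ti in seq_along(tilings)) {
      starts <- tilings[[ti]]$start
      ends <- tilings[[ti]]$end
      Ct <- P
      for (ci in seq_along(starts)) {
        rng <- starts[ci]:ends[ci]
        Ct[, rng] <- phase_core(G, Ct[, rng, drop = FALSE], sire_idx, dam_idx,
                                cands, rng, config$min_surrogate_overlap)
      }
      calls[[ti]] <- Ct
    }
    cons <- cross_core_consensus(calls)
    P <- enforce_genotype_consistency(cons, G)
    rs <- recombination_sweep(P, G, ped)
    P <- rs$phase
    gdos <- rs$gamete_dosage
    both <- P[pr, , drop = FALSE] != MISSING & P[mr, , drop = FALSE] != MISSING
    fill <- G == MISSING & both
    if (any(fill)) {
      sums <- P[pr, , drop = FALSE] + P[mr, , drop = FALSE]
      G[fill] <- sums[fill]
    }
    mf <- mendelian_fill(G, ped, P)
    G <- mf$genotypes
    P <- mf$phase
    n_conflicts <- n_conflicts + mf$n_conflicts
  }

  # final segregation analysis fills alleles that remain unimputed
  freq <- allele_frequencies(genotypes)
  probs <- segregation_probs(G, P, ped, freq)
  Pseg <- call_alleles(probs, config$call_threshold)
  fill <- P == MISSING & Pseg != MISSING
  P[fill] <- Pseg[fill]
  P <- enforce_genotype_consistency(P, G)
  both <- P[pr, , drop = FALSE] != MISSING & P[mr, , drop = FALSE] != MISSING
  fillg <- G == MISSING & both
  if (any(fillg)) {
    sums <- P[pr, , drop = FALSE] + P[mr, , drop = FALSE]
    G[fillg] <- sums[fillg]
  }
  list(genotypes = G, phase = P, gamete_dosage = gdos, freq = freq,
       n_conflicts = n_conflicts)
}
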