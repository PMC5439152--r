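# Long-range phasing with surrogate parents, haplotype-library imputation over
# multi-length cores, cross-core consensus and the recombination sweep.
#
# Marker intervals are 1-based and inclusive throughout ([start, end]).

#' Build core tilings
#'
#' For each core length L the chromosome is tiled into `ceiling(M / L)` cores,
#' the last one possibly shorter.  Each length is used twice, once anchored at
#' the first marker and once offset by half a core, so every allele is phased
#' as part of cores spanning different markers.  The default lengths are 10
#' values evenly log-spaced from 500 to 9000 markers, truncated to `M`.
#'
#' @param M marker count.
#' @param core_lengths integer vector of core lengths (each >= 2).
#' @param use_offsets also produce the half-core-offset tiling per length.
#' @return list of tilings; each tiling is a data.frame with columns
#'   `start`, `end` (1-based, inclusive).
#' @export
build_cores <- function(M, core_lengths = NULL, use_offsets = TRUE) {
  if (is.null(core_lengths)) {
    core_lengths <- unique(pmin(round(exp(seq(log(500), log(9000),
                                              length.out = 10))), M))
  }
  core_lengths <- unique(pmin(as.integer(core_lengths), M))
  stopifnot(all(core_lengths >= 2))
  tile <- function(L, offset) {
    breaks <- unique(c(0L, seq.int(offset, M, by = L), M))
    breaks <- sort(breaks[breaks >= 0 & breaks <= M])
    data.frame(start = head(breaks, -1) + 1L, end = breaks[-1])
  }
  out <- list()
  for (L in core_lengths) {
    out[[length(out) + 1L]] <- tile(L, 0L)
    off <- L %/% 2L
    if (use_offsets && off > 0L && off < M) {
      out[[length(out) + 1L]] <- tile(L, off)
    }
  }
  out
}

#' Count opposing homozygotes between two genotype rows
#'
#' Loci where one row is 0 and the other 2 — proof the two individuals share
#' no gamete there.  Missing and heterozygous loci never count.
#'
#' @param g1,g2 genotype rows (0/1/2/9) of equal length.
#' @param start,end 1-based inclusive marker range (defaults: whole row).
#' @return integer count.
#' @export
count_opposing_homozygotes <- function(g1, g2, start = 1L, end = length(g1)) {
  rng <- start:end
  a <- g1[rng]
  b <- g2[rng]
  sum((a == 0L & b == 2L) | (a == 2L & b == 0L))
}

# Pedigree-side surrogate candidates, computed once per pedigree: for each
# individual, the sire-side set is {sire, sire's parents, sire's other
# offspring, sire's sibs}; maternal analogously.
surrogate_candidates <- function(ped) {
  n <- nrow(ped)
  offspring <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(ped$sire_idx[i], ped$dam_idx[i])) {
      if (!is.na(p)) offspring[[p]] <- c(offspring[[p]], i)
    }
  }
  side_set <- function(i, p) {
    if (is.na(p)) return(integer(0))
    out <- c(p, ped$sire_idx[p], ped$dam_idx[p], offspring[[p]])
    for (gp in c(ped$sire_idx[p], ped$dam_idx[p])) {
      if (!is.na(gp)) out <- c(out, offspring[[gp]])
    }
    setdiff(unique(out[!is.na(out)]), i)
  }
  list(
    paternal = lapply(seq_len(n), function(i) side_set(i, ped$sire_idx[i])),
    maternal = lapply(seq_len(n), function(i) side_set(i, ped$dam_idx[i]))
  )
}

#' Find surrogate parents for a proband in a region
#'
#' Surrogates share a gamete with the proband, evidenced by zero opposing
#' homozygotes across the scanned region.  Candidates connected through the
#' sire side of the pedigree form the paternal set, through the dam side the
#' maternal set.  A minimum informative overlap (both individuals genotyped)
#' guards against spurious matches on sparse rows.
#'
#' @param proband row index (or id) of the proband.
#' @param genotypes n x M genotype matrix.
#' @param ped a [pedigree()].
#' @param start,end marker range.
#' @param min_overlap minimum informative overlap (default 50, capped at the
#'   number of typed proband loci in the region).
#' @param candidates optional precomputed [surrogate_candidates()] sets.
#' @return list with integer index vectors `paternal` and `maternal`.
#' @export
find_surrogates <- function(proband, genotypes, ped, start = 1L,
                            end = ncol(genotypes), min_overlap = 50L,
                            candidates = NULL) {
  if (is.character(proband)) proband <- match(proband, ped$id)
  cand <- candidates %||% surrogate_candidates(ped)
  rng <- start:end
  g <- genotypes[proband, rng]
  need <- min(min_overlap, sum(g != MISSING))
  admit <- function(set) {
    if (!length(set)) return(integer(0))
    Gc <- genotypes[set, rng, drop = FALSE]
    confl <- Gc == 0L & rep(g == 2L, each = length(set)) |
      Gc == 2L & rep(g == 0L, each = length(set))
    ov <- Gc != MISSING & rep(g != MISSING, each = length(set))
    set[rowSums(confl) == 0L & rowSums(ov) >= need]
  }
  list(paternal = admit(cand$paternal[[proband]]),
       maternal = admit(cand$maternal[[proband]]))
}

#' Phase one gamete of a proband by surrogate votes
#'
#' At each heterozygous proband locus, every surrogate that is homozygous
#' there votes for its allele; the allele is called only when all votes agree.
#' Homozygous proband loci are called directly.
#'
#' @param proband row index of the proband.
#' @param surrogates integer indices of the surrogate set for this gamete.
#' @param genotypes n x M genotype matrix.
#' @param start,end marker range.
#' @return integer vector over the region (0/1/9).
#' @export
phase_by_surrogates <- function(proband, surrogates, genotypes,
                                start = 1L, end = ncol(genotypes)) {
  rng <- start:end
  g <- genotypes[proband, rng]
  hap <- rep(MISSING, length(rng))
  hap[g == 0L] <- 0L
  hap[g == 2L] <- 1L
  if (length(surrogates)) {
    S <- genotypes[surrogates, rng, drop = FALSE]
    v0 <- colSums(S == 0L)
    v1 <- colSums(S == 2L)
    het <- g == 1L
    hap[het & v0 > 0L & v1 == 0L] <- 0L
    hap[het & v1 > 0L & v0 == 0L] <- 1L
  }
  hap
}

#' Build or update a haplotype library over cores
#'
#' For each core, every gamete fully resolved (no missing alleles) across the
#' core is inserted; duplicates merge with a count increment.  Updating an
#' existing library keeps previous counts and adds any new haplotype found.
#'
#' @param phase 2n x M phase matrix.
#' @param cores a single tiling from [build_cores()].
#' @param library optional existing library to update.
#' @return a `haplotype_library`: list with one element per core, each a list
#'   `hap` (matrix, one row per distinct haplotype) and `count`.
#' @export
build_library <- function(phase, cores, library = NULL) {
  out <- library %||% rep(list(list(hap = NULL, count = integer(0))),
                          nrow(cores))
  for (ci in seq_len(nrow(cores))) {
    rng <- cores$start[ci]:cores$end[ci]
    block <- phase[, rng, drop = FALSE]
    ok <- rowSums(block == MISSING) == 0L
    if (!any(ok)) next
    block <- block[ok, , drop = FALSE]
    key <- apply(block, 1, paste, collapse = "")
    tab <- table(key)
    ent <- out[[ci]]
    old_key <- if (is.null(ent$hap)) character(0) else
      apply(ent$hap, 1, paste, collapse = "")
    idx <- match(names(tab), old_key)
    hit <- !is.na(idx)
    if (any(hit)) ent$count[idx[hit]] <- ent$count[idx[hit]] + as.integer(tab[hit])
    if (any(!hit)) {
      new_rows <- block[match(names(tab)[!hit], key), , drop = FALSE]
      ent$hap <- rbind(ent$hap, new_rows)
      ent$count <- c(ent$count, as.integer(tab[!hit]))
    }
    out[[ci]] <- ent
  }
  class(out) <- "haplotype_library"
  out
}

#' Impute a partial gamete from a haplotype library core
#'
#' Library haplotypes matching the gamete's known alleles at every non-missing
#' position are the candidates (optionally restricted to a supplied candidate
#' matrix, e.g. parental gametes); a missing position is imputed only when all
#' candidates agree there.  With no candidate the gamete is unchanged.
#'
#' @param gamete partial haplotype over the core (0/1/9).
#' @param library_core one element of a `haplotype_library` (list `hap`,
#'   `count`), or `NULL`.
#' @param restrict_to optional matrix of allowed haplotypes (rows).
#' @return the (possibly) completed gamete.
#' @export
library_impute <- function(gamete, library_core, restrict_to = NULL) {
  hap <- if (!is.null(restrict_to)) restrict_to else library_core$hap
  if (is.null(hap) || nrow(hap) == 0L) return(gamete)
  known <- gamete != MISSING
  if (any(known)) {
    mism <- hap[, known, drop = FALSE] !=
      rep(gamete[known], each = nrow(hap))
    cand <- rowSums(mism) == 0L
  } else {
    cand <- rep(TRUE, nrow(hap))
  }
  if (!any(cand)) return(gamete)
  sub <- hap[cand, , drop = FALSE]
  agree <- colSums(sub) %in% c(0L, nrow(sub))
  fill <- !known & agree
  gamete[fill] <- sub[1, fill]
  gamete
}

# Batch library imputation for all gametes over one core; the candidate filter
# runs as two matrix products (mismatch counts against 0- and 1-alleles).
library_impute_all <- function(P, rng, library_core) {
  hap <- library_core$hap
  if (is.null(hap) || nrow(hap) == 0L) return(P[, rng, drop = FALSE])
  block <- P[, rng, drop = FALSE]
  B0 <- block == 0L
  B1 <- block == 1L
  storage.mode(B0) <- "double"
  storage.mode(B1) <- "double"
  H0 <- t(hap == 0L)
  H1 <- t(hap == 1L)
  storage.mode(H0) <- "double"
  storage.mode(H1) <- "double"
  mism <- B0 %*% H1 + B1 %*% H0 # gametes x library
  for (gi in which(rowSums(block == MISSING) > 0L)) {
    cand <- mism[gi, ] == 0
    if (!any(cand)) next
    sub <- hap[cand, , drop = FALSE]
    cs <- colSums(sub)
    agree <- cs == 0L | cs == nrow(sub)
    fill <- block[gi, ] == MISSING & agree
    if (any(fill)) block[gi, fill] <- sub[1, fill]
  }
  block
}

#' Cross-core consensus over tilings
#'
#' An allele is committed only if every tiling that produced a call at that
#' (gamete, marker) cell agrees; any disagreement leaves the cell missing.
#'
#' @param calls list of 2n x M call matrices (0/1/9), one per tiling.
#' @return 2n x M consensus matrix (0/1/9).
#' @export
cross_core_consensus <- function(calls) {
  stopifnot(length(calls) >= 1)
  lo <- matrix(2L, nrow = nrow(calls[[1]]), ncol = ncol(calls[[1]]))
  hi <- matrix(-1L, nrow = nrow(calls[[1]]), ncol = ncol(calls[[1]]))
  for (cm in calls) {
    known <- cm != MISSING
    lo[known] <- pmin(lo[known], cm[known])
    hi[known] <- pmax(hi[known], cm[known])
  }
  out <- matrix(MISSING, nrow = nrow(lo), ncol = ncol(lo))
  agreed <- hi >= 0L & lo == hi
  out[agreed] <- lo[agreed]
  out
}

# Keep a phase matrix consistent with observed genotypes: cells where both
# gametes are called and their sum contradicts a non-missing genotype are
# reset to missing.
enforce_genotype_consistency <- function(P, G) {
  n <- nrow(G)
  pr <- pat_rows(n)
  mr <- mat_rows(n)
  Pp <- P[pr, , drop = FALSE]
  Pm <- P[mr, , drop = FALSE]
  bad_pair <- Pp != MISSING & Pm != MISSING & G != MISSING & (Pp + Pm) != G
  # single-allele contradictions of a homozygous genotype
  bad_p <- Pp != MISSING & ((G == 0L & Pp == 1L) | (G == 2L & Pp == 0L))
  bad_m <- Pm != MISSING & ((G == 0L & Pm == 1L) | (G == 2L & Pm == 0L))
  Pp[bad_pair | bad_p] <- MISSING
  Pm[bad_pair | bad_m] <- MISSING
  P[pr, ] <- Pp
  P[mr, ] <- Pm
  P
}

#' Recombination sweep
#'
#' For each offspring gamete, assigns grand-parental origin at informative
#' loci (offspring allele matches exactly one parental gamete).  Between
#' consecutive informative loci with the same origin, alleles are copied from
#' the assigned parental gamete; a change of origin brackets a recombination
#' interval, inside which the gamete's allele dosage is the distance-weighted
#' (linear in marker index) average of the parent's two gamete alleles.  The
#' phase stays missing inside the interval so the HMM can refine those loci.
#'
#' @param phase 2n x M phase matrix.
#' @param genotypes n x M genotype matrix (consistency guard).
#' @param ped a [pedigree()].
#' @return list with the updated `phase` and `gamete_dosage` (2n x M, NA
#'   outside recombination intervals).
#' @export
recombination_sweep <- function(phase, genotypes, ped) {
  n <- nrow(ped)
  M <- ncol(phase)
  gdos <- matrix(NA_real_, nrow = 2L * n, ncol = M)
  for (i in seq_len(n)) {
    for (side in 1:2) {
      p <- if (side == 1) ped$sire_idx[i] else ped$dam_idx[i]
      if (is.na(p)) next
      row_off <- 2L * (i - 1L) + side
      off <- phase[row_off, ]
      par1 <- phase[2L * p - 1L, ]
      par2 <- phase[2L * p, ]
      inf <- off != MISSING & par1 != MISSING & par2 != MISSING &
        par1 != par2 & (off == par1 | off == par2)
      if (!any(inf)) next
      pos <- which(inf)
      orig <- ifelse(off[pos] == par1[pos], 1L, 2L)
      # fill within/outside constant-origin stretches
      blocks <- rle(orig)
      ends <- cumsum(blocks$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      new <- off
      for (b in seq_along(blocks$values)) {
        o <- blocks$values[b]
        lo <- if (b == 1) 1L else NA_integer_ # extended below
        left <- if (b == 1) 1L else pos[starts[b]]
        right <- if (b == length(blocks$values)) M else pos[ends[b]]
        src <- if (o == 1L) par1 else par2
        seg <- left:right
        fill <- seg[new[seg] == MISSING & src[seg] != MISSING]
        new[fill] <- src[fill]
      }
      # recombination intervals: consecutive informative loci with different
      # origins
      ch <- which(diff(orig) != 0L)
      for (b in ch) {
        i0 <- pos[b]
        i1 <- pos[b + 1L]
        if (i1 - i0 < 2L) next
        ks <- (i0 + 1L):(i1 - 1L)
        ks <- ks[off[ks] == MISSING & par1[ks] != MISSING & par2[ks] != MISSING]
        if (!length(ks)) next
        w_right <- (ks - i0) / (i1 - i0)
        aL <- if (orig[b] == 1L) par1[ks] else par2[ks]
        aR <- if (orig[b + 1L] == 1L) par1[ks] else par2[ks]
        gdos[row_off, ks] <- (1 - w_right) * aL + w_right * aR
        new[ks] <- MISSING
      }
      phase[row_off, ] <- new
    }
  }
  phase <- enforce_genotype_consistency(phase, genotypes)
  list(phase = phase, gamete_dosage = gdos)
}
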