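# Single-locus heuristics: Mendelian-inheritance rules applied to a fixed
# point, and an approximate single-locus segregation analysis (iterative
# peeling) that yields ordered-genotype probabilities per individual per locus.
#
# Ordered genotype pairs are indexed 1..4 = (0,0), (0,1), (1,0), (1,1) with the
# first element the paternal allele.

pat_rows <- function(n) seq.int(1L, 2L * n, by = 2L)
mat_rows <- function(n) seq.int(2L, 2L * n, by = 2L)

new_phase_matrix <- function(n, M) {
  matrix(MISSING, nrow = 2L * n, ncol = M)
}

#' Fill genotypes and phase by Mendelian-inheritance rules
#'
#' Applies, iteratively to a fixed point: (a) a homozygote has both gametes
#' equal to its allele; (b) a homozygous parent fixes the transmitted allele
#' of each offspring; (c) a heterozygote with one gamete known gets the other
#' by subtraction; (d) a missing genotype with both gametes known is their
#' sum; (e) a missing genotype is filled when both parents are homozygous.
#' Observed genotypes are never altered; a Mendelian conflict sets the
#' offending offspring genotype to missing and is counted, mirroring routine
#' quality control.
#'
#' @param genotypes n x M integer matrix coded 0/1/2/9, rows in pedigree order.
#' @param ped a [pedigree()].
#' @param phase optional 2n x M phase matrix (0/1/9) to start from.
#' @return list with elements `genotypes`, `phase` (2n x M) and `n_conflicts`.
#' @export
mendelian_fill <- function(genotypes, ped, phase = NULL) {
  n <- nrow(ped)
  M <- ncol(genotypes)
  G <- genotypes
  observed <- G != MISSING
  P <- phase %||% new_phase_matrix(n, M)
  pr <- pat_rows(n)
  mr <- mat_rows(n)
  si <- ped$sire_idx
  di <- ped$dam_idx
  n_conflicts <- 0L
  repeat {
    changed <- FALSE

    # conflict check: opposing homozygotes between parent and offspring, or a
    # phase pair contradicting an observed genotype
    for (side in 1:2) {
      pidx <- if (side == 1) si else di
      has <- which(!is.na(pidx))
      if (!length(has)) next
      pg <- G[pidx[has], , drop = FALSE]
      cg <- G[has, , drop = FALSE]
      confl <- (pg == 0L & cg == 2L) | (pg == 2L & cg == 0L)
      if (any(confl)) {
        n_conflicts <- n_conflicts + sum(confl)
        cg[confl] <- MISSING
        G[has, ] <- cg
        # wipe the phase of the reset loci as well
        Pp <- P[pr[has], , drop = FALSE]
        Pm <- P[mr[has], , drop = FALSE]
        Pp[confl] <- MISSING
        Pm[confl] <- MISSING
        P[pr[has], ] <- Pp
        P[mr[has], ] <- Pm
        observed[has, ][confl] <- FALSE
        changed <- TRUE
      }
    }

    Pp <- P[pr, , drop = FALSE]
    Pm <- P[mr, , drop = FALSE]

    # (a) homozygotes phase themselves
    upd <- G == 0L & Pp == MISSING
    if (any(upd)) { Pp[upd] <- 0L; changed <- TRUE }
    upd <- G == 0L & Pm == MISSING
    if (any(upd)) { Pm[upd] <- 0L; changed <- TRUE }
    upd <- G == 2L & Pp == MISSING
    if (any(upd)) { Pp[upd] <- 1L; changed <- TRUE }
    upd <- G == 2L & Pm == MISSING
    if (any(upd)) { Pm[upd] <- 1L; changed <- TRUE }

    # (b) homozygous parent fixes the transmitted gamete
    has <- which(!is.na(si))
    if (length(has)) {
      sg <- G[si[has], , drop = FALSE]
      tgt <- Pp[has, , drop = FALSE]
      upd <- sg == 0L & tgt == MISSING
      tgt[upd] <- 0L
      upd2 <- sg == 2L & tgt == MISSING
      tgt[upd2] <- 1L
      if (any(upd) || any(upd2)) { Pp[has, ] <- tgt; changed <- TRUE }
    }
    has <- which(!is.na(di))
    if (length(has)) {
      dg <- G[di[has], , drop = FALSE]
      tgt <- Pm[has, , drop = FALSE]
      upd <- dg == 0L & tgt == MISSING
      tgt[upd] <- 0L
      upd2 <- dg == 2L & tgt == MISSING
      tgt[upd2] <- 1L
      if (any(upd) || any(upd2)) { Pm[has, ] <- tgt; changed <- TRUE }
    }

    # (c) heterozygote with one gamete known: the other by subtraction
    upd <- G == 1L & Pp != MISSING & Pm == MISSING
    if (any(upd)) { Pm[upd] <- 1L - Pp[upd]; changed <- TRUE }
    upd <- G == 1L & Pm != MISSING & Pp == MISSING
    if (any(upd)) { Pp[upd] <- 1L - Pm[upd]; changed <- TRUE }

    # (d) missing genotype with both gametes known
    upd <- G == MISSING & Pp != MISSING & Pm != MISSING
    if (any(upd)) { G[upd] <- Pp[upd] + Pm[upd]; changed <- TRUE }

    # (e) missing genotype, both parents homozygous
    has <- which(!is.na(si) & !is.na(di))
    if (length(has)) {
      sg <- G[si[has], , drop = FALSE]
      dg <- G[di[has], , drop = FALSE]
      cg <- G[has, , drop = FALSE]
      upd <- cg == MISSING & (sg == 0L | sg == 2L) & (dg == 0L | dg == 2L)
      if (any(upd)) {
        cg[upd] <- (sg[upd] %/% 2L) + (dg[upd] %/% 2L)
        G[has, ] <- cg
        changed <- TRUE
      }
    }

    P[pr, ] <- Pp
    P[mr, ] <- Pm
    if (!changed) break
  }
  # never alter non-missing observed genotypes (conflict resets excepted)
  stopifnot(all(G[observed] == genotypes[observed]))
  list(genotypes = G, phase = P, n_conflicts = n_conflicts)
}

#' Allele frequencies from non-missing genotypes
#' @param genotypes n x M matrix coded 0/1/2/9.
#' @return numeric vector of allele-1 frequencies (0.5 where all missing).
#' @export
allele_frequencies <- function(genotypes) {
  Gna <- genotypes
  Gna[Gna == MISSING] <- NA_integer_
  f <- colMeans(Gna, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0.5
  f
}

# genotype likelihood over ordered pairs given genotype code and called phase;
# returns a 4 x M matrix of 0/1 indicators
pair_likelihood <- function(g, pp, pm) {
  M <- length(g)
  L <- matrix(1, nrow = 4, ncol = M)
  sums <- c(0L, 1L, 1L, 2L)
  pat <- c(0L, 0L, 1L, 1L)
  mat <- c(0L, 1L, 0L, 1L)
  for (j in 1:4) {
    L[j, ] <- (g == MISSING | g == sums[j]) *
      (pp == MISSING | pp == pat[j]) *
      (pm == MISSING | pm == mat[j])
  }
  L
}

#' Single-locus segregation analysis (iterative peeling)
#'
#' Computes, for each individual and locus, a probability distribution over
#' ordered allele pairs (0,0), (0,1), (1,0), (1,1) — the first element the
#' paternal allele — as the normalized product of the genotype likelihood,
#' per-gamete transmission priors from the parents (population frequency for
#' unknown parents) and an aggregated offspring term.  The pedigree is swept
#' down and up a fixed number of times; loops (inbreeding) make the scheme
#' approximate.
#'
#' @param genotypes n x M matrix coded 0/1/2/9.
#' @param phase 2n x M matrix of called alleles (0/1/9); constrains the pairs.
#' @param ped a [pedigree()].
#' @param allele_freq per-marker frequency of allele 1; computed from the
#'   genotypes when `NULL`.
#' @param n_sweeps number of down-up sweep pairs (default 2).
#' @return an array of dimension `c(4, n, M)` of normalized probabilities,
#'   class `ordered_genotype_probs`.
#' @export
segregation_probs <- function(genotypes, phase = NULL, ped,
                              allele_freq = NULL, n_sweeps = 2) {
  n <- nrow(ped)
  M <- ncol(genotypes)
  if (is.null(phase)) phase <- new_phase_matrix(n, M)
  freq <- allele_freq %||% allele_frequencies(genotypes)
  pr <- pat_rows(n)
  mr <- mat_rows(n)

  lik <- vector("list", n) # 4 x M per individual
  for (i in seq_len(n)) {
    lik[[i]] <- pair_likelihood(genotypes[i, ], phase[pr[i], ], phase[mr[i], ])
  }

  childterm <- vector("list", n) # aggregated offspring term, 4 x M
  msg_s <- vector("list", n)     # per-child factor sent to the sire
  msg_d <- vector("list", n)     # per-child factor sent to the dam
  ones <- matrix(1, 4, M)
  for (i in seq_len(n)) {
    childterm[[i]] <- ones
    msg_s[[i]] <- ones
    msg_d[[i]] <- ones
  }

  # marginal probability that an individual transmits allele 1, per locus,
  # from a belief excluding the message of the receiving child
  transmit1 <- function(b) {
    z <- pmax(colSums(b), .Machine$double.eps)
    (0.5 * (b[3, ] + b[4, ]) + 0.5 * (b[2, ] + b[4, ])) / z
  }

  prior_pair <- function(tp, tm) {
    rbind((1 - tp) * (1 - tm), (1 - tp) * tm, tp * (1 - tm), tp * tm)
  }

  # parent priors (anterior terms), updated each downward pass
  anterior <- vector("list", n)
  for (i in seq_len(n)) anterior[[i]] <- prior_pair(freq, freq)

  belief <- function(i) lik[[i]] * anterior[[i]] * childterm[[i]]

  belief_excluding <- function(p, fac) {
    b <- belief(p) / pmax(fac, 1e-12)
    b
  }

  for (sweep in seq_len(n_sweeps + 1L)) {
    # downward: anterior terms from parent transmissions, excluding the
    # child's own upward message (topological order)
    for (i in seq_len(n)) {
      si <- ped$sire_idx[i]
      di <- ped$dam_idx[i]
      tp <- if (is.na(si)) freq else transmit1(belief_excluding(si, msg_s[[i]]))
      tm <- if (is.na(di)) freq else transmit1(belief_excluding(di, msg_d[[i]]))
      anterior[[i]] <- prior_pair(tp, tm)
    }
    if (sweep > n_sweeps) break
    # upward: per-child messages to each parent (reverse order, so each
    # individual's fresh child messages are in place before it messages its
    # own parents); the previous sweep's terms back all belief look-ups so
    # an excluded message is always one the belief actually contains
    new_ct <- vector("list", n)
    for (i in seq_len(n)) new_ct[[i]] <- ones
    new_ms <- msg_s
    new_md <- msg_d
    for (i in rev(seq_len(n))) {
      si <- ped$sire_idx[i]
      di <- ped$dam_idx[i]
      if (is.na(si) && is.na(di)) next
      b <- lik[[i]] * new_ct[[i]]
      tp <- if (is.na(si)) freq else transmit1(belief_excluding(si, msg_s[[i]]))
      tm <- if (is.na(di)) freq else transmit1(belief_excluding(di, msg_d[[i]]))
      if (!is.na(si)) {
        # P(child data | sire transmits t), marginalizing the dam side
        m1 <- colSums(b * prior_pair(rep(1, M), tm))
        m0 <- colSums(b * prior_pair(rep(0, M), tm))
        z <- pmax(m0 + m1, .Machine$double.eps)
        m0 <- m0 / z
        m1 <- m1 / z
        fac <- rbind(m0, 0.5 * (m0 + m1), 0.5 * (m0 + m1), m1)
        new_ms[[i]] <- fac
        new_ct[[si]] <- new_ct[[si]] * fac
      }
      if (!is.na(di)) {
        m1 <- colSums(b * prior_pair(tp, rep(1, M)))
        m0 <- colSums(b * prior_pair(tp, rep(0, M)))
        z <- pmax(m0 + m1, .Machine$double.eps)
        m0 <- m0 / z
        m1 <- m1 / z
        fac <- rbind(m0, 0.5 * (m0 + m1), 0.5 * (m0 + m1), m1)
        new_md[[i]] <- fac
        new_ct[[di]] <- new_ct[[di]] * fac
      }
    }
    childterm <- new_ct
    msg_s <- new_ms
    msg_d <- new_md
    # renormalize child terms to avoid underflow
    for (i in seq_len(n)) {
      z <- pmax(colSums(childterm[[i]]), .Machine$double.eps)
      childterm[[i]] <- childterm[[i]] / rep(z, each = 4)
    }
  }

  q <- vector("list", n)
  for (i in seq_len(n)) {
    b <- belief(i)
    z <- colSums(b)
    bad <- z <= 0
    if (any(bad)) {
      # total conflict: reset to the genotype-consistent uniform
      b[, bad] <- lik[[i]][, bad, drop = FALSE]
      z[bad] <- pmax(colSums(b[, bad, drop = FALSE]), .Machine$double.eps)
    }
    q[[i]] <- b / rep(z, each = 4)
  }

  out <- array(0, dim = c(4, n, M))
  for (i in seq_len(n)) out[, i, ] <- q[[i]]
  class(out) <- "ordered_genotype_probs"
  out
}

#' Call alleles from ordered-genotype probabilities
#'
#' A gamete's allele is hard-called when its marginal probability reaches the
#' threshold (inclusive); otherwise it stays missing.  Because the
#' distributions are genotype-consistent, calls never contradict observed
#' genotypes.
#'
#' @param probs an `ordered_genotype_probs` array (4 x n x M).
#' @param threshold calling threshold in (0.5, 1]; default 0.99.
#' @return 2n x M phase matrix (0/1/9).
#' @export
call_alleles <- function(probs, threshold = 0.99) {
  stopifnot(threshold > 0.5)
  d <- dim(unclass(probs))
  n <- d[2]
  M <- d[3]
  p <- unclass(probs)
  pat1 <- p[3, , , drop = FALSE][1, , ] + p[4, , , drop = FALSE][1, , ]
  mat1 <- p[2, , , drop = FALSE][1, , ] + p[4, , , drop = FALSE][1, , ]
  pat1 <- matrix(pat1, n, M)
  mat1 <- matrix(mat1, n, M)
  P <- new_phase_matrix(n, M)
  Pp <- matrix(MISSING, n, M)
  Pm <- matrix(MISSING, n, M)
  Pp[pat1 >= threshold] <- 1L
  Pp[1 - pat1 >= threshold] <- 0L
  Pm[mat1 >= threshold] <- 1L
  Pm[1 - mat1 >= threshold] <- 0L
  P[pat_rows(n), ] <- Pp
  P[mat_rows(n), ] <- Pm
  P
}
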