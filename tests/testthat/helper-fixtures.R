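# Small in-code fixtures shared across tests.

trio_pedigree <- function() {
  pedigree(c("S", "D", "C"), c("0", "0", "S"), c("0", "0", "D"))
}

# genotype matrix aligned to a pedigree from a named list of rows
geno <- function(ped, ..., M = NULL) {
  rows <- list(...)
  M <- M %||% length(rows[[1]])
  G <- matrix(9L, nrow = nrow(ped), ncol = M, dimnames = list(ped$id, NULL))
  for (id in names(rows)) G[id, ] <- as.integer(rows[[id]])
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive ordered-genotype posterior for pedigrees of <= 6 members:
# founders draw two independent alleles at the population frequency; each
# parent transmits one of its two alleles with probability 1/2; the genotype
# likelihood is the 0/1 indicator of consistency with observations.
enumerate_posterior <- function(ped, G, freq, locus = 1) {
  n <- nrow(ped)
  stopifnot(n <= 6)
  pairs <- as.matrix(expand.grid(rep(list(1:4), n)))
  pat <- c(0L, 0L, 1L, 1L)
  mat <- c(0L, 1L, 0L, 1L)
  f <- freq[locus]
  pallele <- function(a) ifelse(a == 1L, f, 1 - f)
  w <- apply(pairs, 1, function(cfg) {
    p <- 1
    for (i in seq_len(n)) {
      ai <- pat[cfg[i]]
      bi <- mat[cfg[i]]
      g <- G[i, locus]
      if (g != 9L && ai + bi != g) return(0)
      si <- ped$sire_idx[i]
      di <- ped$dam_idx[i]
      p <- p * (if (is.na(si)) pallele(ai) else {
        sa <- pat[cfg[si]]; sb <- mat[cfg[si]]
        0.5 * (sa == ai) + 0.5 * (sb == ai)
      })
      p <- p * (if (is.na(di)) pallele(bi) else {
        da <- pat[cfg[di]]; db <- mat[cfg[di]]
        0.5 * (da == bi) + 0.5 * (db == bi)
      })
    }
    p
  })
  w <- w / sum(w)
  out <- matrix(0, n, 4)
  for (j in 1:4) out[, j] <- vapply(seq_len(n),
                                    function(i) sum(w[pairs[, i] == j]),
                                    numeric(1))
  out # n x 4, ordered pairs (0,0),(0,1),(1,0),(1,1)
}
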