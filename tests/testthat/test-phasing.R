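test_that("core tilings cover the chromosome without overlap", {
  tl <- build_cores(10, core_lengths = 4, use_offsets = FALSE)[[1]]
  expect_equal(tl$start, c(1L, 5L, 9L))
  expect_equal(tl$end, c(4L, 8L, 10L))

  tl2 <- build_cores(6, core_lengths = 6, use_offsets = FALSE)[[1]]
  expect_equal(nrow(tl2), 1L)
  expect_equal(c(tl2$start, tl2$end), c(1L, 6L))

  # every default tiling's core sizes sum to M
  for (t in build_cores(3129)) {
    expect_equal(sum(t$end - t$start + 1L), 3129L)
    expect_true(all(t$start <= t$end))
    expect_equal(t$start[-1], head(t$end, -1) + 1L)
  }
})

test_that("opposing-homozygote counts ignore 9s and heterozygotes", {
  expect_equal(count_opposing_homozygotes(c(0L, 2L, 1L, 9L), c(0L, 2L, 1L, 9L)), 0L)
  expect_equal(count_opposing_homozygotes(c(0L, 2L, 1L, 9L), c(2L, 0L, 1L, 0L)), 2L)
  expect_equal(count_opposing_homozygotes(rep(9L, 5), c(0L, 2L, 1L, 0L, 2L)), 0L)
})

test_that("surrogates are admitted by pedigree side and zero conflicts", {
  # sire S, dam D, proband C, half-sib H via the common sire
  ped <- pedigree(c("S", "D", "D2", "C", "H"),
                  c("0", "0", "0", "S", "S"),
                  c("0", "0", "0", "D", "D2"))
  M <- 8
  G <- geno(ped,
            S = c(0, 0, 2, 2, 1, 1, 0, 2),
            D = c(1, 1, 1, 1, 1, 1, 1, 1),
            D2 = rep(1, 8),
            C = c(0, 1, 2, 1, 1, 1, 0, 2),
            H = c(0, 0, 2, 2, 0, 1, 0, 2))
  s <- find_surrogates("C", G, ped, min_overlap = 3)
  expect_true(match("S", ped$id) %in% s$paternal)
  expect_true(match("H", ped$id) %in% s$paternal)

  # a single opposing homozygote excludes the sire
  G2 <- G
  G2[match("S", ped$id), 1] <- 2L
  s2 <- find_surrogates("C", G2, ped, min_overlap = 3)
  expect_false(match("S", ped$id) %in% s2$paternal)
})

test_that("surrogate votes follow the unanimity rule", {
  ped <- pedigree(c("S", "D", "C"), c("0", "0", "S"), c("0", "0", "D"))
  G <- geno(ped, S = c(0, 0, 2), D = c(1, 1, 1), C = c(1, 1, 2))
  # one homozygous surrogate forces the allele at a het locus
  hap <- phase_by_surrogates(3, match("S", ped$id), G)
  expect_equal(hap[1], 0L)
  # homozygous proband locus is called regardless of surrogates
  expect_equal(hap[3], 1L)
  # disagreeing votes leave the allele missing
  G2 <- geno(ped, S = c(0, 0, 0), D = c(2, 2, 2), C = c(1, 1, 1))
  hap2 <- phase_by_surrogates(3, c(1L, 2L), G2)
  expect_equal(hap2, rep(9L, 3))
})

test_that("haplotype libraries merge duplicates and skip unresolved gametes", {
  cores <- data.frame(start = 1L, end = 3L)
  P <- rbind(c(0L, 1L, 1L), c(0L, 1L, 1L), c(1L, 0L, 0L), c(0L, 9L, 1L))
  lib <- build_library(P, cores)
  expect_equal(nrow(lib[[1]]$hap), 2L)       # gamete with a 9 not inserted
  expect_equal(sum(lib[[1]]$count), 3L)      # counts conserve insertions
  # updating with new gametes increments and extends
  lib2 <- build_library(rbind(c(0L, 1L, 1L), c(1L, 1L, 1L)), cores, lib)
  expect_equal(sum(lib2[[1]]$count), 5L)
  expect_equal(nrow(lib2[[1]]$hap), 3L)
})

test_that("library imputation fills only unanimous candidate positions", {
  lib <- list(hap = rbind(c(0L, 1L, 1L), c(0L, 0L, 0L)), count = c(3L, 1L))
  expect_equal(library_impute(c(0L, 9L, 1L), lib), c(0L, 1L, 1L))
  lib2 <- list(hap = rbind(c(0L, 1L), c(1L, 0L)), count = c(1L, 1L))
  expect_equal(library_impute(c(9L, 9L), lib2), c(9L, 9L))
  expect_equal(library_impute(c(9L, 9L), list(hap = NULL, count = integer(0))),
               c(9L, 9L))
})

test_that("library imputation equals brute-force filter-and-intersect", {
  set.seed(11)
  for (rep in 1:25) {
    B <- sample(1:16, 1)
    Lc <- sample(2:8, 1)
    hap <- matrix(sample(0:1, B * Lc, TRUE), B, Lc)
    gam <- sample(c(0L, 1L, 9L), Lc, TRUE, prob = c(.3, .3, .4))
    got <- library_impute(gam, list(hap = hap, count = rep(1L, B)))
    # oracle: explicit filter then intersect
    keep <- apply(hap, 1, function(h) all(gam == 9L | h == gam))
    want <- gam
    if (any(keep)) {
      sub <- hap[keep, , drop = FALSE]
      for (j in seq_len(Lc)) {
        if (gam[j] == 9L && length(unique(sub[, j])) == 1L) {
          want[j] <- sub[1, j]
        }
      }
    }
    expect_identical(got, want)
  }
})

test_that("cross-core consensus commits only unanimous calls", {
  mk <- function(x) matrix(as.integer(x), 1)
  expect_equal(cross_core_consensus(rep(list(mk(1)), 10)), mk(1))
  expect_equal(cross_core_consensus(c(rep(list(mk(1)), 9), list(mk(0)))), mk(9))
  # a single call among 9s stands (vacuous agreement)
  expect_equal(cross_core_consensus(list(mk(9), mk(0), mk(9))), mk(0))
})

test_that("recombination sweep copies origins and interpolates intervals", {
  # parent P with two fully known distinct gametes; offspring O with an
  # origin switch between informative markers 11 and 21
  M <- 30
  ped <- pedigree(c("P", "D", "O"), c("0", "0", "P"), c("0", "0", "D"))
  P <- matrix(9L, 6, M)
  P[1, ] <- rep(0L, M)              # P paternal gamete
  P[2, ] <- rep(1L, M)              # P maternal gamete
  off <- rep(9L, M)
  off[5] <- 0L; off[11] <- 0L       # origin: gamete 1
  off[21] <- 1L; off[25] <- 1L      # origin: gamete 2
  P[5, ] <- off
  G <- matrix(9L, 3, M)
  r <- recombination_sweep(P, G, ped)
  # outside the interval, alleles copy from the assigned gamete
  expect_equal(r$phase[5, 1:11], rep(0L, 11))
  expect_equal(r$phase[5, 21:30], rep(1L, 10))
  # inside, dosage interpolates linearly and phase stays missing
  expect_equal(r$phase[5, 16], 9L)
  expect_equal(r$gamete_dosage[5, 16], 0.5)
  expect_equal(r$gamete_dosage[5, 13], 0.2) # (13-11)/(21-11) toward gamete 2
  # no interval when the origin never changes
  P2 <- P
  off2 <- rep(9L, M); off2[c(5, 25)] <- 0L
  P2[5, ] <- off2
  r2 <- recombination_sweep(P2, G, ped)
  expect_equal(r2$phase[5, ], rep(0L, M))
  expect_true(all(is.na(r2$gamete_dosage[5, ])))
})

test_that("no phasing operation contradicts an observed genotype", {
  set.seed(21)
  ped <- pedigree(paste0("I", 1:10),
                  c("0", "0", "I1", "I1", "I1", "0", "I3", "I3", "I5", "I5"),
                  c("0", "0", "I2", "I2", "I2", "0", "I6", "I6", "I6", "I4"))
  for (rep in 1:5) {
    G <- matrix(sample(c(0L, 1L, 2L, 9L), 10 * 40, TRUE,
                       prob = c(.35, .2, .35, .1)), 10, 40)
    h <- run_heuristics(G, ped, hybrid_config(core_lengths = c(10, 20),
                                              seed = rep))
    n <- 10
    Pp <- h$phase[seq(1, 2 * n, 2), ]
    Pm <- h$phase[seq(2, 2 * n, 2), ]
    both <- Pp != 9L & Pm != 9L & h$genotypes != 9L
    expect_true(all((Pp + Pm)[both] == h$genotypes[both]))
  }
})
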