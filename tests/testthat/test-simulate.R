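test_that("coalescent nucleotide diversity matches the constant-Ne closed form", {
  # E[pi] = 4 Ne mu L; average over replicates, assert within 3 SE
  set.seed(2)
  d <- sim_demography(length_bp = 5e4, mutation_rate = 1e-6,
                      recombination_rate = 0,
                      times = c(0, 1), sizes = c(500, 500))
  pis <- replicate(60, {
    r <- simulate_base_haplotypes(d, 6)
    H <- r$haplotypes
    if (ncol(H) == 0) return(0)
    cmb <- utils::combn(nrow(H), 2)
    mean(apply(cmb, 2, function(p) sum(H[p[1], ] != H[p[2], ])))
  })
  expected <- 4 * 500 * 1e-6 * 5e4
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se + 1e-9)
})

test_that("segregating sites are sorted, unique and polymorphic", {
  set.seed(5)
  d <- sim_demography(length_bp = 2e5, mutation_rate = 5e-7,
                      recombination_rate = 1e-7,
                      times = c(0, 100), sizes = c(200, 400))
  r <- simulate_base_haplotypes(d, 12)
  expect_false(is.unsorted(r$positions_bp, strictly = TRUE))
  counts <- colSums(r$haplotypes)
  expect_true(all(counts > 0 & counts < 12))
  expect_equal(r$positions_cM, r$positions_bp * d$rr * 100)
})

test_that("zero recombination yields a single genealogy (four-gamete test)", {
  set.seed(6)
  d <- sim_demography(length_bp = 5e4, mutation_rate = 1e-6,
                      recombination_rate = 0,
                      times = c(0, 1), sizes = c(300, 300))
  r <- simulate_base_haplotypes(d, 8)
  H <- r$haplotypes
  S <- ncol(H)
  if (S >= 2) {
    for (a in seq_len(min(S, 15))) {
      for (b in seq_len(min(S, 15))) {
        if (b <= a) next
        pats <- unique(paste(H[, a], H[, b]))
        expect_lt(length(pats), 4) # all four gametes would imply recombination
      }
    }
  }
})

test_that("site count grows with sequence length", {
  set.seed(7)
  d1 <- sim_demography(length_bp = 3e4, mutation_rate = 1e-6,
                       recombination_rate = 0, times = c(0, 1),
                       sizes = c(300, 300))
  d2 <- sim_demography(length_bp = 3e5, mutation_rate = 1e-6,
                       recombination_rate = 0, times = c(0, 1),
                       sizes = c(300, 300))
  s1 <- mean(replicate(5, ncol(simulate_base_haplotypes(d1, 6)$haplotypes)))
  s2 <- mean(replicate(5, ncol(simulate_base_haplotypes(d2, 6)$haplotypes)))
  expect_gt(s2, s1)
})

test_that("gene dropping transmits parental mosaics at the stated rate", {
  set.seed(8)
  S <- 50
  pool <- matrix(sample(0:1, 20 * S, TRUE), 20, S)
  pos <- seq(0, 100, length.out = S) # a 100 cM chromosome
  spec <- sim_pedigree_spec(n_sires = 2, n_dams = 4, n_progeny = 8,
                            n_generations = 2)
  r <- found_and_drop(pool, spec, pos)
  n <- nrow(r$ped)
  # child gamete alleles always come from one of the parent's gametes
  for (i in which(!is.na(r$ped$sire_idx))) {
    s <- r$ped$sire_idx[i]
    pat <- r$phase[2 * i - 1, ]
    expect_true(all(pat == r$phase[2 * s - 1, ] | pat == r$phase[2 * s, ]))
  }
  # a 0 cM map never recombines: child gametes equal one parental gamete
  r0 <- found_and_drop(pool, spec, rep(0, S))
  for (i in which(!is.na(r0$ped$dam_idx))) {
    d <- r0$ped$dam_idx[i]
    mat <- r0$phase[2 * i, ]
    expect_true(identical(mat, r0$phase[2 * d - 1, ]) ||
                  identical(mat, r0$phase[2 * d, ]))
  }
})

test_that("crossover counts average one per meiosis on a 100 cM chromosome", {
  set.seed(9)
  S <- 200
  pos <- seq(0, 100, length.out = S)
  # one distinguishable pair of parental gametes; count switch blocks
  g1 <- rep(0L, S)
  g2 <- rep(1L, S)
  pool <- rbind(g1, g2)
  spec <- sim_pedigree_spec(n_sires = 1, n_dams = 1, n_progeny = 2,
                            n_generations = 1)
  ncross <- replicate(600, {
    r <- found_and_drop(pool, spec, pos)
    ped <- r$ped
    i <- which(!is.na(ped$sire_idx))[1]
    gam <- r$phase[2 * i - 1, ]
    sum(diff(gam) != 0L)
  })
  # detected switches undercount slightly (founders may share a haplotype
  # here they never do, but double crossovers between markers can cancel)
  se <- sd(ncross) / sqrt(length(ncross))
  expect_lt(abs(mean(ncross) - 1.0), 3 * se + 0.05)
})

test_that("panels nest and mask the documented fractions", {
  set.seed(10)
  p <- make_panels(12000, 2000, c(L600 = 600, L15 = 15))
  expect_true(all(p$ld$L600 %in% seq_len(2000)))
  expect_equal(length(p$ld$L600), 600)
  # masking L600 from a 2000-marker panel removes 70% of markers
  expect_equal(1 - 600 / 2000, 0.7)
  expect_equal(1 - 600 / 10000, 0.94)
  expect_error(make_panels(1000, 2000, c(L15 = 15)), "segregating sites")

  G <- matrix(1L, 3, 2000)
  masked <- mask_genotypes(G, p$ld$L15, test_rows = c(1, 3))
  expect_equal(sum(masked[1, ] == 9L), 1985)
  expect_equal(sum(masked[2, ] == 9L), 0) # training rows untouched
  expect_identical(mask_genotypes(G, p$ld$L15, integer(0)), G)
})

test_that("pedigree-link removal founds exactly the selected individuals", {
  ped <- pedigree(c("A", "B", "C", "D"), c("0", "0", "A", "A"),
                  c("0", "0", "B", "B"))
  expect_identical(drop_pedigree_links(ped, character(0)), ped)
  ped2 <- drop_pedigree_links(ped, c("C", "D"))
  expect_true(all(is.na(ped2$sire[3:4])))
  expect_equal(sum(is.na(ped2$sire)) - sum(is.na(ped$sire)), 2)
})

test_that("simulated populations satisfy the truth invariants", {
  set.seed(12)
  pop <- simulate_population(
    seed = 3,
    demog = sim_demography(length_bp = 2e5, mutation_rate = 5e-7,
                           recombination_rate = 2.5e-7),
    spec = sim_pedigree_spec(2, 6, 12, 2),
    n_base_haplotypes = 30, hd_size = 40,
    ld_sizes = c(L30 = 5, L300 = 20), n_remove_links = 4)
  n <- nrow(pop$ped)
  expect_equal(pop$truth_geno,
               pop$truth_phase[seq(1, 2 * n, 2), ] +
                 pop$truth_phase[seq(2, 2 * n, 2), ],
               ignore_attr = TRUE)
  # masked entries are 9 exactly at non-panel markers of test individuals
  tr <- match(pop$test_ids, pop$ped$id)
  m <- pop$masked$L30
  expect_true(all(m[tr, pop$panels$ld$L30] != 9L |
                    pop$truth_geno[tr, pop$panels$ld$L30] == 9L))
  expect_true(all(m[tr, -pop$panels$ld$L30] == 9L))
  expect_identical(m[-tr, ], pop$truth_geno[-tr, ])
  expect_length(pop$removed_ids, 4)
  expect_true(all(pop$removed_ids %in% pop$test_ids))
})
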