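test_that("phased-individual counting uses the inclusive 99% rule", {
  M <- 100
  P <- matrix(0L, 4, M)
  # individual 1: both gametes complete; individual 2: one gamete 98%
  P[3, 1:2] <- 9L
  ph <- count_phased_gametes(P, fraction = 0.99)
  expect_true(ph$phased[1])
  expect_false(ph$phased[2])
  # exactly 99% resolved counts as phased (inclusive)
  P[3, ] <- 0L
  P[3, 1] <- 9L
  ph2 <- count_phased_gametes(P, fraction = 0.99)
  expect_true(ph2$phased[2])
})

test_that("training and imputation modes follow the thresholds", {
  cfg <- hybrid_config()
  cfg$heuristics_enabled <- FALSE
  expect_equal(select_training_mode(cfg, 0.9), 1L)
  cfg$heuristics_enabled <- TRUE
  expect_equal(select_training_mode(cfg, 0.8), 2L)
  expect_equal(select_training_mode(cfg, 0.3), 3L)
  # strict > at the threshold itself
  expect_equal(select_training_mode(cfg, 0.5), 3L)

  P <- matrix(0L, 2, 100)
  P[1, 1:5] <- 9L # 95% imputed
  expect_equal(select_imputation_mode(1, P, 0.9), 1L)
  P[1, 1:50] <- 9L
  expect_equal(select_imputation_mode(1, P, 0.9), 2L)
})

test_that("training sets respect per-individual exclusivity", {
  n <- 6
  M <- 40
  set.seed(2)
  G <- matrix(sample(c(0L, 1L, 2L), n * M, TRUE), n, M)
  P <- matrix(9L, 2 * n, M)
  # individuals 1-3 fully phased; 4-6 unphased but genotyped
  for (i in 1:3) {
    P[2 * i - 1, ] <- 0L
    P[2 * i, ] <- 1L
  }
  freq <- rep(0.5, M)
  cfg <- hybrid_config()
  ts2 <- build_training_set(2L, P, G, freq, cfg)
  expect_equal(nrow(ts2$pool), 6)
  expect_length(ts2$diploid_units, 0)
  ts3 <- build_training_set(3L, P, G, freq, cfg)
  # every individual enters exactly once (two gametes each)
  expect_equal(sort(unique(ts3$owner)), 1:6)
  expect_equal(as.vector(table(ts3$owner)), rep(2L, 6))
  # phased individuals enter as haplotypes, not as diploid units
  expect_setequal(ts3$diploid_units, 4:6)
  # a pool of fewer than 2 haplotypes is a configuration error
  expect_error(build_training_set(2L, matrix(9L, 2, M), G[1, , drop = FALSE],
                                  freq, cfg),
               "pool")
})

test_that("heuristic single-allele calls become emission constraints", {
  g <- c(9L, 9L, 1L, 9L)
  hp <- c(0L, 9L, 9L, 1L)
  hm <- c(9L, 9L, 9L, 9L)
  obs <- hybridimpute:::diploid_obs_row(g, hp, hm)
  expect_equal(obs, c(3L, 9L, 1L, 4L))
})

test_that("a fully observed population passes through unchanged", {
  set.seed(3)
  ped <- pedigree(paste0("I", 1:6),
                  c("0", "0", "I1", "I1", "I3", "I3"),
                  c("0", "0", "I2", "I2", "I4", "I4"))
  pool <- matrix(sample(0:1, 12 * 30, TRUE), 12, 30)
  dropped <- found_and_drop(pool, sim_pedigree_spec(1, 2, 4, 1),
                            seq(0, 10, length.out = 30))
  G <- dropped$phase[seq(1, 2 * nrow(dropped$ped), 2), ] +
    dropped$phase[seq(2, 2 * nrow(dropped$ped), 2), ]
  storage.mode(G) <- "integer"
  res <- run_hybrid(dropped$ped, G,
                    config = hybrid_config(core_lengths = c(10, 30), seed = 1))
  expect_identical(res$genotypes, G)
  expect_equal(res$dosages, G, ignore_attr = TRUE)
  n <- nrow(G)
  pr <- seq(1, 2 * n, 2)
  mr <- seq(2, 2 * n, 2)
  expect_true(all(res$provenance %in% c("observed", "heuristic", "hmm")))
  hom <- G == 0L | G == 2L
  expect_true(all(res$provenance[pr, ][hom] == "observed"))
  expect_true(all(res$provenance[mr, ][hom] == "observed"))
})

test_that("hybrid runs are deterministic given the seed and complete", {
  set.seed(4)
  pop <- simulate_population(
    seed = 21,
    demog = sim_demography(length_bp = 3e5, mutation_rate = 4e-7,
                           recombination_rate = 2.5e-7),
    spec = sim_pedigree_spec(2, 6, 12, 3),
    n_base_haplotypes = 40, hd_size = 60,
    ld_sizes = c(L30 = 8), n_remove_links = 6)
  ped <- drop_pedigree_links(pop$ped, pop$removed_ids)
  cfg <- hybrid_config(n_templates = 20, n_iterations = 6, burn_in = 2,
                       core_lengths = c(15, 30), seed = 7)
  r1 <- run_hybrid(ped, pop$masked$L30, config = cfg)
  r2 <- run_hybrid(ped, pop$masked$L30, config = cfg)
  expect_identical(r1$dosages, r2$dosages)
  expect_identical(r1$phase, r2$phase)
  # output completeness: no missing dosage, all dosages in [0, 2]
  expect_false(anyNA(r1$dosages))
  expect_true(all(r1$dosages >= 0 & r1$dosages <= 2))
  expect_false(any(r1$genotypes == 9L))
  # observed genotypes are retained verbatim
  obs <- pop$masked$L30 != 9L
  expect_true(all(r1$genotypes[obs] == pop$masked$L30[obs]))
  # provenance partitions all cells
  expect_true(all(r1$provenance %in% c("observed", "heuristic", "hmm")))
})

test_that("disabling the HMM reproduces heuristic-only output conventions", {
  set.seed(5)
  pop <- simulate_population(
    seed = 22,
    demog = sim_demography(length_bp = 3e5, mutation_rate = 4e-7,
                           recombination_rate = 2.5e-7),
    spec = sim_pedigree_spec(2, 6, 12, 3),
    n_base_haplotypes = 40, hd_size = 60,
    ld_sizes = c(L30 = 8), n_remove_links = 6)
  ped <- drop_pedigree_links(pop$ped, pop$removed_ids)
  res <- run_hybrid(ped, pop$masked$L30,
                    config = hybrid_config(hmm_enabled = FALSE,
                                           core_lengths = c(15, 30), seed = 1))
  # unimputed genotypes stay 9; their dosage defaults to 2 x frequency
  rem <- match(pop$removed_ids, pop$ped$id)
  expect_true(any(res$genotypes[rem, ] == 9L))
  i <- rem[1]
  js <- which(res$genotypes[i, ] == 9L &
                res$phase[2 * i - 1, ] == 9L & res$phase[2 * i, ] == 9L &
                is.na(res$allele_probs[2 * i - 1, ]) == FALSE)
  js <- js[abs(res$allele_probs[2 * i - 1, js] -
                 res$allele_freq[js]) < 1e-12]
  expect_gt(length(js), 0)
  expect_equal(res$dosages[i, js[1]], 2 * res$allele_freq[js[1]])
})

test_that("disabling heuristics reduces the run to a pure diploid HMM", {
  set.seed(6)
  n <- 8
  M <- 40
  ped <- pedigree(paste0("U", 1:n), rep("0", n), rep("0", n))
  pool <- matrix(sample(0:1, 16 * M, TRUE), 16, M)
  P <- pool[sample(16, 2 * n, TRUE), ]
  G <- P[seq(1, 2 * n, 2), ] + P[seq(2, 2 * n, 2), ]
  storage.mode(G) <- "integer"
  G[1, sample(M, 20)] <- 9L
  cfg <- hybrid_config(heuristics_enabled = FALSE, n_templates = 8,
                       n_iterations = 4, burn_in = 1, seed = 3)
  res <- run_hybrid(ped, G, config = cfg)
  expect_equal(res$training_mode, 1L)
  expect_false(anyNA(res$dosages))
  # observed homozygous cells carry observed provenance, the rest HMM-side
  hom <- G == 0L | G == 2L
  expect_true(all(res$provenance[seq(1, 2 * n, 2), ][hom] == "observed"))
  expect_true(all(res$provenance[seq(2, 2 * n, 2), ][hom] == "observed"))
})
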