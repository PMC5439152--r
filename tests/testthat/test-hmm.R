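test_that("parameters initialize at 0.01 and require two markers", {
  p <- init_params(5)
  expect_equal(p$theta, rep(0.01, 4))
  expect_equal(p$eps, rep(0.01, 5))
  expect_length(init_params(2)$theta, 1)
  expect_error(init_params(1))
})

test_that("transition weights follow the stay/jump mosaic and sum to one", {
  expect_equal(transition_weight(0, TRUE, 10), 1)
  expect_equal(transition_weight(0, FALSE, 10), 0)
  expect_equal(transition_weight(1, TRUE, 4), 0.25)
  expect_equal(transition_weight(1, FALSE, 4), 0.25)
  expect_equal(transition_weight(0.01, TRUE, 100), 0.9901)
  expect_equal(transition_weight(0.01, FALSE, 100), 1e-4)
  # row sum: stay + (H-1) specific switches
  for (th in c(0, 0.01, 0.3, 1)) {
    expect_equal(transition_weight(th, TRUE, 7) +
                   6 * transition_weight(th, FALSE, 7), 1)
  }
})

test_that("emissions behave at limits and sum to one over genotypes", {
  expect_equal(emission_haploid(0L, 0L, 0), 1)
  expect_equal(emission_haploid(0L, 1L, 0.01), 0.01)
  expect_equal(emission_haploid(9L, 0L, 0.3), 1)
  expect_equal(emission_haploid(9L, 1L, 0.3), 1)

  expect_equal(emission_diploid(1L, c(0L, 1L), 0), 1)
  expect_equal(emission_diploid(2L, c(0L, 0L), 0), 0)
  probs <- vapply(0:2, emission_diploid, numeric(1),
                  template_alleles = c(0L, 0L), eps_i = 0.1)
  expect_equal(probs, c(0.81, 0.18, 0.01))
  expect_equal(sum(probs), 1)
  # constrained codes are sums of compatible genotype emissions
  expect_equal(emission_diploid(3L, c(0L, 0L), 0.1), 0.81 + 0.18)
  expect_equal(emission_diploid(4L, c(0L, 0L), 0.1), 0.18 + 0.01)
})

test_that("haploid forward-backward equals the exhaustive path sum", {
  set.seed(5)
  for (rep in 1:10) {
    nH <- sample(2:3, 1)
    M <- sample(3:4, 1)
    H <- matrix(sample(0:1, nH * M, TRUE), nH, M)
    obs <- sample(c(0L, 1L, 9L), M, TRUE)
    p <- init_params(M)
    p$theta <- runif(M - 1, 0, 0.5)
    p$eps <- runif(M, 0.01, 0.3)
    got <- forward_backward_haploid(obs, H, p)
    want <- brute_haploid(obs, H, p$theta, p$eps)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_lt(max(abs(got$posteriors - want$post)), 1e-10)
    expect_true(all(abs(rowSums(got$posteriors) - 1) < 1e-9))
  }
})

test_that("haploid limits: uniform prior at M = 1-like and template lock", {
  H <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L))
  p <- init_params(3)
  # all-missing observations: posterior stays uniform
  r <- forward_backward_haploid(c(9L, 9L, 9L), H, p)
  expect_equal(unname(r$posteriors), matrix(0.5, 3, 2), tolerance = 1e-9)
  expect_equal(r$loglik, 0, tolerance = 1e-9)
  # eps, theta -> 0 with obs equal to a template: mass locks on it
  p$theta[] <- 1e-9
  p$eps[] <- 1e-9
  r2 <- forward_backward_haploid(c(1L, 1L, 1L), H, p)
  expect_true(all(r2$posteriors[, 2] > 1 - 1e-6))
})

test_that("diploid factorized likelihood equals the dense oracle", {
  set.seed(6)
  for (rep in 1:10) {
    nH <- sample(2:4, 1)
    M <- sample(3:6, 1)
    H <- matrix(sample(0:1, nH * M, TRUE), nH, M)
    obs <- sample(c(0L, 1L, 2L, 9L, 3L, 4L), M, TRUE)
    p <- init_params(M)
    p$theta <- runif(M - 1, 0, 0.5)
    p$eps <- runif(M, 0.01, 0.3)
    got <- forward_backward_diploid(obs, H, p)
    want <- dense_diploid_loglik(obs, H, p$theta, p$eps)
    expect_equal(got$loglik, want, tolerance = 1e-10)
    expect_true(all(abs(rowSums(got$posteriors) - 1) < 1e-9))
  }
})

test_that("sampled paths are deterministic under a seed and constant at theta=0", {
  H <- rbind(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L), c(0L, 0L, 1L, 1L))
  p <- init_params(4)
  p$theta[] <- 0
  obs <- c(9L, 9L, 9L, 9L)
  set.seed(1)
  s1 <- sample_path_haploid(obs, H, p)
  expect_equal(length(unique(s1$path)), 1L)
  expect_equal(sum(s1$jumps), 0L)
  set.seed(1)
  s2 <- sample_path_haploid(obs, H, p)
  expect_identical(s1$path, s2$path)

  set.seed(2)
  d1 <- sample_path_diploid(c(1L, 9L, 1L, 9L), H, p)
  set.seed(2)
  d2 <- sample_path_diploid(c(1L, 9L, 1L, 9L), H, p)
  expect_identical(d1$path1, d2$path1)
  expect_identical(d1$path2, d2$path2)
})

test_that("haploid sampling matches the enumerated path posterior", {
  # |H| = 2, M = 2: four paths, exact posterior by enumeration
  H <- rbind(c(0L, 1L), c(1L, 0L))
  p <- init_params(2)
  p$theta <- 0.3
  p$eps <- c(0.1, 0.2)
  obs <- c(0L, 0L)
  want <- brute_haploid(obs, H, p$theta, p$eps)
  # enumerate joint path probabilities
  em <- function(o, t, e) if (o == t) 1 - e else e
  joint <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    joint[a, b] <- 0.5 * em(obs[1], H[a, 1], p$eps[1]) *
      transition_weight(p$theta, a == b, 2) * em(obs[2], H[b, 2], p$eps[2])
  }
  joint <- joint / sum(joint)
  set.seed(8)
  n <- 20000
  counts <- matrix(0, 2, 2)
  for (i in seq_len(n)) {
    s <- sample_path_haploid(obs, H, p)
    counts[s$path[1], s$path[2]] <- counts[s$path[1], s$path[2]] + 1
  }
  expect_gt(stats::chisq.test(as.vector(counts),
                              p = as.vector(joint))$p.value, 1e-3)
})

test_that("initial guesses respect genotypes and frequencies", {
  expect_equal(initial_guess(c(2L, 0L), c(0.5, 0.5)),
               rbind(c(1L, 0L), c(1L, 0L)))
  set.seed(4)
  h <- initial_guess(c(1L), 0.5)
  expect_equal(sort(h[, 1]), c(0L, 1L))
  # degenerate frequency: missing draws are forced
  expect_equal(initial_guess(c(9L), 1.0)[, 1], c(1L, 1L))
  expect_equal(initial_guess(c(9L), 0.0)[, 1], c(0L, 0L))
})

test_that("parameter updates use Laplace smoothing and clamping", {
  M <- 3
  counts <- list(jumps = c(0, 0), transits = c(98, 98),
                 mismatches = c(0, 0, 0), comparisons = c(0, 0, 0))
  p <- update_params(counts, init_params(M))
  expect_equal(p$theta, rep(1 / 100, 2))
  # vacuous counts push eps to the 0.5 clamp boundary
  expect_equal(p$eps, rep(0.5, 3))
})

test_that("iterated updates recover generating parameters within 20%", {
  set.seed(14)
  M <- 60
  nH <- 20
  theta_true <- 0.05
  eps_true <- 0.02
  H <- matrix(sample(0:1, nH * M, TRUE), nH, M)
  n_gam <- 2000
  # simulate gametes from the model
  obs <- matrix(0L, n_gam, M)
  for (g in seq_len(n_gam)) {
    h <- sample.int(nH, 1)
    for (i in seq_len(M)) {
      if (i > 1 && runif(1) < theta_true) h <- sample.int(nH, 1)
      a <- H[h, i]
      if (runif(1) < eps_true) a <- 1L - a
      obs[g, i] <- a
    }
  }
  p <- init_params(M)
  for (it in 1:5) {
    counts <- hybridimpute:::new_hmm_counts(M)
    for (g in seq_len(n_gam)) {
      s <- sample_path_haploid(obs[g, ], H, p)
      counts <- hybridimpute:::add_hap_counts(counts, s$jumps, s$alleles,
                                              obs[g, ])
    }
    p <- update_params(counts, p)
  }
  expect_lt(abs(mean(p$theta) - theta_true) / theta_true, 0.2)
  expect_lt(abs(mean(p$eps) - eps_true) / eps_true, 0.2)
})

test_that("consensus pairs minimize switch disagreement with the samples", {
  # identical iterations reproduce themselves
  pair <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L))
  expect_equal(consensus_pair(list(pair, pair, pair)), pair)
  # pairs differing only by a global swap give either ordering
  sw <- pair[2:1, ]
  cons <- consensus_pair(list(pair, sw, pair))
  expect_true(identical(cons, pair) || identical(cons, sw))

  # exhaustive switch-error oracle on <= 4 heterozygous sites
  switch_cost <- function(h1, samples) {
    het <- which(h1 + (1L - h1) == 1L) # all sites het here by construction
    tot <- 0
    for (s in samples) {
      for (j in seq_len(length(het) - 1)) {
        o_cons <- h1[het[j]] == h1[het[j + 1]]
        o_s <- s[1, het[j]] == s[1, het[j + 1]]
        tot <- tot + (o_cons != o_s)
      }
    }
    unname(tot)
  }
  set.seed(31)
  for (rep in 1:10) {
    Msites <- sample(2:4, 1)
    samples <- replicate(3, {
      top <- sample(0:1, Msites, TRUE)
      rbind(top, 1L - top)
    }, simplify = FALSE)
    cons <- consensus_pair(samples)
    got <- switch_cost(cons[1, ], samples)
    best <- min(vapply(0:(2^Msites - 1), function(mask) {
      top <- as.integer(intToBits(mask))[1:Msites]
      switch_cost(top, samples)
    }, numeric(1)))
    expect_equal(got, best)
  }
})

test_that("theta,eps -> 0 limit reproduces an observed template exactly", {
  set.seed(12)
  M <- 12
  H <- matrix(sample(0:1, 6 * M, TRUE), 6, M)
  p <- init_params(M)
  p$theta[] <- 1e-9
  p$eps[] <- 1e-9
  obs <- H[3, ]
  set.seed(99)
  pairs <- replicate(5, {
    s <- sample_path_haploid(obs, H, p)
    rbind(s$alleles, s$alleles)
  }, simplify = FALSE)
  cons <- consensus_pair(pairs)
  expect_equal(cons[1, ], H[3, ])
})
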