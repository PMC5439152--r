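# MaCH-style Li-Stephens HMM: parameters, transition/emission primitives,
# forward-backward wrappers (compiled kernels), mosaic sampling, parameter
# re-estimation and the switch-error-minimizing consensus pair.

#' Initialize HMM parameters
#'
#' Crossover parameters (one per marker interval) and error parameters (one
#' per marker) all start at 0.01 and are re-estimated each iteration.
#'
#' @param M marker count (>= 2).
#' @return list with numeric vectors `theta` (length M - 1) and `eps`
#'   (length M), class `hmm_params`.
#' @export
init_params <- function(M) {
  if (M < 2) stop("the HMM needs at least 2 markers")
  structure(list(theta = rep(0.01, M - 1L), eps = rep(0.01, M)),
            class = "hmm_params")
}

#' Per-gamete Li-Stephens transition weight
#'
#' Staying on the current template has weight `(1 - theta) + theta / H_size`;
#' switching to one specific other template has weight `theta / H_size`.
#' Diploid transitions are products of the two gametes' weights.
#'
#' @param theta_i crossover parameter for the interval.
#' @param same logical: transition to the same template?
#' @param H_size number of template haplotypes.
#' @return transition probability.
#' @export
transition_weight <- function(theta_i, same, H_size) {
  ifelse(same, (1 - theta_i) + theta_i / H_size, theta_i / H_size)
}

#' Haploid emission probability
#' @param observed_allele 0, 1 or 9 (missing).
#' @param template_allele 0 or 1.
#' @param eps_i per-marker error parameter.
#' @return `1 - eps_i` on match, `eps_i` on mismatch, 1 when missing.
#' @export
emission_haploid <- function(observed_allele, template_allele, eps_i) {
  ifelse(observed_allele == MISSING, 1,
         ifelse(observed_allele == template_allele, 1 - eps_i, eps_i))
}

#' Diploid emission probability
#'
#' Each template allele is read with independent flip probability `eps_i`;
#' the emission is the probability that the two error-prone reads sum to the
#' observed genotype.  Codes 3 and 4 denote partially constrained genotypes
#' (in `{0,1}` and `{1,2}` respectively); 9 is uninformative.
#'
#' @param observed_genotype 0, 1, 2, 9, or the constraint codes 3/4.
#' @param template_alleles length-2 vector of template alleles.
#' @param eps_i per-marker error parameter.
#' @return emission probability.
#' @export
emission_diploid <- function(observed_genotype, template_alleles, eps_i) {
  qa1 <- ifelse(template_alleles[1] == 1, 1 - eps_i, eps_i)
  qb1 <- ifelse(template_alleles[2] == 1, 1 - eps_i, eps_i)
  p <- c((1 - qa1) * (1 - qb1),
         qa1 * (1 - qb1) + (1 - qa1) * qb1,
         qa1 * qb1)
  switch(as.character(observed_genotype),
         "0" = p[1], "1" = p[2], "2" = p[3],
         "3" = p[1] + p[2], "4" = p[2] + p[3], 1)
}

#' Haploid forward-backward
#'
#' Uniform prior over templates at the first marker; factorized transitions
#' make each step O(|H|).  Per-marker posteriors sum to 1 and the scaling
#' constants accumulate to the log-likelihood.
#'
#' @param obs partial haplotype (0/1/9), length M.
#' @param templates |H| x M matrix of template haplotypes (0/1).
#' @param params an [init_params()] object.
#' @return list with `posteriors` (M x |H|) and `loglik`.
#' @export
forward_backward_haploid <- function(obs, templates, params) {
  fb_haploid_full(as.integer(obs), templates, params$theta, params$eps)
}

#' Diploid forward-backward
#'
#' Same contract over ordered template pairs; a transition step costs
#' O(|H|^2) rather than the dense O(|H|^4) by collapsing the per-gamete
#' stay/jump structure.
#'
#' @param obs genotype row (0/1/2/9 and constraint codes 3/4), length M.
#' @param templates |H| x M matrix.
#' @param params an [init_params()] object.
#' @return list with `posteriors` (M x |H|^2, pair (h, k) in column
#'   `(h - 1) * |H| + k`) and `loglik`.
#' @export
forward_backward_diploid <- function(obs, templates, params) {
  fb_diploid_full(as.integer(obs), templates, params$theta, params$eps)
}

#' Sample a mosaic path (haploid)
#'
#' Backward stochastic traceback from the filtered distributions; at each
#' interval the jump indicator is sampled from its conditional probability
#' given the two flanking states, so jumps that land on the same template are
#' counted as recombinations.
#'
#' @inheritParams forward_backward_haploid
#' @return list with `path` (1-based template indices), `jumps` (0/1 per
#'   interval), `alleles`, `p1` (posterior allele-1 probabilities), `loglik`.
#' @export
sample_path_haploid <- function(obs, templates, params) {
  r <- hmm_sample_haploid(as.integer(obs), templates, params$theta, params$eps)
  r$path <- r$path + 1L
  r
}

#' Sample a mosaic pair (diploid)
#' @inheritParams forward_backward_diploid
#' @return list with `path1`/`path2`, `jumps1`/`jumps2`, `alleles1`/
#'   `alleles2`, `p1`/`p2`, `loglik`.
#' @export
sample_path_diploid <- function(obs, templates, params) {
  r <- hmm_sample_diploid(as.integer(obs), templates, params$theta, params$eps)
  r$path1 <- r$path1 + 1L
  r$path2 <- r$path2 + 1L
  r
}

#' Initial haplotype guess for an individual
#'
#' Homozygous markers fix both alleles; heterozygous markers are phased
#' randomly; missing markers draw two independent alleles at the population
#' frequency.
#'
#' @param obs genotype row (0/1/2/9).
#' @param allele_freq per-marker allele-1 frequencies.
#' @return 2 x M integer matrix of alleles.
#' @export
initial_guess <- function(obs, allele_freq) {
  M <- length(obs)
  h <- matrix(0L, 2, M)
  h[, obs == 2L] <- 1L
  het <- which(obs == 1L)
  if (length(het)) {
    top <- rbinom(length(het), 1L, 0.5)
    h[1, het] <- top
    h[2, het] <- 1L - top
  }
  mis <- which(obs == MISSING)
  if (length(mis)) {
    h[1, mis] <- rbinom(length(mis), 1L, allele_freq[mis])
    h[2, mis] <- rbinom(length(mis), 1L, allele_freq[mis])
  }
  h
}

# Zeroed count accumulator for parameter re-estimation.
new_hmm_counts <- function(M) {
  list(jumps = numeric(M - 1L), transits = numeric(M - 1L),
       mismatches = numeric(M), comparisons = numeric(M))
}

# Add one sampled gamete's contribution: jump indicators and allele agreement
# with the observed (non-missing) alleles.
add_hap_counts <- function(counts, jumps, sampled_alleles, obs_alleles) {
  counts$jumps <- counts$jumps + jumps
  counts$transits <- counts$transits + 1
  known <- obs_alleles != MISSING
  counts$mismatches <- counts$mismatches +
    known * (sampled_alleles != obs_alleles)
  counts$comparisons <- counts$comparisons + known
  counts
}

# Diploid contribution: genotype-level agreement (|sampled - observed| allele
# mismatches out of 2 comparisons per non-missing marker).
add_dip_counts <- function(counts, jumps1, jumps2, g_sampled, g_obs) {
  counts$jumps <- counts$jumps + jumps1 + jumps2
  counts$transits <- counts$transits + 2
  known <- g_obs %in% c(0L, 1L, 2L)
  counts$mismatches <- counts$mismatches + known * abs(g_sampled - g_obs)
  counts$comparisons <- counts$comparisons + 2 * known
  counts
}

#' Re-estimate HMM parameters from sampled mosaics
#'
#' Crossover parameters are updated from the sampled jump events per interval,
#' error parameters from disagreements between sampled template alleles and
#' observed alleles, both with Laplace (+1 / +2) smoothing and clamped to
#' `[1e-6, 0.5]`.
#'
#' @param counts accumulated counts (internal structure produced during an
#'   iteration: `jumps`, `transits`, `mismatches`, `comparisons`).
#' @param params current `hmm_params` (carried for sizes).
#' @return updated `hmm_params`.
#' @export
update_params <- function(counts, params) {
  theta <- (counts$jumps + 1) / (counts$transits + 2)
  eps <- (counts$mismatches + 1) / (counts$comparisons + 2)
  params$theta <- pmin(pmax(theta, 1e-6), 0.5)
  params$eps <- pmin(pmax(eps, 1e-6), 0.5)
  params
}

#' Consensus pair of haplotypes across sampled iterations
#'
#' The consensus genotype at each locus is the majority sampled genotype; at
#' heterozygous consensus sites the relative phase of each pair of consecutive
#' sites is the majority relative orientation across iterations, which
#' minimizes the total switch disagreement with the sampled pairs (each
#' interval is independent).  Gamete 1 is reported as the lexicographically
#' smaller haplotype.
#'
#' @param pairs list of 2 x M integer matrices (sampled haplotype pairs).
#' @return 2 x M integer consensus pair.
#' @export
consensus_pair <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  M <- ncol(pairs[[1]])
  G <- vapply(pairs, function(p) p[1, ] + p[2, ], numeric(M))
  G <- matrix(G, nrow = M)
  gcons <- apply(G, 1, function(g) {
    tab <- tabulate(g + 1L, nbins = 3L)
    which.max(tab) - 1L # ties resolved toward the smaller genotype
  })
  h <- matrix(0L, 2, M)
  h[, gcons == 2L] <- 1L
  het <- which(gcons == 1L)
  if (length(het) >= 1) {
    phi <- integer(length(het))
    if (length(het) >= 2) {
      for (j in seq_len(length(het) - 1L)) {
        s <- het[j]
        t <- het[j + 1L]
        votes <- 0L
        nv <- 0L
        for (p in pairs) {
          if (p[1, s] + p[2, s] == 1L && p[1, t] + p[2, t] == 1L) {
            votes <- votes + as.integer(p[1, s] != p[1, t])
            nv <- nv + 1L
          }
        }
        flip <- nv > 0L && votes * 2L > nv # majority says trans
        phi[j + 1L] <- if (flip) 1L - phi[j] else phi[j]
      }
    }
    h[1, het] <- phi
    h[2, het] <- 1L - phi
  }
  # label symmetry: gamete 1 lexicographically smaller
  cmp <- h[1, ] - h[2, ]
  first <- which(cmp != 0L)[1]
  if (!is.na(first) && cmp[first] > 0L) h <- h[2:1, , drop = FALSE]
  h
}

# Draw a template subset: rows of `pool`, uniformly without replacement,
# excluding the proband's own gametes.
draw_templates <- function(pool, n_templates, exclude = integer(0)) {
  avail <- setdiff(seq_len(nrow(pool)), exclude)
  if (length(avail) < 2) stop("template pool smaller than 2")
  take <- min(n_templates, length(avail))
  pool[sample(avail, take), , drop = FALSE]
}
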