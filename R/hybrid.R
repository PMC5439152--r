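# Orchestration: heuristic stage -> training/imputation mode selection ->
# HMM iterations with burn-in -> merged result with per-allele provenance.

#' Hybrid run configuration
#'
#' Defaults follow the method's standard settings: 200 template haplotypes,
#' 20 iterations with 5 burn-in iterations, a 50% phased-gamete threshold for
#' the training mode, the 99%-phased definition of a phased individual, a 90%
#' imputed-allele threshold for the haploid imputation mode, and 5 iterations
#' of the heuristic rules.
#'
#' @param n_templates number of template haplotypes per draw.
#' @param n_iterations total HMM iterations.
#' @param burn_in iterations discarded before dosages are accumulated.
#' @param training_threshold phased-individual fraction above which the
#'   haploid training mode is used.
#' @param phased_individual_fraction fraction of markers both gametes must
#'   have resolved for an individual to count as phased (inclusive).
#' @param haploid_imputation_threshold imputed-allele fraction above which an
#'   individual is imputed with the haploid model.
#' @param heuristics_enabled run the heuristic stage?
#' @param hmm_enabled run the HMM stage?
#' @param n_training_gametes per iteration, at most this many training-pool
#'   gametes are swept through the haploid model for parameter re-estimation
#'   (templates are still drawn from the whole pool); crossover and error
#'   counts saturate quickly, so a bounded sweep changes estimates little.
#' @param core_lengths core lengths for long-range phasing (NULL = default).
#' @param n_heuristic_iterations iterations of the heuristic rules.
#' @param min_surrogate_overlap minimum informative overlap for surrogates.
#' @param call_threshold segregation-analysis calling threshold.
#' @param seed master seed; all stage and per-individual streams derive from
#'   it.
#' @return a `hybrid_config` list.
#' @export
hybrid_config <- function(n_templates = 200, n_iterations = 20, burn_in = 5,
                          training_threshold = 0.50,
                          phased_individual_fraction = 0.99,
                          haploid_imputation_threshold = 0.90,
                          heuristics_enabled = TRUE, hmm_enabled = TRUE,
                          core_lengths = NULL, n_heuristic_iterations = 5,
                          min_surrogate_overlap = 50, call_threshold = 0.99,
                          n_training_gametes = 200, seed = 1) {
  stopifnot(burn_in < n_iterations, n_templates >= 2,
            training_threshold > 0, training_threshold <= 1,
            phased_individual_fraction > 0, phased_individual_fraction <= 1,
            haploid_imputation_threshold > 0, haploid_imputation_threshold <= 1)
  structure(as.list(environment()), class = "hybrid_config")
}

#' Count phased gametes and individuals
#'
#' An individual is phased when both its gametes have at least `fraction`
#' non-missing entries (inclusive).
#'
#' @param phase 2n x M phase matrix.
#' @param fraction phased-individual definition (default 0.99).
#' @return list with `phased` (logical per individual), `count` and
#'   `fraction_phased`.
#' @export
count_phased_gametes <- function(phase, fraction = 0.99) {
  n <- nrow(phase) %/% 2L
  M <- ncol(phase)
  res_p <- rowMeans(phase[pat_rows(n), , drop = FALSE] != MISSING)
  res_m <- rowMeans(phase[mat_rows(n), , drop = FALSE] != MISSING)
  phased <- res_p >= fraction & res_m >= fraction
  list(phased = phased, count = sum(phased),
       fraction_phased = mean(phased))
}

#' Select the global training mode
#'
#' Mode 1 (diploid training on genotypes) when the heuristics are disabled;
#' mode 2 (haploid training on heuristically phased gametes) when the phased
#' fraction exceeds the threshold; mode 3 (both data types, haplotypes taking
#' precedence) otherwise.
#'
#' @param config a [hybrid_config()].
#' @param phased_fraction fraction of phased individuals.
#' @return integer mode (1, 2 or 3).
#' @export
select_training_mode <- function(config, phased_fraction) {
  if (!config$heuristics_enabled) return(1L)
  if (phased_fraction > config$training_threshold) 2L else 3L
}

#' Select the imputation mode for one individual
#'
#' Haploid (mode 1) when the fraction of the individual's alleles imputed by
#' the heuristics exceeds the threshold, diploid (mode 2) otherwise.
#'
#' @param i individual row index.
#' @param phase 2n x M phase matrix after the heuristic stage.
#' @param threshold haploid-imputation threshold (default 0.90).
#' @return 1L (haploid) or 2L (diploid).
#' @export
select_imputation_mode <- function(i, phase, threshold = 0.90) {
  frac <- mean(phase[c(2L * i - 1L, 2L * i), ] != MISSING)
  if (frac > threshold) 1L else 2L
}

#' Build the HMM training set
#'
#' Mode 1: every genotyped individual enters with a random initial haplotype
#' pair and is re-sampled diploid each iteration.  Mode 2: whole-chromosome
#' resolved gametes from the heuristic stage (residual missing alleles drawn
#' at the population frequency).  Mode 3: the union, each individual entering
#' once with haplotype information taking precedence.
#'
#' @param mode training mode (1, 2 or 3).
#' @param phase 2n x M heuristic phase matrix.
#' @param genotypes n x M genotype matrix.
#' @param freq allele-1 frequencies.
#' @param config a [hybrid_config()].
#' @return list with `pool` (gamete matrix), `owner` (individual index per
#'   row) and `diploid_units` (individual indices re-sampled diploid during
#'   training).
#' @export
build_training_set <- function(mode, phase, genotypes, freq, config) {
  n <- nrow(genotypes)
  M <- ncol(genotypes)
  phased <- count_phased_gametes(phase, config$phased_individual_fraction)$phased
  genotyped <- rowMeans(genotypes != MISSING) >= 0.9
  pool <- NULL
  owner <- integer(0)
  diploid_units <- integer(0)
  add_gametes <- function(idx) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    block <- phase[rows, , drop = FALSE]
    mis <- block == MISSING
    if (any(mis)) {
      fills <- matrix(rbinom(length(block), 1L, rep(freq, each = nrow(block))),
                      nrow = nrow(block))
      block[mis] <- fills[mis]
    }
    pool <<- rbind(pool, block)
    owner <<- c(owner, rep(idx, each = 2L))
  }
  add_guesses <- function(idx) {
    for (i in idx) {
      h <- initial_guess(genotypes[i, ], freq)
      pool <<- rbind(pool, h)
      owner <<- c(owner, i, i)
    }
  }
  if (mode == 1L) {
    idx <- which(genotyped)
    add_guesses(idx)
    diploid_units <- idx
  } else if (mode == 2L) {
    add_gametes(which(phased))
  } else {
    add_gametes(which(phased))
    rest <- which(genotyped & !phased)
    add_guesses(rest)
    diploid_units <- rest
  }
  if (is.null(pool) || nrow(pool) < 2L) {
    stop("training pool smaller than 2 haplotypes")
  }
  storage.mode(pool) <- "integer"
  list(pool = pool, owner = owner, diploid_units = diploid_units)
}

# genotype observation row for the diploid model, with partially known
# gametes encoded as constraint codes (3: carries a 0; 4: carries a 1)
diploid_obs_row <- function(g, hp, hm) {
  obs <- g
  unknown_g <- g == MISSING
  one_known <- xor(hp != MISSING, hm != MISSING)
  a <- ifelse(hp != MISSING, hp, hm)
  obs[unknown_g & one_known & a == 0L] <- CONSTRAINED_REF
  obs[unknown_g & one_known & a == 1L] <- CONSTRAINED_ALT
  obs
}

#' Run the hybrid imputation method
#'
#' Applies the heuristic stage (unless disabled), selects the training and
#' imputation modes, runs the HMM iterations with burn-in, and merges the
#' outputs: observed and heuristic alleles are retained verbatim; HMM dosages
#' and probabilities fill only loci the heuristics left uncalled.  The run is
#' deterministic given the inputs and the seed.
#'
#' @param ped a [pedigree()].
#' @param genotypes n x M genotype matrix aligned to the pedigree.
#' @param map optional marker map (unused by the core model beyond ordering).
#' @param config a [hybrid_config()].
#' @param heuristic_stage optional precomputed [run_heuristics()] output for
#'   these inputs (the heuristic stage is deterministic, so sharing it across
#'   runs with different HMM settings changes nothing).
#' @return an `imputation_result`: list with `genotypes`, `phase`, `dosages`,
#'   `allele_probs` (2n x M), `provenance` (2n x M character), `params`,
#'   `training_mode`, `pedigree`.
#' @export
run_hybrid <- function(ped, genotypes, map = NULL, config = hybrid_config(),
                       heuristic_stage = NULL) {
  n <- nrow(ped)
  M <- ncol(genotypes)
  stopifnot(nrow(genotypes) == n)
  freq <- allele_frequencies(genotypes)

  if (config$heuristics_enabled) {
    h <- heuristic_stage %||% run_heuristics(genotypes, ped, config)
  } else {
    # without heuristics only the trivial self-phasing of homozygotes is kept
    P0 <- new_phase_matrix(n, M)
    P0[pat_rows(n), ][genotypes == 0L] <- 0L
    P0[mat_rows(n), ][genotypes == 0L] <- 0L
    P0[pat_rows(n), ][genotypes == 2L] <- 1L
    P0[mat_rows(n), ][genotypes == 2L] <- 1L
    h <- list(genotypes = genotypes, phase = P0,
              gamete_dosage = matrix(NA_real_, 2L * n, M))
  }
  G_h <- h$genotypes
  P_h <- h$phase
  gdos <- h$gamete_dosage

  # provenance: observed = forced by an observed genotype; heuristic = called
  # by the heuristic stage (incl. recombination-interval dosages); hmm = rest
  prov <- matrix("hmm", nrow = 2L * n, ncol = M)
  pr <- pat_rows(n)
  mr <- mat_rows(n)
  hom_obs <- genotypes == 0L | genotypes == 2L
  prov[pr, ][P_h[pr, , drop = FALSE] != MISSING] <- "heuristic"
  prov[mr, ][P_h[mr, , drop = FALSE] != MISSING] <- "heuristic"
  prov[pr, ][hom_obs] <- "observed"
  prov[mr, ][hom_obs] <- "observed"

  # allele probabilities seeded from the heuristic stage; recombination
  # -interval dosages are used only when the HMM does not refine those loci
  probs <- matrix(NA_real_, nrow = 2L * n, ncol = M)
  known <- P_h != MISSING
  probs[known] <- P_h[known]
  if (!config$hmm_enabled) {
    idx <- is.na(probs) & !is.na(gdos)
    probs[idx] <- gdos[idx]
    prov[idx] <- "heuristic"
  }

  params <- init_params(M)
  training_mode <- NA_integer_

  if (config$hmm_enabled) {
    phased <- count_phased_gametes(P_h, config$phased_individual_fraction)
    training_mode <- select_training_mode(config, phased$fraction_phased)
    set.seed(child_seed(config$seed, 300L))
    ts <- build_training_set(training_mode, P_h, G_h, freq, config)
    pool <- ts$pool
    owner <- ts$owner

    # imputation units: individuals with missing genotypes; an observed but
    # unphased genotype needs no imputation (its dosage is the genotype)
    unresolved <- which(rowSums(G_h == MISSING) > 0L)
    imp_mode <- vapply(unresolved, select_imputation_mode,
                       integer(1), phase = P_h,
                       threshold = config$haploid_imputation_threshold)

    keep_iters <- config$n_iterations - config$burn_in
    psum <- matrix(0, nrow = 2L * n, ncol = M)
    nacc <- 0L
    pair_samples <- list() # per diploid individual: list of 2 x M matrices
    hap_votes1 <- matrix(0, nrow = n, ncol = M) # haploid allele-1 votes
    hap_votes2 <- matrix(0, nrow = n, ncol = M)

    for (iter in seq_len(config$n_iterations)) {
      counts <- new_hmm_counts(M)
      # ---- training units ----
      if (training_mode %in% c(2L, 3L)) {
        hap_rows <- which(!(owner %in% ts$diploid_units))
        if (length(hap_rows) > config$n_training_gametes) {
          set.seed(child_seed(config$seed, 500L + iter))
          hap_rows <- sort(sample(hap_rows, config$n_training_gametes))
        }
        for (r in hap_rows) {
          set.seed(child_seed(config$seed, 1000L + iter, r))
          tmpl <- draw_templates(pool, config$n_templates,
                                 exclude = which(owner == owner[r]))
          obs <- pool[r, ]
          s <- hmm_sample_haploid(obs, tmpl, params$theta, params$eps)
          counts <- add_hap_counts(counts, s$jumps, s$alleles, obs)
        }
      }
      for (i in ts$diploid_units) {
        set.seed(child_seed(config$seed, 2000L + iter, i))
        rows_i <- which(owner == i)
        tmpl <- draw_templates(pool, config$n_templates, exclude = rows_i)
        obs <- G_h[i, ]
        s <- hmm_sample_diploid(obs, tmpl, params$theta, params$eps)
        counts <- add_dip_counts(counts, s$jumps1, s$jumps2,
                                 s$alleles1 + s$alleles2, obs)
        pool[rows_i[1], ] <- s$alleles1
        pool[rows_i[2], ] <- s$alleles2
      }
      # ---- imputation units ----
      for (ui in seq_along(unresolved)) {
        i <- unresolved[ui]
        set.seed(child_seed(config$seed, 3000L + iter, i))
        rows_i <- which(owner == i)
        tmpl <- draw_templates(pool, config$n_templates, exclude = rows_i)
        if (imp_mode[ui] == 1L) {
          for (side in 1:2) {
            row <- 2L * (i - 1L) + side
            obs <- P_h[row, ]
            s <- hmm_sample_haploid(obs, tmpl, params$theta, params$eps)
            counts <- add_hap_counts(counts, s$jumps, s$alleles, obs)
            if (iter > config$burn_in) {
              psum[row, ] <- psum[row, ] + s$p1
              if (side == 1) {
                hap_votes1[i, ] <- hap_votes1[i, ] + s$alleles
              } else {
                hap_votes2[i, ] <- hap_votes2[i, ] + s$alleles
              }
            }
          }
        } else {
          obs <- diploid_obs_row(G_h[i, ], P_h[2L * i - 1L, ], P_h[2L * i, ])
          s <- hmm_sample_diploid(obs, tmpl, params$theta, params$eps)
          counts <- add_dip_counts(counts, s$jumps1, s$jumps2,
                                   s$alleles1 + s$alleles2, G_h[i, ])
          if (iter > config$burn_in) {
            psum[2L * i - 1L, ] <- psum[2L * i - 1L, ] + s$p1
            psum[2L * i, ] <- psum[2L * i, ] + s$p2
            key <- as.character(i)
            pair_samples[[key]] <- c(pair_samples[[key]],
                                     list(rbind(s$alleles1, s$alleles2)))
          }
        }
      }
      if (iter > config$burn_in) nacc <- nacc + 1L
      params <- update_params(counts, params)
    }

    # ---- finalize: fill unresolved cells with averaged posteriors ----
    for (ui in seq_along(unresolved)) {
      i <- unresolved[ui]
      rows <- c(2L * i - 1L, 2L * i)
      if (imp_mode[ui] == 1L) {
        for (side in 1:2) {
          row <- rows[side]
          fill <- P_h[row, ] == MISSING
          pm <- psum[row, ] / nacc
          probs[row, fill] <- pm[fill]
          votes <- if (side == 1) hap_votes1[i, ] else hap_votes2[i, ]
          P_h[row, fill] <- as.integer(votes[fill] * 2L > nacc)
        }
      } else {
        cons <- consensus_pair(pair_samples[[as.character(i)]])
        for (side in 1:2) {
          row <- rows[side]
          fill <- P_h[row, ] == MISSING
          pm <- psum[row, ] / nacc
          probs[row, fill] <- pm[fill]
          P_h[row, fill] <- cons[side, fill]
        }
      }
    }
    P_h <- enforce_genotype_consistency(P_h, G_h)
  }

  # make allele probabilities exact at observed genotypes (dosage equals the
  # genotype wherever it is certain), then fall back to the population
  # frequency for cells nothing produced (only reachable with the HMM off)
  for (i in seq_len(n)) {
    rp <- 2L * i - 1L
    rm_ <- 2L * i
    g <- G_h[i, ]
    hp <- P_h[rp, ]
    hm <- P_h[rm_, ]
    known <- g != MISSING
    bothk <- known & hp != MISSING & hm != MISSING
    probs[rp, bothk] <- hp[bothk]
    probs[rm_, bothk] <- hm[bothk]
    onep <- known & hp != MISSING & hm == MISSING
    probs[rp, onep] <- hp[onep]
    probs[rm_, onep] <- pmin(pmax(g[onep] - hp[onep], 0), 1)
    onem <- known & hm != MISSING & hp == MISSING
    probs[rm_, onem] <- hm[onem]
    probs[rp, onem] <- pmin(pmax(g[onem] - hm[onem], 0), 1)
    none <- known & hp == MISSING & hm == MISSING
    probs[rp, none] <- g[none] / 2
    probs[rm_, none] <- g[none] / 2
    for (row in c(rp, rm_)) {
      na <- is.na(probs[row, ])
      if (any(na)) probs[row, na] <- freq[na]
    }
  }

  dosages <- probs[pr, , drop = FALSE] + probs[mr, , drop = FALSE]
  G_out <- G_h
  both_known <- P_h[pr, , drop = FALSE] != MISSING &
    P_h[mr, , drop = FALSE] != MISSING
  fill_g <- G_out == MISSING & both_known
  sums <- P_h[pr, , drop = FALSE] + P_h[mr, , drop = FALSE]
  G_out[fill_g] <- sums[fill_g]
  if (config$hmm_enabled) {
    still <- G_out == MISSING
    G_out[still] <- as.integer(round(dosages))[still]
  }

  structure(list(genotypes = G_out, phase = P_h, dosages = dosages,
                 allele_probs = probs, provenance = prov, params = params,
                 training_mode = training_mode, pedigree = ped,
                 config = config, allele_freq = freq),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  n <- nrow(x$genotypes)
  M <- ncol(x$genotypes)
  cat("imputation_result: ", n, " individuals x ", M, " markers\n", sep = "")
  cat("  training mode: ", x$training_mode, "\n", sep = "")
  tab <- table(factor(x$provenance, levels = c("observed", "heuristic", "hmm")))
  cat("  allele provenance: ",
      paste(names(tab), format(as.vector(tab)), collapse = ", "), "\n")
  invisible(x)
}
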