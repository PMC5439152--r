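# End-to-end benchmark: simulate replicates of the study design, run each
# method x panel x pedigree condition, and tabulate dosage-correlation
# accuracies.  The same machinery backs the acceptance script and the test
# suite, at different scales.

#' Desk-scale study design
#'
#' A single-CPU-sized rendition of the simulated study: one chromosome whose
#' genetic length, low-density anchor densities (markers per cM) and pedigree
#' proportions follow the full design, with sequence length, marker counts
#' and family counts scaled down.  The defaults simulate a 25 cM chromosome
#' (2 Mb at 1.25e-7 crossovers per bp) with 400 base haplotypes, a 320-marker
#' high-density panel (12.8 markers/cM) and low-density panels of 4, 8, 75,
#' 150 and 256 markers (the per-cM equivalents of 15, 30, 300, 600 and 2000
#' markers on a 100 cM chromosome, the densest capped at 80% of the
#' high-density panel), and a 4-sire x 20-dam pedigree producing 40 progeny
#' per generation for 5 generations; 16 of the 40 last-generation
#' individuals lose their pedigree links in the no-pedigree scenario.
#'
#' @param n_sires,n_dams,n_progeny,n_generations pedigree design.
#' @param n_base_haplotypes base haplotypes from the coalescent.
#' @param length_bp,mutation_rate,recombination_rate sequence scale.
#' @param hd_size high-density panel size.
#' @param ld_sizes named low-density panel sizes.
#' @param n_remove_links pedigree links removed in the no-pedigree scenario.
#' @param n_templates default template count.
#' @param n_iterations,burn_in HMM iteration schedule.
#' @return a `study_scale` list.
#' @export
desk_scale <- function(n_sires = 4, n_dams = 20, n_progeny = 40,
                       n_generations = 5, n_base_haplotypes = 400,
                       length_bp = 2e6, mutation_rate = 1e-7,
                       recombination_rate = 1.25e-7, hd_size = 320,
                       ld_sizes = c(L15 = 4, L30 = 8, L300 = 75,
                                    L600 = 150, L2k = 256),
                       n_remove_links = 16, n_templates = 200,
                       n_iterations = 20, burn_in = 5) {
  M <- hd_size
  structure(list(
    demog = sim_demography(length_bp = length_bp,
                           mutation_rate = mutation_rate,
                           recombination_rate = recombination_rate),
    spec = sim_pedigree_spec(n_sires, n_dams, n_progeny, n_generations),
    n_base_haplotypes = n_base_haplotypes,
    hd_size = hd_size, ld_sizes = ld_sizes,
    n_remove_links = n_remove_links,
    core_lengths = round(exp(seq(log(0.05 * M), log(0.9 * M),
                                 length.out = 10))),
    n_templates = n_templates, n_iterations = n_iterations,
    burn_in = burn_in), class = "study_scale")
}

scale_config <- function(scale, seed, method = "hybrid", n_templates = NULL) {
  hybrid_config(
    n_templates = n_templates %||% scale$n_templates,
    n_iterations = scale$n_iterations,
    burn_in = scale$burn_in,
    heuristics_enabled = method != "hmm",
    hmm_enabled = method != "heuristic",
    core_lengths = scale$core_lengths,
    seed = seed)
}

#' Run one benchmark condition on a simulated population
#'
#' @param pop a [simulate_population()] result.
#' @param panel low-density panel name (of `pop$masked`).
#' @param pedigree `"full"` or `"none"` (no-pedigree scenario: the removed
#'   individuals' links are dropped and accuracy is evaluated on them).
#' @param method `"hybrid"`, `"heuristic"` (heuristics only) or `"hmm"`
#'   (HMM only, pedigree-free).
#' @param scale a [desk_scale()].
#' @param seed run seed.
#' @param n_templates template count (default from scale).
#' @param heuristic_stage optional precomputed heuristic stage.
#' @return list with `accuracy` (mean animal-wise r over the evaluation set),
#'   `animal` / `marker` reports, and the `result`.
#' @export
run_condition <- function(pop, panel, pedigree = c("full", "none"),
                          method = c("hybrid", "heuristic", "hmm"),
                          scale = desk_scale(), seed = 1, n_templates = NULL,
                          heuristic_stage = NULL) {
  pedigree <- match.arg(pedigree)
  method <- match.arg(method)
  ped <- if (pedigree == "none") {
    drop_pedigree_links(pop$ped, pop$removed_ids)
  } else {
    pop$ped
  }
  eval_ids <- if (pedigree == "none") pop$removed_ids else pop$test_ids
  G <- pop$masked[[panel]]
  cfg <- scale_config(scale, seed, method, n_templates)
  res <- run_hybrid(ped, G, config = cfg, heuristic_stage = heuristic_stage)
  rows <- match(eval_ids, pop$ped$id)
  animal <- animalwise_accuracy(pop$truth_geno[rows, , drop = FALSE],
                                res$dosages[rows, , drop = FALSE],
                                ids = eval_ids)
  marker <- markerwise_accuracy(pop$truth_geno[rows, , drop = FALSE],
                                res$dosages[rows, , drop = FALSE])
  list(accuracy = attr(animal, "mean_r"), animal = animal, marker = marker,
       result = res)
}

#' Benchmark the imputation methods over simulated replicates
#'
#' Simulates `n_replicates` populations and runs the requested conditions on
#' each, reusing the (deterministic) heuristic stage across methods and
#' template counts within a panel/pedigree combination.
#'
#' @param seed master seed; replicate r uses a seed derived from `(seed, r)`.
#' @param n_replicates number of simulation replicates (default 3).
#' @param scale a [desk_scale()].
#' @param conditions data.frame with columns `panel`, `pedigree`, `method`,
#'   `n_templates`; `NULL` selects the standard comparison grid.
#' @param keep_maf_for optional row-selection function: for conditions where
#'   it returns `TRUE`, per-MAF-bin marker-wise means are collected.
#' @return list with tibbles `accuracy` (one row per replicate x condition)
#'   and `maf` (per-bin means for selected conditions).
#' @export
benchmark_imputation <- function(seed, n_replicates = 3, scale = desk_scale(),
                                 conditions = NULL, keep_maf_for = NULL) {
  conditions <- conditions %||% standard_conditions(scale)
  keep_maf_for <- keep_maf_for %||% function(cond) {
    cond$panel == "L30" && cond$pedigree == "none" &&
      cond$method == "hybrid" && cond$n_templates == scale$n_templates
  }
  acc <- list()
  maf <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- child_seed(seed, 11L, r)
    pop <- simulate_population(
      rep_seed, demog = scale$demog, spec = scale$spec,
      n_base_haplotypes = scale$n_base_haplotypes, hd_size = scale$hd_size,
      ld_sizes = scale$ld_sizes, n_remove_links = scale$n_remove_links)
    hcache <- list()
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      key <- paste(cond$panel, cond$pedigree)
      run_seed <- child_seed(seed, 13L, r, ci)
      if (cond$method != "hmm") {
        if (is.null(hcache[[key]])) {
          ped <- if (cond$pedigree == "none") {
            drop_pedigree_links(pop$ped, pop$removed_ids)
          } else {
            pop$ped
          }
          hcache[[key]] <- run_heuristics(pop$masked[[cond$panel]], ped,
                                          scale_config(scale, run_seed))
        }
        hs <- hcache[[key]]
      } else {
        hs <- NULL
      }
      out <- run_condition(pop, cond$panel, cond$pedigree, cond$method,
                           scale, seed = run_seed,
                           n_templates = cond$n_templates,
                           heuristic_stage = hs)
      acc[[length(acc) + 1L]] <- tibble::tibble(
        replicate = r, panel = cond$panel, pedigree = cond$pedigree,
        method = cond$method, n_templates = cond$n_templates,
        accuracy = out$accuracy)
      if (isTRUE(keep_maf_for(cond))) {
        maf[[length(maf) + 1L]] <- dplyr::mutate(
          maf_bin_means(out$marker),
          replicate = r, panel = cond$panel, pedigree = cond$pedigree,
          method = cond$method, .before = 1)
      }
    }
  }
  list(accuracy = dplyr::bind_rows(acc),
       maf = if (length(maf)) dplyr::bind_rows(maf) else tibble::tibble())
}

#' Standard comparison grid
#'
#' With full pedigree: hybrid and heuristic-only on every panel.  Without
#' pedigree: heuristic-only and hybrid at 100/200/300 templates on the L30
#' panel, hybrid on the three densest panels.
#'
#' @param scale a [desk_scale()].
#' @return tibble of conditions.
#' @export
standard_conditions <- function(scale = desk_scale()) {
  nt <- scale$n_templates
  panels <- names(scale$ld_sizes)
  dplyr::bind_rows(
    tidyr::expand_grid(panel = panels, pedigree = "full",
                       method = c("hybrid", "heuristic"), n_templates = nt),
    tibble::tibble(panel = "L30", pedigree = "none", method = "heuristic",
                   n_templates = nt),
    tibble::tibble(panel = "L30", pedigree = "none", method = "hybrid",
                   n_templates = c(100L, nt, 300L)),
    tibble::tibble(panel = c("L300", "L600", "L2k"), pedigree = "none",
                   method = "hybrid", n_templates = nt))
}

#' Plot benchmark accuracies by panel
#' @param bench output of [benchmark_imputation()].
#' @return a ggplot object (mean accuracy vs panel, by method and pedigree).
#' @export
plot_benchmark <- function(bench) {
  dat <- bench$accuracy |>
    dplyr::group_by(.data$panel, .data$pedigree, .data$method,
                    .data$n_templates) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$panel, y = .data$accuracy,
                                    colour = .data$method,
                                    linetype = .data$pedigree,
                                    group = interaction(.data$method,
                                                        .data$pedigree,
                                                        .data$n_templates))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "low-density panel", y = "mean animal-wise accuracy") +
    ggplot2::theme_minimal()
}
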