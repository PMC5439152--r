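# hybridimpute

Genotype imputation for pedigreed (livestock) populations that combines two
complementary strategies in one pipeline:

1. a **heuristic stage** — Mendelian-inheritance rules, single-locus
   segregation analysis (iterative peeling), long-range phasing with
   surrogate parents, and haplotype-library imputation over multi-length
   cores — which resolves most alleles of well-connected individuals quickly
   and builds a library of accurately phased haplotypes; and
2. a **Li–Stephens haplotype-copying HMM** (MaCH-style) that imputes
   whatever the heuristics leave unresolved, using the heuristic haplotypes
   as its template set.

Each gamete is modeled as a mosaic of |H| template haplotypes. Between
markers *i* and *i+1* the copied template stays with probability
(1 − θᵢ) + θᵢ/|H| and switches to any specific other template with
probability θᵢ/|H|; an observed allele disagrees with the copied template
with per-marker error probability εᵢ. The diploid model runs over ordered
template pairs (h, k); the factorized transition reduces a forward step from
O(|H|⁴) to O(|H|²). Both parameter vectors start at 0.01 and are
re-estimated each Monte-Carlo iteration from sampled mosaics (jump events →
θ, allele disagreements → ε). Individuals that the heuristics leave more
than 90% imputed are refined with a haploid HMM per gamete; the rest run the
diploid HMM on their genotype rows, with heuristic single-allele calls
entering as constrained observations. Dosages are averaged posterior
allele-1 probabilities over post-burn-in iterations; the final phase is the
switch-error-minimizing consensus pair.

The package also ships the full simulation and evaluation machinery: an
ancestral-recombination-graph coalescent under piecewise-linear demography,
pedigree gene dropping with 1% crossover probability per cM, high/low
density panel construction and masking, pedigree-link removal, and accuracy
evaluation as animal-wise and marker-wise Pearson correlations of true vs
imputed allele dosages with minor-allele-frequency bins and
ancestor-genotyping categories. Everything is testable without external
data.

## A worked example

```r
library(hybridimpute)

# simulate a pedigreed population on one 25 cM chromosome: 320-marker HD
# panel, last generation masked to 8 markers (the per-cM equivalent of a
# 30-marker panel on a 100 cM chromosome)
pop <- simulate_population(
  seed = 1,
  demog = sim_demography(length_bp = 2e6, mutation_rate = 1e-7,
                         recombination_rate = 1.25e-7),
  spec = sim_pedigree_spec(n_sires = 4, n_dams = 20, n_progeny = 40,
                           n_generations = 5),
  n_base_haplotypes = 400, hd_size = 320,
  ld_sizes = c(L30 = 8))

res <- run_hybrid(pop$ped, pop$masked$L30, config = hybrid_config(seed = 1))
res
#> imputation_result: 224 individuals x 320 markers
#>   training mode: 2
#>   allele provenance:  observed 80268, heuristic 57955, hmm  5137

rows <- match(pop$test_ids, pop$ped$id)
aw <- animalwise_accuracy(pop$truth_geno[rows, ], res$dosages[rows, ])
glance(aw)
#> # A tibble: 1 x 2
#>       n mean_r
#>   <int>  <dbl>
#> 1    40  0.977
```

The printed `mean_r` is the study's headline statistic: the Pearson
correlation between true and imputed allele dosages computed across markers
within each test animal, averaged over animals — 1.0 means every masked
genotype was recovered exactly, and values in the mid-0.90s are typical for
30-marker-per-100 cM panels when the pedigree is complete. (Exact numbers
vary slightly with the seed; the provenance line shows how many alleles were
observed, resolved by the heuristics, or left to the HMM.)

`run_hybrid(..., hybrid_config(hmm_enabled = FALSE))` reproduces
heuristic-only behavior (unimputed genotypes stay 9 with dosage twice the
allele frequency); `heuristics_enabled = FALSE` gives the pure, pedigree-free
diploid HMM. A thin command-line wrapper with `run`, `simulate`, `evaluate`
and `benchmark` subcommands lives at `inst/cli/hybridimpute.R`.

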