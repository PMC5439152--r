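---
title: "Hybrid heuristic and HMM genotype imputation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid heuristic and HMM genotype imputation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Livestock breeding programs genotype a few animals on expensive high-density
(HD) marker panels and many animals on cheap low-density (LD) panels, then
infer the untyped HD genotypes of the LD animals. Two families of methods
dominate. *Heuristic* methods exploit pedigree information and the long
haplotypes shared by close relatives: they are fast and very accurate where
their rules apply, but leave alleles unimputed where the pedigree is missing,
wrong, or uninformative. *Probabilistic* methods model each genotype as a
mosaic of template haplotypes with a hidden Markov model (HMM): they need no
pedigree, impute everything, but are slower and — in pedigreed populations —
often less accurate. `hybridimpute` implements a hybrid of the two: the
heuristic stage resolves what it can and builds a library of accurately
phased haplotypes; the HMM, seeded with those haplotypes as templates,
imputes whatever is left.

Genotypes are biallelic, coded 0 (reference homozygote), 1 (heterozygote),
2 (alternative homozygote), 9 (missing); alleles are 0/1/9. Allele
probabilities lie in [0, 1]; the allele dosage of a genotype is the sum of
the two gametes' allele probabilities, in [0, 2].

# The heuristic stage

Five iterations (configurable) of four rule sets:

1. **Mendelian inheritance** (`mendelian_fill()`): homozygotes phase
   themselves; a homozygous parent fixes the transmitted allele; a
   heterozygote with one gamete known gets the other by subtraction; a
   missing genotype is filled when both gametes, or both parents'
   homozygous genotypes, determine it. Opposing parent/offspring
   homozygotes are treated as recording errors: the offending genotype is
   set to missing and counted, not fatal.
2. **Long-range phasing with surrogate parents** (`find_surrogates()`,
   `phase_by_surrogates()`): within each *core* (a contiguous marker block),
   individuals that share zero opposing homozygotes with the proband — and
   are connected through the sire or dam side of the pedigree — act as
   surrogate parents. At each heterozygous proband locus, homozygous
   surrogates vote; only unanimous votes are called. A minimum informative
   overlap (default 50 loci, capped at the proband's typed loci in the
   region) guards against vacuous zero-conflict matches on sparse rows.
3. **Haplotype-library imputation** (`build_library()`, `library_impute()`):
   every fully resolved gamete over a core enters the core's library.
   Library haplotypes consistent with a proband gamete's known alleles are
   candidate haplotypes; a missing position is imputed only where all
   candidates agree. A second, parent-restricted pass admits only the two
   parental gametes as candidates. Ten core lengths are used, each tiling
   the chromosome twice (anchored and offset by half a core), and an allele
   is committed only when all tilings that call it agree
   (`cross_core_consensus()`). No call ever contradicts an observed
   genotype.
4. **Recombination sweep** (`recombination_sweep()`): each offspring gamete
   is assigned a grand-parental origin at informative loci; a change of
   origin brackets a putative crossover, inside which the gamete dosage is
   the linear, marker-index-weighted average of the parent's two gametes.
   The phase stays missing there so the HMM can refine those loci.

The stage ends with a single-locus **segregation analysis**
(`segregation_probs()`): iterative peeling over the pedigree that combines
each individual's genotype likelihood, per-gamete transmission priors from
its parents (population frequency for unknown parents) and an aggregated
offspring term. Downward messages exclude the receiving child's own upward
contribution, so the scheme is exact on loop-free pedigrees and approximate
under inbreeding loops (no junction tree is built; the stage is itself a
heuristic). Marginal gamete probabilities at or above 0.99 become hard
calls.

# The HMM stage

The HMM is a Li–Stephens haplotype-copying model. A gamete is a mosaic of
|H| template haplotypes; between adjacent markers the copied template stays
with probability $(1-\theta_i) + \theta_i/|H|$ and switches to any specific
other template with probability $\theta_i/|H|$. An observed allele disagrees
with the copied template allele with per-marker error probability
$\varepsilon_i$; a genotype observation reads both template alleles with
independent errors. Both parameter vectors start at 0.01 and are
re-estimated each iteration from the sampled mosaics: $\theta_i$ from
sampled jump events (a jump may land on the same template and still counts —
it is a recombination), $\varepsilon_i$ from disagreements between sampled
and observed alleles, each with Laplace (+1/+2) smoothing and clamped to
$[10^{-6}, 0.5]$.

The diploid model runs over ordered template pairs. The factorized
transition lets a forward step cost $O(|H|^2)$ instead of the dense
$O(|H|^4)$; the test suite checks the equivalence against a dense
transition-matrix oracle to $10^{-10}$. The implementation additionally
exploits that the diploid forward and backward matrices are symmetric in the
two gamete labels, computing only a triangle, and stores the forward history
in single precision (values are renormalized per marker, so about seven
significant digits are retained; dosages are accumulated in double
precision).

Per individual and iteration, a template subset (default 200) is drawn
uniformly without replacement from the pool, excluding the individual's own
gametes, with a stream seeded by (seed, iteration, individual) so results do
not depend on processing order. Posterior allele-1 probabilities are
accumulated after 5 burn-in iterations (of 20); the final phase is the
consensus pair that minimizes switch disagreement with the sampled pairs
(per-interval majority of relative orientations, exact because intervals
are independent; verified against an exhaustive oracle on small instances).

**Training modes.** Mode 1 (heuristics disabled): every genotyped
individual enters with a random initial haplotype pair and is re-sampled
diploid each iteration — the classic pedigree-free HMM. Mode 2 (more than
50% of individuals phased, where "phased" means both gametes at least 99%
resolved, inclusive): the pool is the heuristically phased gametes, with
residual missing alleles drawn once at the population frequency. Mode 3:
both, each individual entering once, haplotypes taking precedence. In modes
2/3 a bounded random sweep of pool gametes (default 100 per iteration) runs
through the haploid model purely to feed the parameter counts; jump and
error counts saturate with a few thousand gamete-transits, so sweeping the
whole pool every iteration changes estimates negligibly while dominating
runtime.

**Imputation modes.** An individual more than 90% imputed by the heuristics
is refined gamete-by-gamete with the haploid model (missing alleles as 9s);
anything less runs the diploid model on its genotype row, with heuristic
single-allele calls at missing genotypes encoded as constrained
observations (genotype in {0,1} or {1,2}), which effectively raises the
individual's marker density. Only individuals with missing *genotypes* are
imputation units: an observed but unphased heterozygote needs no dosage
imputation (its dosage is its genotype).

**Merge.** Observed alleles are kept verbatim, heuristic calls next, HMM
probabilities fill the rest; per-allele provenance (observed / heuristic /
hmm) is recorded. Every (individual, marker) ends with a dosage. With the
HMM disabled, unimputed genotypes are emitted as 9 with dosage twice the
allele frequency; recombination-interval dosages from the sweep are used
only in that mode, since the HMM otherwise refines those loci.

# The simulator

`simulate_base_haplotypes()` is an ancestral-recombination-graph coalescent:
pairwise coalescence at rate $1/(2N_e(t))$ under a piecewise-linear
demography ($N_e$ = 100 at present, 1256 at 1,000, 4,350 at 10,000 and
43,500 at 100,000 generations ago, one generation per year), lineage
recombination at the per-site rate times the lineage's ancestral-material
length, and mutations dropped on the graph at the per-site rate, emitted as
biallelic segregating sites. Two standard accelerations are used: intervals
whose marginal tree has found its most recent common ancestor are pruned,
and breakpoints fall only inside ancestral material (trapped non-ancestral
material is ignored, an approximation in the direction of the sequential
Markov coalescent that leaves each site's marginal tree correctly
distributed). Nucleotide diversity and the four-gamete test are checked
against closed forms in the test suite.

`found_and_drop()` gene-drops the base haplotypes through a sire × dam
pedigree: founders draw two base haplotypes, each meiosis places a
binomial(1 cM intervals, 0.01) number of crossovers uniformly in genetic
distance, without interference. Panels are uniform random site subsets
(every LD panel nested in the HD panel); the last generation is masked to
the LD panel; the no-pedigree scenario removes the sire and dam links of
half the last generation while keeping everyone's genotypes.

# Desk scale

All stochastic end-to-end checks run at a fixed "desk scale"
(`desk_scale()`), chosen once so that a full benchmark fits a single CPU:
one 25 cM chromosome (2 Mb with a per-bp crossover rate of 1.25e-7 and
mutation rate 1e-7, giving a few thousand segregating sites), 400 base
haplotypes, a 320-marker HD panel (12.8 markers/cM), and LD panels of 4, 8,
75, 150 and 256 markers — the per-centimorgan equivalents of the full
design's 15, 30, 300, 600 and 2000 markers per 100 cM chromosome, the
densest capped at 80% of the HD panel. The pedigree mates 4 sires with 20
dams for 40 progeny per generation over 5 generations (224 individuals);
the no-pedigree scenario removes the links of 16 of the 40 last-generation
individuals. Template counts of 100–300 with 20 iterations and 5 burn-in
match the standard settings; the test suite exercises the same design at
150 templates (100 for the pedigree-free HMM) to stay within a single-CPU
budget.

Scaling preserves the quantities the method is sensitive to — LD-panel
anchor density per cM, crossovers per chromosome and per meiosis, pedigree
depth and family structure, the coalescent demography — but not the
absolute counts: the desk HD panel covers fewer markers per chromosome, the
template pool holds ~400 rather than many thousands of gametes, and the
dense LD panels cover a much larger *fraction* of the HD panel than at full
scale. Dense-panel accuracies are therefore slightly flattered (more of the
animal-wise correlation comes from observed markers), while no-pedigree
HMM accuracies are slightly penalized (fewer distinct templates to copy
from). Passing desk-scale checks shows the machinery reproduces the
method's behavior under the stated population model, not that the exact
full-scale numbers would be reproduced on real data.

# Numerical and design choices

- **Phase convention**: rows $2i-1$ / $2i$ are the sire- and dam-inherited
  gametes; founder orientation is arbitrary but fixed per run.
- **Unknown parents** are the literal token `"0"` in all files; missing data
  are always the code 9, never `NA`, keeping matrices dense integer.
- **Scaling** in the HMM uses per-marker renormalization with accumulated
  log constants rather than log-space recursions — simpler and adequate at
  the marker counts handled here.
- **Tie-breaks**: consensus genotypes resolve ties toward the smaller
  genotype; consensus pairs report the lexicographically smaller gamete
  first; surrogate votes require unanimity, deferring disagreements to the
  HMM.
- **Degenerate inputs**: an individual with no genotypes at all is imputed
  purely from the model (diploid, population prior); a zero normalizer in
  the segregation analysis resets that locus to the genotype-consistent
  uniform and is logged; markers monomorphic in truth are flagged undefined
  in marker-wise accuracy and excluded from bin means, and zero-variance
  animals likewise from animal-wise means.
- **Accuracy measures**: animal-wise accuracy is the Pearson correlation of
  true and imputed dosages across markers within an animal, averaged over
  animals. Marker-wise accuracy standardizes both vectors by the *truth's*
  mean and standard deviation before the cross-product, so a constant
  imputation (e.g. twice the allele frequency) scores exactly zero; this is
  the measure of choice for rare alleles. Note the two reward different
  things: a graded dosage that encodes allele-frequency information earns
  animal-wise correlation even where no individual-specific signal exists,
  but earns nothing marker-wise. Heuristic tools that emit hard calls (or
  nothing) therefore score much lower animal-wise than this package's
  frequency-informed dosage fill, under otherwise identical imputations —
  a metric artifact worth keeping in mind when comparing animal-wise
  numbers across software.

# Known limitations

- Single chromosome per run (the command-line wrapper loops).
- The segregation analysis is single-locus and approximate under
  inbreeding loops.
- No genotype-likelihood (sequencing) input; the error model lives entirely
  in $\varepsilon_i$ on the inference side — the simulator injects no
  genotyping errors.
- The long-range phasing stage implements the published behavior of the
  surrogate-parent and haplotype-library algorithms, not every internal of
  the original phasing software (e.g. its error-mining pass); vote rules
  and the overlap minimum are declared stand-ins.
- Selection, non-random mating and crossover interference are out of scope
  for the simulator.

# A worked example

```{r example}
library(hybridimpute)

pop <- simulate_population(
  seed = 1,
  demog = sim_demography(length_bp = 2e6, mutation_rate = 1e-7,
                         recombination_rate = 1.25e-7),
  spec = sim_pedigree_spec(4, 20, 40, 5),
  n_base_haplotypes = 400, hd_size = 400,
  ld_sizes = c(L30 = 8), n_remove_links = 0)

res <- run_hybrid(pop$ped, pop$masked$L30,
                  config = hybrid_config(seed = 1))

rows <- match(pop$test_ids, pop$ped$id)
aw <- animalwise_accuracy(pop$truth_geno[rows, ], res$dosages[rows, ])
glance(aw)
autoplot(markerwise_accuracy(pop$truth_geno[rows, ], res$dosages[rows, ]))
```
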