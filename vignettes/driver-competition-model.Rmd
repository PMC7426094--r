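---
title: "Modelling competing wtf drivers: meiosis, invasion, and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling competing wtf drivers: meiosis, invasion, and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtfdrive)
```

## The killing model

A *wtf* element is a poison–antidote pair. During sporulation every spore of
the ascus is exposed to each segregating poison; a spore is rescued from a
given poison only if it inherits the element encoding the matching antidote.
`wtfdrive` reduces this to a single per-spore rule: survival is the product,
over every driver allele segregating in the diploid, of 1 if the spore
carries an allele with the same id *and* that allele encodes an antidote,
and (1 − `kill_prob`) otherwise. Poison-only (separation-of-function)
alleles never contribute a rescue factor, so they kill carriers and
non-carriers alike — which is why they depress fertility without changing
the genotype composition of the survivors. Nullisomic spores are inviable
regardless of drivers, because a spore missing any chromosome cannot
germinate.

A meiosis is one of three mutually exclusive events:

* **MI nondisjunction of chromosome 3** (probability `misseg_prob`, *m*):
  two heterozygous disomes carrying both parental haplotypes plus two
  nullisomes. We model nondisjunction as a whole-meiosis event because it
  reproduces the 50% disome / 50% dead split of a fully missegregating
  meiosis exactly and keeps enumeration closed-form. Disomes are always
  heterozygous here; identical-homolog disomes are not modelled because MI
  nondisjunction of homologs cannot produce them.
* **Unequal interhomolog crossover** (probability `uneq_xo_prob`, *u*,
  conditional on a normal meiosis and requiring Rec12): one product carries
  both alleles of the designated locus in tandem (a driver duplication), its
  reciprocal carries neither — predicting a marker-less spore class — and
  the other two products are parental.
* **Normal meiosis**: four haploid products. Parental origin along the
  locus list follows per-interval recombination fractions (first interval:
  centromere to locus 1), with at most one crossover per interval and no
  interference; the four products are treated as independent draws. This is
  deliberately coarser than four-strand chromatid bookkeeping — the data the
  model confronts are pairwise recombinant fractions, which this
  parameterisation matches directly.

Setting `rec12_active = FALSE` silences both induced recombination and
unequal crossovers, mirroring a *rec12* deletion.

`enumerate_meiosis()` returns the exact probability census over spore
classes (tolerance on normalisation: 1e-12); `simulate_meioses()` samples
the same hierarchy with one root seed, so identical inputs and seed give
identical counts. `simulation_gof()` tests the sampler against the
enumeration with a chi-square that respects the sampling structure: branch
counts are multinomial, products within the normal branch are multinomial,
and viable counts per class are binomial, so the component Pearson
statistics are independent and their sum is chi-square on the summed degrees
of freedom. A naive multinomial chi-square over census cells would be
anti-conservative, because nondisjunction forces two disomes and two
nullisomes per meiosis and inflates those cells' variance.

## Summaries and degenerate cases

`summarise_census()` computes the assayed quantities: the viable fraction of
all spores; disomy among viable spores; per-marker transmission among viable
haploids, excluding spores showing both or neither of a locus's markers
(the analogue of setting aside double-resistant colonies, which cannot be
assigned to a haplotype); the recombinant fraction among viable haploids;
and relative fertility against a reference census. When no spore survives,
the conditional quantities are returned as `NA` with `undefined = TRUE`
rather than 0/0. `observed_recombination()` reports the recombinant fraction
a geneticist would score between two marked loci from marker phenotypes
alone — the quantity that driver killing distorts away from the true map
fraction.

## The invasion recursion

The population model tracks a mutation that degrades chromosome-3
segregation in a population segregating *n* drivers, each at frequency
1/*n* and strength *t*. Chromosome 3 is treated as exhibiting
whole-chromosome drive: a random mating is driver-homozygous with
probability 1/*n* (all spores rescued) and driver-heterozygous with
probability (*n* − 1)/*n* (each haploid spore killed with probability *t*).
The expected viable output of a faithful meiosis is therefore
4·[1/*n* + ((*n* − 1)/*n*)(1 − *t*)]. A mutant meiosis missegregates with
probability φ (0, *h·f*, *f* for wild type, heterozygote, homozygote),
yielding 2 disomes with viability (1 − *s_s*); disomes carry both haplotypes
and escape killing, and the extra chromosome is shed afterwards, so driver
symmetry is preserved. The mutation's own cost is multiplicative on the
carrier's total output (*h·s_m* in heterozygotes). The mutant locus is
unlinked to chromosome 3, so mutant transmission among a heterozygote's
viable spores is 1/2 whatever the chromosome-3 outcome.

The lifecycle is haploid pool → random union → meiosis → viability-weighted
spore pool. One generation is

p′ = Σ<sub>g</sub> freq<sub>g</sub>·W<sub>g</sub>·mut<sub>g</sub> /
Σ<sub>g</sub> freq<sub>g</sub>·W<sub>g</sub>,

with Hardy–Weinberg diploid frequencies. Comparing the rare heterozygote
against the wild type gives the invasion condition; cost-free it reduces
algebraically to *t* > *n* / (2(*n* − 1)), and `invasion_boundary()`
confirms the same threshold by root-bracketing without the closed form
(agreement to 1e-9 for *n* = 2..50 in the tests). At the threshold all three
genotype outputs are equal, so the frequency is exactly stationary;
`drive_trajectory()` detects this interior fixed point and stops rather than
iterating to `max_gen`. Defaults follow the anchor trajectories: *n* = 3,
*f* = 1, *h* = 0.5, no costs, p0 = 0.1, under which *t* = 0.55 loses the
mutant and *t* = 0.95 fixes it; the trajectory caption fixes only p0, so the
remaining values are this package's choice, made so the critical strength
0.75 separates the two printed outcomes. Convergence uses eps = 1e-6 and
max_gen = 1e5. Dominance *h* rescales φ in heterozygotes only, so with no
costs it changes the time to absorption but not the outcome.

A note on costs: because *s_m* enters heterozygotes as *h·s_m*, a mutation
with *s_m* = 1 is only carrier-lethal when dominant (*h* = 1); at *h* < 1 a
rare carrier retains part of its output and can still invade at high *t*
and *n*. The tests assert the no-invasion property in the dominant case.

## Assay statistics

The G-test is the likelihood-ratio goodness-of-fit statistic
G = 2ΣO·ln(O/E) with 0·ln 0 = 0, referred to chi-square on *k* − 1 degrees
of freedom, without Williams or continuity correction — matching how
transmission and disomy counts are compared. Because counts are discrete,
the null distribution of its p-value is a step function; the calibration
test therefore checks empirical rejection rates at working thresholds
rather than a continuous-distribution KS statistic. The Wilcoxon rank-sum
test uses the exact distribution when the smaller fertility group has at
most 8 replicates and no ties, and the tie-corrected normal approximation
otherwise. Map distances are offered both as the raw recombinant percentage
and through Haldane's function −50·ln(1 − 2·RF); the raw estimate saturates
at 50 cM, which is why a long control interval needs the mapping function
while drive-distorted intervals do not. The two-proportion sample-size
formula is the standard pooled normal approximation, returned as the
smallest integer meeting the requested power.

## Synthetic data: what it emulates and what it does not

`scenario_library()` fixes the study conditions once: driver strength 0.95
(empirical drive is generally above 0.9), MI nondisjunction 0.1 (about one
meiosis in ten, matching ~5% disomy among viable spores of a faithful
control), 300 genotyped spores per diploid, unequal-crossover rate 0.01 at
the assayed locus, fertility baseline 2 viable spores per plated cell in
arbitrary units with lognormal noise of σ = 0.3 on the log scale. The
double-driver preset places the two strongest drivers (0.98) on one
haplotype against a weaker pair (0.70), the configuration in which
recombination uncouples the strong pair and killing shortens the observed
map distance; the mosaic presets segregate eight drivers (two against six)
across six loci with markers at the centromere-linked and distal assay loci.

`synth_count_table()` genotypes only viable spores (colonies are what the
assays score), drawing one multinomial sample from the enumeration
conditioned on viability. `synth_fertility()` multiplies the control
baseline by the model-predicted viable-output ratio and lognormal noise.
`fit_drive_strength()` inverts the single-driver transmission ratio:
t̂ = 1 − (non-driver count)/(driver count), clipped to [0, 1], with a
continuity-corrected Wilson interval on the underlying binomial proportion
mapped through the same transformation; at the study condition (t = 0.9,
5000 scored spores) the exact coverage of that interval is about 95%.

The generator reproduces the statistical structure the analysis assumes —
multinomial class counts with model-derived probabilities, positive noisy
yields — but not everything real data carry: no between-diploid
heterogeneity in *m* or *t*, no colony-scoring misclassification, no
aneuploid instability during colony growth, and fertility noise is
single-scale lognormal rather than assay-specific. Passing tests therefore
demonstrate the internal consistency of the pipeline and the identifiability
of its parameters under the stated model, not the fit of that model to any
particular empirical table.

## Problem sizes and numerical choices

Exact enumeration is limited to 8 loci (2^L patterns); the presets use at
most 6. The test suite samples 1e5 meioses per oracle-equivalence run
(20 seeds per scenario, independent seed streams per scenario), recovers
drive strength from 100 tables of 5000 spores, and tracks a 1e6-haploid
Wright–Fisher simulation for 50 generations against the recursion inside a
delta-method drift envelope. Censuses assert normalisation to 1e-12.
Chi-square components pool cells with expected counts below 5.

## Known limitations

Chromosomes 1 and 2 are not modelled (their aneuploidies are lethal and
their drivers rare); intragenic recombination within *wtf* genes,
molecular poison–antidote interactions, duplication fitness costs, and
linkage between the infidelity mutant and chromosome 3 are out of scope.
The recursion holds driver frequencies fixed at 1/*n*; it is not a model of
driver evolution itself, and finite-population drift enters only as a test
oracle.
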