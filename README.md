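# wtfdrive

Competing gamete-killing meiotic drivers and the fitness landscape of
fission-yeast meiosis.

## The problem

*Schizosaccharomyces pombe* genomes carry multiple *wtf* killer meiotic
drivers, nearly all on chromosome 3. Each *wtf* element encodes a poison that
attacks every developing spore of the ascus and an antidote that rescues only
the spores inheriting that element. Antidotes are specific: they do not
neutralise the poisons of diverged *wtf* genes. When two isolates outcross,
distinct drivers end up on opposite haplotypes and *compete*: a haploid spore
inherits one haplotype's drivers and is destroyed by the other's poisons.
Spores that inherit *both* chromosome-3 haplotypes — heterozygous disomes
produced by meiosis I nondisjunction, or haploids carrying a driver
duplication from an unequal crossover — carry every antidote and survive.
Driver competition therefore turns "mistakes" of meiosis into the fittest
products, and can favour mutations that degrade the fidelity of chromosome
segregation.

`wtfdrive` implements this model end to end, for geneticists studying drive
and for population geneticists exploring its evolutionary consequences:

* **Meiosis simulator** — exact enumeration (`enumerate_meiosis()`) and
  seeded Monte-Carlo sampling (`simulate_meioses()`) of single meioses with
  MI nondisjunction (probability *m*), per-interval recombination, unequal
  crossovers (probability *u*), and poison/antidote spore survival: a spore
  survives with probability Π over drivers of 1 (carries the matching
  antidote) or (1 − *t*), where *t* is the drive strength.
* **Invasion recursion** — a deterministic infinite-population model for a
  chromosome-segregation-infidelity mutant in a population segregating *n*
  equally frequent drivers of strength *t*, with missegregation level *f*,
  dominance *h*, and costs *s_m* (on the carrier) and *s_s* (on disomic
  spores). In the cost-free case a rare mutant invades exactly when
  *t* > *n* / (2(*n* − 1)) (`critical_drive_strength()`,
  `mutant_invades()`, `drive_trajectory()`, `phase_grid()`).
* **Assay statistics** — the computations applied to spore-count and
  fertility tables: disomy frequency, allele transmission with
  double-resistant spores excluded, likelihood-ratio G-tests, exact/normal
  Wilcoxon rank-sum tests, viable spore yield, relative fertility, disomes
  per plated cell, raw and Haldane map distances, and two-proportion power
  analysis.
* **Synthetic source data** — scenario presets mirroring the study designs
  (`scenario_library()`), multinomial genotype tables conditioned on
  viability (`synth_count_table()`), lognormal fertility replicates
  (`synth_fertility()`), and maximum-likelihood drive-strength recovery with
  Wilson intervals (`fit_drive_strength()`).

Results are tibbles; fitted objects support `tidy()`/`glance()` and
`autoplot()`.

## Worked example

A diploid heterozygous for two competing drivers at one locus (*t* = 0.95
each, *m* = 0.1, *u* = 0.01), summarised against a driver-free control:

```r
library(wtfdrive)

cross <- diploid_cross(
  hapA = haplotype(list(driver_allele("Sk_wtf4",  kill_prob = 0.95)), markers = "kanMX4"),
  hapB = haplotype(list(driver_allele("Sk_wtf28", kill_prob = 0.95)), markers = "hphMX6"),
  misseg_prob = 0.1, uneq_xo_prob = 0.01, dup_locus = 1
)
control <- diploid_cross(
  hapA = haplotype(list(NULL), markers = "kanMX4"),
  hapB = haplotype(list(NULL), markers = "hphMX6"), misseg_prob = 0.1
)
summarise_census(enumerate_meiosis(cross), reference = enumerate_meiosis(control))
#>   viable_fraction disomy_among_viable recombinant_fraction relative_fertility
#> 1          0.0970               0.515             0.000120              0.102
```

Only 9.7% of spores survive (10-fold fertility drop versus the control), and
half the survivors are heterozygous disomes — killing enriches atypical
spores without producing more of them.

The invasion model at the *t* = 0.95 anchor (threshold for *n* = 3 drivers is
0.75), starting from mutant frequency 0.1:

```r
glance(drive_trajectory(model_params(n = 3, t = 0.95)))
#>   outcome generations p_final n    t     f   h   s_m s_s  p0  t_critical
#> 1 fixed   110         1.000   3  0.95     1 0.5     0   0 0.1       0.75
```

Drive-strength recovery from a synthetic 5000-spore genotyping table of a
single-driver heterozygote simulated at *t* = 0.9:

```r
tbl <- synth_count_table(single_driver_scenario(t = 0.9, n_spores = 5000), seed = 42)
glance(fit_drive_strength(tbl))
#>   n_diploids n_driver n_nondriver estimate conf.low conf.high
#> 1          1     4153         413    0.901    0.890     0.910
```

The estimate is `1 - 413/4153 = 0.901`; the interval is a Wilson score
interval on the driver-transmission proportion mapped to the drive-strength
scale.

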