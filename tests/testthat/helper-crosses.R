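# Small crosses built in code and shared across tests.

# One locus, distinct drivers on each haplotype (competing pair).
het_pair_cross <- function(t1 = 1, t2 = 1, m = 0, u = 0,
                           antidote = TRUE) {
  diploid_cross(
    hapA = haplotype(list(driver_allele("A", t1, has_antidote = antidote)),
                     markers = "kanMX4"),
    hapB = haplotype(list(driver_allele("B", t2, has_antidote = antidote)),
                     markers = "hphMX6"),
    misseg_prob = m, uneq_xo_prob = u, dup_locus = 1
  )
}

# Marked cross with no drivers.
no_driver_cross <- function(m = 0, r = 0, n_loci = 1) {
  markA <- c("ade6+", "ura4+", "lys1+")[seq_len(n_loci)]
  markB <- c("hphMX6", "ura4-", "lys1-")[seq_len(n_loci)]
  diploid_cross(
    hapA = haplotype(rep(list(NULL), n_loci), markers = markA),
    hapB = haplotype(rep(list(NULL), n_loci), markers = markB),
    map = genetic_map(rep(r, n_loci)),
    misseg_prob = m
  )
}

# Two loci, one competing driver pair per locus (four distinct ids).
two_locus_pair_cross <- function(tA = 1, tB = 1, m = 0, r = 0.2) {
  diploid_cross(
    hapA = haplotype(list(driver_allele("A1", tA), driver_allele("A2", tA)),
                     markers = c("natMX4", "ura4+")),
    hapB = haplotype(list(driver_allele("B1", tB), driver_allele("B2", tB)),
                     markers = c("hphMX6", "ura4-")),
    map = genetic_map(c(0.01, r)),
    misseg_prob = m
  )
}

viable_fraction_of <- function(cross) {
  summarise_census(enumerate_meiosis(cross))$viable_fraction
}
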