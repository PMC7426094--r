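test_that("spore survival follows the poison/antidote product rule", {
  cross <- het_pair_cross(t1 = 1, t2 = 1)
  # haploid lacking driver B is destroyed by B's poison
  expect_equal(
    spore_survival_probability(list(allele_ids = "A", chr3_copies = 1), cross), 0)
  # disome inheriting both competing drivers carries both antidotes
  expect_equal(
    spore_survival_probability(list(allele_ids = c("A", "B"), chr3_copies = 2), cross), 1)
  # nullisomes are inviable regardless of drivers
  expect_equal(
    spore_survival_probability(list(allele_ids = character(), chr3_copies = 0), cross), 0)
  # no poison acts when all kill probabilities are zero
  cross0 <- het_pair_cross(t1 = 0, t2 = 0)
  expect_equal(
    spore_survival_probability(list(allele_ids = character(), chr3_copies = 1), cross0), 1)
  # partial drive: product rule gives 1 - kill_prob per missing antidote
  cross9 <- het_pair_cross(t1 = 0.9, t2 = 0.8)
  expect_equal(
    spore_survival_probability(list(allele_ids = "A", chr3_copies = 1), cross9), 0.2)
  expect_equal(
    spore_survival_probability(list(allele_ids = character(), chr3_copies = 1), cross9),
    0.1 * 0.2)
  # poison-only alleles kill carriers too
  po <- het_pair_cross(t1 = 0.9, t2 = 0.9, antidote = FALSE)
  expect_equal(
    spore_survival_probability(list(allele_ids = "A", chr3_copies = 1), po),
    0.1 * 0.1)
  # unknown allele id is a configuration error
  expect_error(
    spore_survival_probability(list(allele_ids = "Z", chr3_copies = 1), cross),
    "unknown")
})

test_that("partial-drive survival matches Monte-Carlo frequency", {
  # single heterozygous driver, kill 0.9: non-driver haploids survive at 0.1
  cross <- diploid_cross(
    hapA = haplotype(list(driver_allele("A", 0.9)), markers = "kanMX4"),
    hapB = haplotype(list(NULL), markers = "hphMX6")
  )
  sim <- simulate_meioses(cross, 1e5, seed = 11)
  nd <- sim$phenotype == "hphMX6"
  n_tot <- sum(sim$count[nd])
  phat <- sum(sim$count[nd & sim$viable]) / n_tot
  se <- sqrt(0.1 * 0.9 / n_tot)
  expect_lt(abs(phat - 0.1), 3 * se)
})

test_that("exact censuses are normalised and reproduce hand-computed cases", {
  # perfect competing pair, no missegregation: every spore dies
  expect_equal(viable_fraction_of(het_pair_cross(1, 1, m = 0)), 0)
  s0 <- summarise_census(enumerate_meiosis(het_pair_cross(1, 1, m = 0)))
  expect_true(s0$undefined)
  expect_true(is.na(s0$disomy_among_viable))

  # with missegregation the only survivors are heterozygous disomes
  s <- summarise_census(enumerate_meiosis(het_pair_cross(1, 1, m = 0.05)))
  expect_equal(s$disomy_among_viable, 1)
  expect_equal(s$viable_fraction, 0.05 / 2)

  # no drivers: disomy among viable = m / (2 - m)
  s2 <- summarise_census(enumerate_meiosis(no_driver_cross(m = 0.05)))
  expect_equal(s2$disomy_among_viable, 0.05 / (2 - 0.05))

  # probabilities sum to one for a spread of configurations
  for (cross in list(het_pair_cross(0.7, 0.9, m = 0.1, u = 0.02),
                     no_driver_cross(m = 0.3, r = 0.2, n_loci = 2),
                     two_locus_pair_cross(0.95, 0.6, m = 0.1, r = 0.3))) {
    expect_equal(sum(enumerate_meiosis(cross)$prob), 1, tolerance = 1e-12)
  }
})

test_that("transmission among viable haploids matches the drive expectations", {
  # no drive: 50% per marker
  s <- summarise_census(enumerate_meiosis(no_driver_cross(m = 0)))
  expect_equal(s$transmission[[1]]$transmission, c(0.5, 0.5))

  # single heterozygous driver with kill 1: 100% driver-linked transmission
  cross <- diploid_cross(
    hapA = haplotype(list(driver_allele("A", 1)), markers = "kanMX4"),
    hapB = haplotype(list(NULL), markers = "hphMX6"),
    misseg_prob = 0.05
  )
  tr <- summarise_census(enumerate_meiosis(cross))$transmission[[1]]
  expect_equal(tr$transmission[tr$marker == "kanMX4"], 1)

  # symmetric competing pair: 50% among surviving haploids
  tr2 <- summarise_census(enumerate_meiosis(het_pair_cross(0.9, 0.9, m = 0.1)))$transmission[[1]]
  expect_equal(tr2$transmission, c(0.5, 0.5))

  # transmission of the two markers at a locus always sums to 1
  tr3 <- summarise_census(enumerate_meiosis(two_locus_pair_cross(0.95, 0.6, m = 0.1)))$transmission[[1]]
  sums <- as.numeric(tapply(tr3$transmission, tr3$locus, sum))
  expect_equal(sums, rep(1, length(sums)))
})

test_that("viable fraction is non-increasing in every kill probability", {
  for (t2 in c(0, 0.5, 1)) {
    vf <- vapply(seq(0, 1, by = 0.25), function(t1) {
      viable_fraction_of(het_pair_cross(t1, t2, m = 0.1))
    }, numeric(1))
    expect_true(all(diff(vf) <= 1e-12))
  }
})

test_that("rec12 deletion silences recombination and unequal crossovers", {
  cross <- diploid_cross(
    hapA = haplotype(list(driver_allele("A", 0.9), NULL),
                     markers = c("natMX4", "ura4+")),
    hapB = haplotype(list(driver_allele("B", 0.9), NULL),
                     markers = c("hphMX6", "ura4-")),
    map = genetic_map(c(0.1, 0.3), rec12_active = FALSE),
    misseg_prob = 0.1, uneq_xo_prob = 0.05, dup_locus = 1
  )
  cen <- enumerate_meiosis(cross)
  s <- summarise_census(cen)
  expect_equal(s$recombinant_fraction, 0)
  expect_false(any(cen$klass %in% c("haploid_recombinant", "haploid_duplication")))
  # haploids transmit parental marker combinations intact
  hap <- cen[cen$chr3_copies == 1, ]
  expect_true(all(hap$phenotype %in% c("natMX4/ura4+", "hphMX6/ura4-")))
})

test_that("unequal crossovers create duplication and marker-less products", {
  cross <- het_pair_cross(0.95, 0.95, m = 0.1, u = 0.02)
  cen <- enumerate_meiosis(cross)
  dup <- cen[cen$klass == "haploid_duplication" & cen$viable, ]
  # the duplication haploid carries both antidotes and survives outright
  expect_equal(sum(dup$prob), (1 - 0.1) * 0.02 / 4)
  expect_equal(dup$phenotype, "hphMX6/kanMX4")
  # its reciprocal lacks both drivers and both markers
  recip <- cen[cen$klass == "haploid_recombinant", ]
  expect_true(all(recip$phenotype == "no-marker"))
  expect_equal(sum(recip$prob), (1 - 0.1) * 0.02 / 4)
})

test_that("poison-only heterozygotes cut yield without reshaping survivors", {
  control <- no_driver_cross(m = 0.1)
  po <- het_pair_cross(0.95, 0.95, m = 0.1, antidote = FALSE)
  s_ctrl <- summarise_census(enumerate_meiosis(control))
  s_po <- summarise_census(enumerate_meiosis(po), reference = enumerate_meiosis(control))
  expect_lt(s_po$viable_fraction, s_ctrl$viable_fraction)
  # survival is genotype-independent, so disomy among survivors is unchanged
  expect_identical(s_po$disomy_among_viable, s_ctrl$disomy_among_viable)
  expect_equal(s_po$relative_fertility, (1 - 0.95)^2)
})

test_that("cross construction rejects invalid configurations", {
  expect_error(driver_allele("", 0.5), "non-empty")
  expect_error(driver_allele("A", 1.5), "probability")
  expect_error(haplotype(list(list(driver_allele("A"), driver_allele("A")))),
               "same id")
  expect_error(
    diploid_cross(haplotype(list(NULL)), haplotype(list(NULL, NULL))),
    "same locus list")
  expect_error(
    diploid_cross(haplotype(list(NULL)), haplotype(list(NULL)),
                  uneq_xo_prob = 0.1),
    "dup_locus")
  expect_error(genetic_map(0.7), "0.5")
})
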