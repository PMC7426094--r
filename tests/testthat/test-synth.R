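test_that("the scenario library covers the study's cross designs", {
  lib <- scenario_library()
  expect_gte(length(lib), 6)
  needed <- c("control_two_locus", "double_driver", "single_locus_double_driver",
              "mosaic_rec12d", "mosaic_rec12", "poison_only", "single_driver")
  expect_true(all(needed %in% names(lib)))
  # every driver scenario names a control that exists in the library
  for (s in lib) {
    if (!is.na(s$control)) expect_true(s$control %in% names(lib))
  }
  # rec12-deleted scenarios carry no effective recombination
  expect_false(lib$mosaic_rec12d$cross$map$rec12_active)
  expect_true(all(lib$mosaic_rec12d$cross$map$rec_fractions == 0))
  # the two-locus double driver segregates four distinct driver ids
  ids <- vapply(cross_alleles <- c(
    unlist(lib$double_driver$cross$hapA$alleles, recursive = FALSE),
    unlist(lib$double_driver$cross$hapB$alleles, recursive = FALSE)
  ), `[[`, character(1), "id")
  expect_length(unique(ids), 4)
  # mosaic diploids are heterozygous for eight drivers
  mos <- lib$mosaic_rec12$cross
  n_drivers <- length(unlist(mos$hapA$alleles, recursive = FALSE)) +
    length(unlist(mos$hapB$alleles, recursive = FALSE))
  expect_equal(n_drivers, 8)
})

test_that("synthetic count tables are reproducible and track the exact model", {
  lib <- scenario_library()
  s <- lib$single_locus_double_driver
  expect_identical(synth_count_table(s, seed = 3), synth_count_table(s, seed = 3))
  expect_false(identical(synth_count_table(s, seed = 3), synth_count_table(s, seed = 4)))

  # control disomy converges to m / (2 - m)
  ctrl <- lib$control_single_locus
  ctrl$n_spores <- 1e5L
  tbl <- synth_count_table(ctrl, seed = 9)
  p <- 0.1 / (2 - 0.1)
  dis <- disomy_frequency(tbl)
  # both_markers also catches rare duplication haploids; allow their mass
  dup_extra <- 0.9 * 0.01 / 4 / summarise_census(enumerate_meiosis(ctrl$cross))$viable_fraction
  se <- sqrt(p * (1 - p) / dis$n_total)
  expect_lt(abs(dis$disomy - (p + dup_extra)), 3 * se + 1e-3)

  # perfect competing drivers: essentially every genotyped spore is disomic
  perfect <- scenario("perfect", het_pair_cross(1, 1, m = 0.1), n_spores = 2000)
  expect_equal(disomy_frequency(synth_count_table(perfect, seed = 2))$disomy, 1)

  # a no-survivor scenario is an explicit error, not an empty table
  dead <- scenario("dead", het_pair_cross(1, 1, m = 0))
  expect_error(synth_count_table(dead, seed = 1), "no viable spores")
})

test_that("synthetic fertility follows baseline x predicted ratio x noise", {
  lib <- scenario_library()
  s <- lib$single_locus_double_driver
  ctrl <- lib$control_single_locus
  # zero noise: replicates equal the model prediction exactly
  s0 <- s; s0$sigma <- 0
  ft <- synth_fertility(s0, ctrl, n_reps = 4, seed = 1)
  ratio <- summarise_census(enumerate_meiosis(s$cross))$viable_fraction /
    summarise_census(enumerate_meiosis(ctrl$cross))$viable_fraction
  expect_equal(ft$yield, rep(s$baseline * ratio, 4))
  # the double-driver fertility cannot exceed its disome production rate:
  # with kill 1 all haploids die, so output is bounded by the disome supply
  perfect <- scenario("perfect", het_pair_cross(1, 1, m = 0.1))
  expect_lte(summarise_census(enumerate_meiosis(perfect$cross))$viable_fraction /
               summarise_census(enumerate_meiosis(ctrl$cross))$viable_fraction,
             0.1 / 2 / summarise_census(enumerate_meiosis(ctrl$cross))$viable_fraction)
  # reproducibility and positivity
  expect_identical(synth_fertility(s, ctrl, seed = 5), synth_fertility(s, ctrl, seed = 5))
  expect_true(all(synth_fertility(s, ctrl, seed = 5)$yield > 0))
})

test_that("assay statistics on synthetic tables converge to enumeration", {
  lib <- scenario_library()
  for (nm in c("control_single_locus", "single_locus_double_driver", "mosaic_rec12d")) {
    s <- lib[[nm]]
    s$n_spores <- 5e4L
    tbl <- synth_count_table(s, seed = 21)
    cen <- enumerate_meiosis(s$cross)
    pair <- c(A = s$cross$hapA$markers[s$assay_locus],
              B = s$cross$hapB$markers[s$assay_locus])
    # transmission among single-marker haploids matches the census summary
    tr_emp <- allele_transmission(tbl, pair[["A"]])$transmission
    tr_exact <- summarise_census(cen)$transmission[[1]]
    tr_exact <- tr_exact$transmission[tr_exact$marker == pair[["A"]]]
    n_hap <- allele_transmission(tbl, pair[["A"]])$n_haploid
    if (n_hap > 50) {
      se <- sqrt(tr_exact * (1 - tr_exact) / n_hap)
      expect_lt(abs(tr_emp - tr_exact), 3 * se + 1e-3)
    }
  }
})

test_that("drive strength recovery is unbiased with honest intervals", {
  # moderate-scale check across the drive-strength grid (the acceptance test
  # runs the full 100-seed study at t = 0.9)
  for (t in c(0.5, 0.7, 0.9, 0.99)) {
    sc <- single_driver_scenario(t = t, n_spores = 2000)
    fits <- lapply(1:40, function(s) glance(fit_drive_strength(synth_count_table(sc, s))))
    est <- vapply(fits, `[[`, numeric(1), "estimate")
    covered <- vapply(fits, function(f) f$conf.low <= t && t <= f$conf.high, logical(1))
    se_mean <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - t), 3 * se_mean + 0.005)
    expect_gte(mean(covered), 0.85)
  }
  # degenerate tables
  tbl <- tibble::tibble(diploid = "d", kanMX4 = 100L, hphMX6 = 100L)
  expect_equal(fit_drive_strength(tbl, driver = "kanMX4", nondriver = "hphMX6")$estimate, 0)
  tbl2 <- tibble::tibble(diploid = "d", kanMX4 = 100L, hphMX6 = 0L)
  expect_equal(fit_drive_strength(tbl2, driver = "kanMX4", nondriver = "hphMX6")$estimate, 1)
  tbl3 <- tibble::tibble(diploid = "d", kanMX4 = 0L, hphMX6 = 50L)
  fit3 <- fit_drive_strength(tbl3, driver = "kanMX4", nondriver = "hphMX6")
  expect_true(fit3$undefined)
  expect_true(is.na(fit3$estimate))
})
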