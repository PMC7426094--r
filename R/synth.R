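# Scenario presets and source-data-shaped synthetic tables. The presets mirror
# the study's cross designs: a two-locus marker control, double-driver
# heterozygotes, Sp/Sk mosaic diploids with and without Rec12, poison-only
# heterozygotes, and a single heterozygous driver. Default rates are fixed
# once: kill_prob 0.95 (drive strength is generally high, > 0.9),
# misseg_prob 0.1 (chromosome 3 missegregates in about one meiosis in ten,
# giving ~5% disomy among viable spores of a no-drive control), 300 scored
# spores per diploid, lognormal fertility noise with sigma 0.3 on a baseline
# of 2 viable spores per plated cell (arbitrary units).

#' Build a named scenario
#'
#' A scenario bundles a [diploid_cross()] with the sampling parameters of the
#' synthetic assays: how many viable spores are genotyped, the fertility
#' baseline of its control, the lognormal noise scale, and the name of its
#' matched no-driver control in the library.
#'
#' @param name Scenario name.
#' @param cross A [diploid_cross()].
#' @param n_spores Viable spores genotyped per diploid (>= 1).
#' @param baseline Control-scale viable spore yield (arbitrary units).
#' @param sigma Lognormal noise scale for fertility replicates (>= 0).
#' @param control Name of the matched control scenario, or `NA`.
#' @param assay_locus Locus index whose markers define the count-table classes
#'   (default: first marked locus).
#' @return An object of class `drive_scenario`.
#' @export
scenario <- function(name, cross, n_spores = 300, baseline = 2, sigma = 0.3,
                     control = NA_character_, assay_locus = NULL) {
  if (!inherits(cross, "diploid_cross")) abort("`cross` must be a diploid_cross.")
  if (n_spores < 1) abort("`n_spores` must be >= 1.")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (is.null(assay_locus)) {
    marked <- which(!is.na(cross$hapA$markers) & !is.na(cross$hapB$markers))
    if (length(marked) == 0) abort("The cross has no marked locus to assay.")
    assay_locus <- marked[1]
  }
  structure(list(name = name, cross = cross, n_spores = as.integer(n_spores),
                 baseline = baseline, sigma = sigma, control = control,
                 assay_locus = assay_locus),
            class = "drive_scenario")
}

#' @export
print.drive_scenario <- function(x, ...) {
  cat(sprintf("<drive_scenario> %s (control: %s, n_spores = %d)\n",
              x$name, x$control, x$n_spores))
  print(x$cross)
  invisible(x)
}

mk_hap <- function(ids, kill, antidote, markers, n_loci) {
  al <- vector("list", n_loci)
  for (i in seq_along(ids)) {
    if (!is.na(ids[[i]]) && nzchar(ids[[i]])) {
      al[[i]] <- driver_allele(ids[[i]], kill[[i]], antidote[[i]])
    }
  }
  haplotype(al, markers)
}

#' A single heterozygous driver cross
#'
#' One *wtf* driver (with antidote) on one haplotype at a marked locus, no
#' driver opposite — the configuration whose transmission ratio among viable
#' haploids identifies the drive strength.
#'
#' @param t Drive strength of the heterozygous driver.
#' @param m MI nondisjunction probability.
#' @param n_spores Viable spores genotyped.
#' @return A `drive_scenario` whose matched control is `"control_single_locus"`.
#' @export
single_driver_scenario <- function(t = 0.95, m = 0.1, n_spores = 300) {
  cross <- diploid_cross(
    hapA = haplotype(list(driver_allele("wtf4", t)), markers = "kanMX4"),
    hapB = haplotype(list(NULL), markers = "hphMX6"),
    misseg_prob = m
  )
  scenario("single_driver", cross, n_spores = n_spores,
           control = "control_single_locus")
}

#' Library of preset cross scenarios
#'
#' Named presets mirroring the study's designs, each with a matched no-driver
#' control: a two-locus marker control; a two-locus double-driver heterozygote
#' (four distinct driver ids, the two strongest on one haplotype so
#' recombination can uncouple them); a single-locus double-driver heterozygote
#' with unequal crossovers; Sp/Sk-style mosaic diploids heterozygous for eight
#' drivers, with Rec12 present or deleted, plus a driver-deletion variant; a
#' poison-only heterozygote; and a single heterozygous driver.
#'
#' @param kill_prob Default drive strength of preset drivers.
#' @param m Default MI nondisjunction probability.
#' @param n_spores Viable spores genotyped per diploid.
#' @return A named list of `drive_scenario` objects.
#' @examples
#' names(scenario_library())
#' @export
scenario_library <- function(kill_prob = 0.95, m = 0.1, n_spores = 300) {
  lib <- list()
  add <- function(s) lib[[s$name]] <<- s

  # --- two-locus background: ade6-linked locus then ura4, ~0.39 recombinant
  # fraction between them (75 cM by Haldane in the no-driver control)
  map2 <- genetic_map(c(0.01, 0.39))
  ctrl2 <- diploid_cross(
    hapA = mk_hap(list(NA, NA), list(NA, NA), list(NA, NA),
                  c("natMX4", "ura4+"), 2),
    hapB = mk_hap(list(NA, NA), list(NA, NA), list(NA, NA),
                  c("hphMX6", "ura4-"), 2),
    map = map2, misseg_prob = m
  )
  add(scenario("control_two_locus", ctrl2, n_spores = n_spores))

  dd <- diploid_cross(
    hapA = mk_hap(list("wtf13", "wtf35"), list(0.98, 0.98), list(TRUE, TRUE),
                  c("natMX4", "ura4+"), 2),
    hapB = mk_hap(list("wtf36", "wtf19"), list(0.70, 0.70), list(TRUE, TRUE),
                  c("hphMX6", "ura4-"), 2),
    map = map2, misseg_prob = m
  )
  add(scenario("double_driver", dd, n_spores = n_spores,
               control = "control_two_locus"))

  # --- single-locus background (drivers or empty vectors at ade6)
  ctrl1 <- diploid_cross(
    hapA = haplotype(list(NULL), markers = "kanMX4"),
    hapB = haplotype(list(NULL), markers = "hphMX6"),
    misseg_prob = m, uneq_xo_prob = 0.01, dup_locus = 1,
    map = genetic_map(0.01)
  )
  add(scenario("control_single_locus", ctrl1, n_spores = n_spores))

  sd1 <- diploid_cross(
    hapA = haplotype(list(driver_allele("wtf4", kill_prob)), markers = "kanMX4"),
    hapB = haplotype(list(driver_allele("wtf28", kill_prob)), markers = "hphMX6"),
    misseg_prob = m, uneq_xo_prob = 0.01, dup_locus = 1,
    map = genetic_map(0.01)
  )
  add(scenario("single_locus_double_driver", sd1, n_spores = n_spores,
               control = "control_single_locus"))

  po <- diploid_cross(
    hapA = haplotype(list(driver_allele("wtf28_poison", kill_prob, has_antidote = FALSE)),
                     markers = "kanMX4"),
    hapB = haplotype(list(driver_allele("wtf4_poison", kill_prob, has_antidote = FALSE)),
                     markers = "hphMX6"),
    misseg_prob = m, uneq_xo_prob = 0.01, dup_locus = 1,
    map = genetic_map(0.01)
  )
  add(scenario("poison_only", po, n_spores = n_spores,
               control = "control_single_locus"))

  add(single_driver_scenario(t = kill_prob, m = m, n_spores = n_spores))

  # --- mosaic background: 6 chromosome-3 loci; Sp haplotype carries 2 drivers,
  # Sk haplotype 6; markers at the ade6-linked locus 1 and at ura4 (locus 4)
  mosaic_haps <- function(sp_drivers = c("Sp_wtf4", "Sp_wtf13")) {
    spA <- list(NA, NA, NA, NA, NA, NA)
    if ("Sp_wtf4" %in% sp_drivers) spA[[2]] <- "Sp_wtf4"
    if ("Sp_wtf13" %in% sp_drivers) spA[[5]] <- "Sp_wtf13"
    hapA <- mk_hap(spA, rep(list(kill_prob), 6), rep(list(TRUE), 6),
                   c("ade6+", NA, NA, "ura4+", NA, NA), 6)
    hapB <- mk_hap(as.list(paste0("Sk_wtf", 1:6)), rep(list(kill_prob), 6),
                   rep(list(TRUE), 6),
                   c("hphMX6", NA, NA, "ura4-", NA, NA), 6)
    list(A = hapA, B = hapB)
  }
  map_r0 <- genetic_map(rep(0, 6), rec12_active = FALSE)
  map_r1 <- genetic_map(c(0.02, rep(0.08, 5)))

  h <- mosaic_haps()
  add(scenario("mosaic_rec12d",
               diploid_cross(h$A, h$B, map = map_r0, misseg_prob = m),
               n_spores = n_spores, control = "control_mosaic_rec12d"))
  add(scenario("mosaic_rec12",
               diploid_cross(h$A, h$B, map = map_r1, misseg_prob = m),
               n_spores = n_spores, control = "control_mosaic_rec12"))

  hdel <- mosaic_haps(sp_drivers = character())
  add(scenario("mosaic_rec12_wtfdel",
               diploid_cross(hdel$A, hdel$B, map = map_r1, misseg_prob = m),
               n_spores = n_spores, control = "control_mosaic_rec12"))

  ctrl_mos <- function(map) {
    diploid_cross(
      hapA = mk_hap(rep(list(NA), 6), rep(list(NA), 6), rep(list(NA), 6),
                    c("ade6+", NA, NA, "ura4+", NA, NA), 6),
      hapB = mk_hap(rep(list(NA), 6), rep(list(NA), 6), rep(list(NA), 6),
                    c("hphMX6", NA, NA, "ura4-", NA, NA), 6),
      map = map, misseg_prob = m
    )
  }
  add(scenario("control_mosaic_rec12d", ctrl_mos(map_r0), n_spores = n_spores))
  add(scenario("control_mosaic_rec12", ctrl_mos(map_r1), n_spores = n_spores))

  lib
}

census_classes <- function(markers_list, pair) {
  side <- marker_at(markers_list, pair)
  cls <- c(A = unname(pair[["A"]]), B = unname(pair[["B"]]),
           both = "both_markers", none = "no_marker")
  unname(cls[side])
}

#' Synthetic spore genotype count table
#'
#' Genotypes `n_spores` viable spores of the scenario's cross: class
#' probabilities come from [enumerate_meiosis()] conditioned on viability
#' (only viable spores grow into scoreable colonies), and counts are one
#' multinomial draw. Classes are the marker phenotypes at the scenario's assay
#' locus: one column per single marker, a `both_markers` (disomic /
#' duplication) column, and a `no_marker` column.
#'
#' @param scenario A `drive_scenario`.
#' @param seed Integer seed.
#' @return A one-row count table tibble carrying its schema as the
#'   `count_schema` attribute, ready for [disomy_frequency()] and friends.
#' @examples
#' lib <- scenario_library()
#' synth_count_table(lib$single_locus_double_driver, seed = 1)
#' @export
synth_count_table <- function(scenario, seed) {
  if (!inherits(scenario, "drive_scenario")) abort("`scenario` must be a drive_scenario.")
  census <- enumerate_meiosis(scenario$cross)
  pair <- attr(census, "marker_pairs")[[scenario$assay_locus]]
  viable <- census[census$viable, ]
  if (nrow(viable) == 0 || sum(viable$prob) <= 0) {
    abort(sprintf("Scenario '%s' produces no viable spores: empty table.", scenario$name))
  }
  cls <- census_classes(viable$markers, pair)
  probs <- tapply(viable$prob, cls, sum)
  all_cls <- c(unname(pair), "both_markers", "no_marker")
  p <- setNames(numeric(length(all_cls)), all_cls)
  p[names(probs)] <- probs
  counts <- withr::with_seed(as.integer(seed),
                             as.vector(rmultinom(1, scenario$n_spores, p)))
  tbl <- as_tibble(c(list(diploid = scenario$name),
                     setNames(as.list(as.integer(counts)), all_cls)))
  attr(tbl, "count_schema") <- list(single = unname(pair), double = "both_markers",
                                    no_marker = "no_marker", id = "diploid")
  tbl
}

#' Synthetic viable-spore-yield replicates
#'
#' Fertility replicates drawn as `baseline * predicted relative viable output *
#' lognormal noise`, where the predicted ratio is the scenario's viable spore
#' fraction over its control's (from exact enumeration) and the noise is
#' `exp(rnorm(0, sigma))`. With `sigma = 0` the replicates equal the predicted
#' value exactly.
#'
#' @param scenario A `drive_scenario`.
#' @param control_scenario Its matched control (`NULL` for a ratio of 1).
#' @param n_reps Number of replicates (>= 3).
#' @param seed Integer seed.
#' @return A tibble `diploid`, `replicate`, `yield` (positive values).
#' @export
synth_fertility <- function(scenario, control_scenario = NULL, n_reps = 6, seed) {
  if (!inherits(scenario, "drive_scenario")) abort("`scenario` must be a drive_scenario.")
  if (n_reps < 3) abort("`n_reps` must be >= 3.")
  vf <- summarise_census(enumerate_meiosis(scenario$cross))$viable_fraction
  ratio <- if (is.null(control_scenario)) 1 else {
    vf0 <- summarise_census(enumerate_meiosis(control_scenario$cross))$viable_fraction
    if (vf0 <= 0) abort("Control scenario has no viable spores.")
    vf / vf0
  }
  yields <- withr::with_seed(as.integer(seed), {
    scenario$baseline * ratio * exp(rnorm(n_reps, 0, scenario$sigma))
  })
  tibble(diploid = scenario$name, replicate = seq_len(n_reps), yield = yields)
}

# Wilson score interval with continuity correction (slightly conservative).
wilson_interval <- function(x, n, conf.level = 0.95) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  p <- x / n
  lower <- if (x == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) / (2 * (n + z^2))
  }
  upper <- if (x == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) / (2 * (n + z^2))
  }
  c(lower = max(0, min(lower, p)), upper = min(1, max(upper, p)))
}

#' Estimate drive strength from a count table
#'
#' Maximum-likelihood kill probability of a single heterozygous driver from
#' the transmission ratio among viable haploids: with driver-linked count `d`
#' and opposite-marker count `w`, `t_hat = 1 - w / d`, clipped to \[0, 1\].
#' The confidence interval is a Wilson score interval on the binomial
#' proportion `d / (d + w)`, transformed to the drive-strength scale.
#'
#' @param tbl A genotype count table (one or more diploid rows).
#' @param driver Name of the driver-linked single-marker class column. Default:
#'   the first single-marker class of the table's schema.
#' @param nondriver Name of the opposite single-marker class column.
#' @param conf.level Confidence level of the interval.
#' @param id Diploid identifier column.
#' @return A `drive_fit` tibble: one row per diploid with `n_driver`,
#'   `n_nondriver`, `estimate`, `conf.low`, `conf.high`, `undefined` (`TRUE`
#'   when the driver class is empty). [tidy()] returns it as a plain tibble;
#'   [glance()] gives the pooled estimate across rows.
#' @examples
#' fit_drive_strength(synth_count_table(single_driver_scenario(t = 0.9), seed = 1))
#' @export
fit_drive_strength <- function(tbl, driver = NULL, nondriver = NULL,
                               conf.level = 0.95, id = NULL) {
  sch <- schema_of(tbl, NULL, NULL, NULL, id)
  if (length(sch$single) < 2 && (is.null(driver) || is.null(nondriver))) {
    abort("Name the `driver` and `nondriver` single-marker columns.")
  }
  driver <- driver %||% sch$single[1]
  nondriver <- nondriver %||% setdiff(sch$single, driver)[1]
  d <- tbl[[driver]]
  w <- tbl[[nondriver]]
  n <- d + w
  est <- ifelse(d > 0, pmin(pmax(1 - w / d, 0), 1), NA_real_)
  lo <- hi <- rep(NA_real_, length(d))
  t_of_q <- function(q) pmin(pmax(ifelse(q > 0, 2 - 1 / q, 0), 0), 1)
  for (i in seq_along(d)) {
    if (d[i] > 0 && n[i] > 0) {
      ci <- wilson_interval(d[i], n[i], conf.level)
      lo[i] <- t_of_q(ci[["lower"]])
      hi[i] <- t_of_q(ci[["upper"]])
    }
  }
  out <- tibble(
    !!sch$id := tbl[[sch$id]],
    n_driver = d, n_nondriver = w,
    estimate = est, conf.low = lo, conf.high = hi,
    undefined = d == 0
  )
  structure(out, class = c("drive_fit", class(tibble())),
            conf.level = conf.level, driver = driver, nondriver = nondriver)
}

#' @rdname fit_drive_strength
#' @param x A `drive_fit` object.
#' @param ... Unused.
#' @method tidy drive_fit
#' @export
tidy.drive_fit <- function(x, ...) as_tibble(x)

#' @rdname fit_drive_strength
#' @method glance drive_fit
#' @export
glance.drive_fit <- function(x, ...) {
  d <- sum(x$n_driver); w <- sum(x$n_nondriver)
  est <- if (d > 0) min(max(1 - w / d, 0), 1) else NA_real_
  ci <- if (d > 0) wilson_interval(d, d + w, attr(x, "conf.level")) else
    c(lower = NA_real_, upper = NA_real_)
  t_of_q <- function(q) min(max(if (!is.na(q) && q > 0) 2 - 1 / q else 0, 0), 1)
  tibble(n_diploids = nrow(x), n_driver = d, n_nondriver = w,
         estimate = est, conf.low = t_of_q(ci[["lower"]]),
         conf.high = t_of_q(ci[["upper"]]))
}
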