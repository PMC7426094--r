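# Statistics computed on spore genotype count tables and fertility replicate
# tables shaped like the study's source-data files: one row per diploid,
# one column per marker-phenotype class.

schema_of <- function(tbl, single, double, no_marker, id) {
  sch <- attr(tbl, "count_schema")
  list(
    single = single %||% sch$single %||%
      setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
              c(double %||% sch$double, no_marker %||% sch$no_marker)),
    double = double %||% sch$double,
    no_marker = no_marker %||% sch$no_marker,
    id = id %||% sch$id %||% "diploid"
  )
}

count_cols <- function(tbl, sch) {
  cols <- c(sch$single, sch$double, sch$no_marker)
  missing <- setdiff(cols, names(tbl))
  if (length(missing)) {
    abort(sprintf("Count table lacks class columns: %s", paste(missing, collapse = ", ")))
  }
  cols
}

#' Disomy frequency per diploid
#'
#' Fraction of all scored viable spores showing both centromere-linked markers
#' (the double-resistant class): these are heterozygous aneuploid or diploid
#' spores (plus, at a single assayed locus, rare haploids carrying a driver
#' duplication).
#'
#' @param tbl A genotype count table: one row per diploid, numeric class-count
#'   columns. Tables written by [synth_count_table()] or read by
#'   [read_count_table()] carry their schema and need no column arguments.
#' @param single Character vector naming the single-marker class columns.
#' @param double Name of the double-marker class column.
#' @param no_marker Optional name of the marker-less class column.
#' @param id Name of the diploid identifier column.
#' @return A tibble with one row per diploid: `n_total`, `n_double`, `disomy`,
#'   and `undefined` (`TRUE` when no spores were scored).
#' @examples
#' tbl <- tibble::tibble(diploid = "d1", `Ade+HygS` = 48, `Ade-HygR` = 48,
#'                       `Ade+HygR` = 4)
#' disomy_frequency(tbl, single = c("Ade+HygS", "Ade-HygR"), double = "Ade+HygR")
#' @export
disomy_frequency <- function(tbl, single = NULL, double = NULL,
                             no_marker = NULL, id = NULL) {
  sch <- schema_of(tbl, single, double, no_marker, id)
  if (is.null(sch$double)) abort("A `double` (double-marker) class column is required.")
  cols <- count_cols(tbl, sch)
  total <- rowSums(tbl[cols])
  tibble(
    !!sch$id := tbl[[sch$id]],
    n_total = total,
    n_double = tbl[[sch$double]],
    disomy = ifelse(total > 0, tbl[[sch$double]] / total, NA_real_),
    undefined = total == 0
  )
}

#' Allele transmission per diploid
#'
#' Fraction of viable spores inheriting a given marker, among spores carrying
#' exactly one of the locus's markers: double-marker (disomic/duplication) and
#' marker-less classes are excluded from the denominator, following the
#' scoring convention of the source data. 50% is the Mendelian expectation; a
#' significant excess indicates drive favouring the overrepresented allele.
#'
#' @inheritParams disomy_frequency
#' @param marker Name of the single-marker class column whose transmission is
#'   reported.
#' @return A tibble with one row per diploid: `n_haploid` (denominator after
#'   exclusions), `transmission`, and `undefined`.
#' @examples
#' tbl <- tibble::tibble(diploid = "d1", `Ade+HygS` = 90, `Ade-HygR` = 10,
#'                       `Ade+HygR` = 0)
#' allele_transmission(tbl, marker = "Ade+HygS",
#'                     single = c("Ade+HygS", "Ade-HygR"), double = "Ade+HygR")
#' @export
allele_transmission <- function(tbl, marker, single = NULL, double = NULL,
                                no_marker = NULL, id = NULL) {
  sch <- schema_of(tbl, single, double, no_marker, id)
  count_cols(tbl, sch)
  if (!marker %in% sch$single) {
    abort(sprintf("`marker` must be one of the single-marker classes: %s",
                  paste(sch$single, collapse = ", ")))
  }
  denom <- rowSums(tbl[sch$single])
  trans <- ifelse(denom > 0, tbl[[marker]] / denom, NA_real_)
  tibble(
    !!sch$id := tbl[[sch$id]],
    marker = marker,
    n_haploid = denom,
    transmission = trans,
    undefined = denom == 0
  )
}

#' Likelihood-ratio goodness-of-fit (G) test
#'
#' `G = 2 * sum(O * log(O / E))` with `0 * log(0) = 0`, compared to a
#' chi-square distribution on `k - 1` degrees of freedom. No continuity or
#' Williams correction is applied. This is the test used on allele-transmission
#' and disomy counts throughout the assays.
#'
#' @param observed Non-negative count vector with at least one positive entry.
#' @param expected Expected proportions (default: equal). Rescaled to sum to 1.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' g_test(c(90, 10))                 # vs 50:50
#' g_test(c(30, 70), c(0.25, 0.75))
#' @export
g_test <- function(observed, expected = NULL) {
  observed <- as.numeric(observed)
  if (any(observed < 0) || sum(observed) <= 0) {
    abort("`observed` must be non-negative counts with a positive total.")
  }
  k <- length(observed)
  if (is.null(expected)) expected <- rep(1 / k, k)
  if (length(expected) != k || any(expected < 0)) {
    abort("`expected` must be non-negative proportions matching `observed`.")
  }
  if (any(expected == 0 & observed > 0)) {
    abort("Observed counts in a class with expected proportion 0.")
  }
  expected <- expected / sum(expected)
  E <- sum(observed) * expected
  terms <- ifelse(observed > 0, observed * log(observed / E), 0)
  G <- 2 * sum(terms)
  tibble(statistic = G, df = k - 1L,
         p.value = pchisq(G, df = k - 1L, lower.tail = FALSE))
}

#' Wilcoxon rank-sum test for fertility replicates
#'
#' Two-sided rank-sum comparison of two sets of viable-spore-yield replicates.
#' Uses the exact distribution when the smaller group has at most 8 values and
#' there are no ties, otherwise the normal approximation with tie-corrected
#' variance.
#'
#' @param x,y Numeric vectors of replicate values (each non-empty).
#' @return A one-row tibble: `statistic` (rank-sum W), `p.value`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("Both groups need at least one value.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE)
  )
  tibble(statistic = unname(res$statistic),
         p.value = min(res$p.value, 1),
         method = if (exact) "exact" else "normal approximation")
}

#' Viable spore yield
#'
#' Viable spores recovered per diploid cell placed on sporulation media, the
#' fertility measure of the assays: `colonies * dilution_factor /
#' cells_plated`. Values are in arbitrary units and should be compared to a
#' matched control.
#'
#' @param colonies Colony count(s).
#' @param dilution_factor Dilution factor applied before plating.
#' @param cells_plated Number of cells placed on the starvation media (> 0).
#' @return Numeric yield(s).
#' @export
viable_spore_yield <- function(colonies, dilution_factor, cells_plated) {
  if (any(cells_plated <= 0)) abort("`cells_plated` must be > 0.")
  if (any(colonies < 0) || any(dilution_factor < 0)) {
    abort("`colonies` and `dilution_factor` must be non-negative.")
  }
  colonies * dilution_factor / cells_plated
}

#' Relative fertility
#'
#' Ratio of mean viable spore yield in a test diploid to a matched control,
#' the "relative fertility" of the source data.
#'
#' @param test,control Numeric vectors of yield replicates.
#' @return A single ratio.
#' @export
relative_fertility <- function(test, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) abort("Control mean yield must be positive.")
  mean(test) / mc
}

#' Disomes produced per plated diploid cell
#'
#' The product of the disomy fraction among viable spores and the viable spore
#' yield: an estimate of how many disomic spores each diploid cell contributes.
#' Under the killing model this is unchanged by driver competition — drivers
#' enrich disomes among survivors by destroying haploids, not by producing
#' more disomes.
#'
#' @param disomy_fraction Fraction of viable spores that are disomic.
#' @param yield Viable spore yield.
#' @return Numeric disomes per cell.
#' @export
disomes_per_cell <- function(disomy_fraction, yield) {
  if (any(disomy_fraction < 0 | disomy_fraction > 1)) {
    abort("`disomy_fraction` must lie in [0, 1].")
  }
  disomy_fraction * yield
}

#' Genetic map distance from recombinant counts
#'
#' Raw distance is `100 * recombinants / haploid_total` centiMorgans; the
#' Haldane mapping function `-50 * log(1 - 2 * RF)` corrects for multiple
#' crossovers and is undefined at recombinant fractions >= 0.5. Disomic spores
#' must be excluded upstream.
#'
#' @param recombinants Recombinant spore count(s).
#' @param haploid_total Total informative haploid spores (> 0).
#' @param method `"raw"` or `"haldane"`.
#' @return A tibble with `rf`, `cM`, and `undefined` (Haldane at RF >= 0.5).
#' @examples
#' map_distance(20, 100)
#' map_distance(20, 100, method = "haldane")
#' @export
map_distance <- function(recombinants, haploid_total, method = c("raw", "haldane")) {
  method <- match.arg(method)
  if (any(haploid_total <= 0)) abort("`haploid_total` must be > 0.")
  if (any(recombinants < 0) || any(recombinants > haploid_total)) {
    abort("`recombinants` must lie in [0, haploid_total].")
  }
  rf <- recombinants / haploid_total
  if (method == "raw") {
    tibble(rf = rf, cM = 100 * rf, undefined = FALSE)
  } else {
    undef <- rf >= 0.5
    tibble(rf = rf,
           cM = ifelse(undef, NA_real_, -50 * log(1 - 2 * rf)),
           undefined = undef)
  }
}

#' Sample size for comparing two proportions
#'
#' Smallest per-group sample size giving the requested power against the
#' difference `p1 - p2` at two-sided level `alpha`, by the standard
#' normal-approximation formula (pooled variance under the null). Used to plan
#' how many spores to score to detect a recombination-frequency change.
#'
#' @param p1,p2 The two proportions (distinct, strictly inside (0, 1)).
#' @param alpha Two-sided significance level.
#' @param power Required power.
#' @return Integer sample size per group.
#' @examples
#' required_n_two_proportions(0.5, 0.4)
#' @export
required_n_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8) {
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1)) abort("`p1`, `p2` must be in (0, 1).")
  if (p1 == p2) abort("`p1` and `p2` must differ.")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must be in (0, 1).")
  }
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  as.integer(ceiling(n))
}
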