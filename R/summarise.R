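census_weight <- function(census) {
  if ("count" %in% names(census)) census$count else census$prob
}

marker_at <- function(markers_list, pair) {
  # For each census row, which of the pair's labels the spore shows at a locus:
  # "A", "B", "both", or "none".
  vapply(markers_list, function(m) {
    m <- m[!is.na(m)]
    # duplication phenotypes store a combined label at the locus
    hasA <- any(vapply(m, function(x) pair[["A"]] %in% strsplit(x, "/", fixed = TRUE)[[1]], logical(1)))
    hasB <- any(vapply(m, function(x) pair[["B"]] %in% strsplit(x, "/", fixed = TRUE)[[1]], logical(1)))
    if (hasA && hasB) "both" else if (hasA) "A" else if (hasB) "B" else "none"
  }, character(1))
}

#' Assay-level summary of a spore census
#'
#' Reduces a census to the quantities scored in the genetic assays: the viable
#' fraction of all spores, disomy among viable spores, per-marker transmission
#' among viable haploids (spores showing both or neither of a locus's markers
#' are excluded, mirroring how double-resistant colonies are set aside), the
#' recombinant fraction among viable haploids, and — when a no-killing
#' reference census is supplied — relative fertility, the ratio of viable
#' output to the reference's.
#'
#' @param census A `spore_census` from [enumerate_meiosis()] or
#'   [simulate_meioses()].
#' @param reference Optional reference `spore_census` from a matched control
#'   cross, used only for `relative_fertility`.
#' @return A one-row tibble with columns `viable_fraction`,
#'   `disomy_among_viable`, `recombinant_fraction`, `relative_fertility`, a
#'   nested `transmission` tibble (`locus`, `marker`, `transmission`), and
#'   `undefined` (`TRUE` when no spore survives, in which case the conditional
#'   quantities are `NA` rather than 0/0).
#' @examples
#' cross <- diploid_cross(
#'   hapA = haplotype(list(NULL), markers = "ade6+"),
#'   hapB = haplotype(list(NULL), markers = "hphMX6"),
#'   misseg_prob = 0.1
#' )
#' summarise_census(enumerate_meiosis(cross))
#' @export
summarise_census <- function(census, reference = NULL) {
  if (!inherits(census, "spore_census")) abort("`census` must be a spore_census.")
  w <- census_weight(census)
  total <- sum(w)
  viable <- census$viable
  w_viable <- sum(w[viable])
  viable_fraction <- w_viable / total

  if (w_viable == 0) {
    out <- tibble(
      viable_fraction = 0, disomy_among_viable = NA_real_,
      recombinant_fraction = NA_real_,
      relative_fertility = NA_real_,
      transmission = list(tibble(locus = integer(), marker = character(),
                                 transmission = numeric())),
      undefined = TRUE
    )
  } else {
    disomy <- sum(w[viable & census$klass == "disome"]) / w_viable
    hap <- viable & census$chr3_copies == 1
    w_hap <- sum(w[hap])
    recomb <- if (w_hap > 0) {
      sum(w[hap & census$klass == "haploid_recombinant"]) / w_hap
    } else NA_real_

    pairs <- attr(census, "marker_pairs")
    trans <- list()
    for (i in seq_along(pairs)) {
      pair <- pairs[[i]]
      if (any(is.na(pair))) next
      side <- marker_at(census$markers, pair)
      wA <- sum(w[hap & side == "A"])
      wB <- sum(w[hap & side == "B"])
      if (wA + wB > 0) {
        trans[[length(trans) + 1L]] <- tibble(
          locus = i, marker = unname(c(pair[["A"]], pair[["B"]])),
          transmission = c(wA, wB) / (wA + wB))
      }
    }
    out <- tibble(
      viable_fraction = viable_fraction,
      disomy_among_viable = disomy,
      recombinant_fraction = recomb,
      relative_fertility = NA_real_,
      transmission = list(bind_rows(trans)),
      undefined = FALSE
    )
  }

  if (!is.null(reference)) {
    ref <- summarise_census(reference)
    if (ref$viable_fraction > 0) {
      out$relative_fertility <- out$viable_fraction / ref$viable_fraction
    }
  }
  out
}

#' Observed recombinant fraction between two marked loci
#'
#' Computes the recombination fraction a geneticist would score from marker
#' phenotypes: among viable haploid spores showing exactly one marker at each
#' of two marked loci, the fraction with a non-parental marker combination.
#' Disomic and duplication-bearing (double-marker) spores are excluded, so
#' driver killing that removes recombinant haploids depresses this value below
#' the true map fraction.
#'
#' @param census A `spore_census` whose cross has at least two marked loci.
#' @param loci Integer pair selecting the marked loci (default: the first two).
#' @return A one-row tibble with `rf` (observed recombinant fraction), `weight`
#'   (probability mass or count of informative spores), and `undefined`.
#' @export
observed_recombination <- function(census, loci = NULL) {
  if (!inherits(census, "spore_census")) abort("`census` must be a spore_census.")
  pairs <- attr(census, "marker_pairs")
  marked <- which(vapply(pairs, function(p) !any(is.na(p)), logical(1)))
  if (is.null(loci)) loci <- marked[1:2]
  if (length(loci) != 2 || any(is.na(loci)) || !all(loci %in% marked)) {
    abort("`loci` must select two marked loci of the cross.")
  }
  w <- census_weight(census)
  hap <- census$viable & census$chr3_copies == 1
  s1 <- marker_at(census$markers, pairs[[loci[1]]])
  s2 <- marker_at(census$markers, pairs[[loci[2]]])
  informative <- hap & s1 %in% c("A", "B") & s2 %in% c("A", "B")
  w_inf <- sum(w[informative])
  if (w_inf == 0) {
    return(tibble(rf = NA_real_, weight = 0, undefined = TRUE))
  }
  w_rec <- sum(w[informative & s1 != s2])
  tibble(rf = w_rec / w_inf, weight = w_inf, undefined = FALSE)
}
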