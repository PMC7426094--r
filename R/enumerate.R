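# Exact enumeration of a single meiosis under the poison/antidote killing model.
#
# A meiosis is one of three mutually exclusive events:
#   * MI nondisjunction of chromosome 3 (prob m): 2 heterozygous disomes +
#     2 nullisomes;
#   * an unequal interhomolog crossover at the designated locus
#     (prob (1 - m) * u, Rec12-dependent): one duplication product carrying both
#     alleles at that locus, its reciprocal carrying neither, two parental
#     products;
#   * a normal meiosis: 4 haploid products whose parental origin per locus
#     follows the per-interval recombination fractions (independent products,
#     at most one crossover per interval, no interference).
# Every spore then survives with the product over all drivers segregating in
# the cross of 1 (carries the matching antidote) or (1 - kill_prob).

survival_from_ids <- function(ids, alleles) {
  s <- 1
  for (a in alleles) {
    if (a$has_antidote && a$id %in% ids) next
    s <- s * (1 - a$kill_prob)
  }
  s
}

#' Survival probability of one spore
#'
#' Implements the killing rule of the drive model: a spore is destroyed by any
#' *wtf* driver segregating in the cross whose antidote it does not express.
#' Poison-only alleles (no antidote) act on every spore, carriers included.
#' Nullisomic spores are always inviable.
#'
#' @param spore A list with fields `allele_ids` (character vector of carried
#'   driver ids) and `chr3_copies` (0, 1, or 2).
#' @param cross A [diploid_cross()] from which the spore derives.
#' @return A survival probability in \[0, 1\].
#' @examples
#' cross <- diploid_cross(
#'   hapA = haplotype(list(driver_allele("A", 1))),
#'   hapB = haplotype(list(driver_allele("B", 1)))
#' )
#' # haploid inheriting only driver A is killed by driver B's poison
#' spore_survival_probability(list(allele_ids = "A", chr3_copies = 1), cross)
#' # a disome inheriting both drivers carries both antidotes
#' spore_survival_probability(list(allele_ids = c("A", "B"), chr3_copies = 2), cross)
#' @export
spore_survival_probability <- function(spore, cross) {
  if (!inherits(cross, "diploid_cross")) abort("`cross` must be a diploid_cross.")
  chr3 <- spore$chr3_copies %||% 1L
  if (chr3 == 0) return(0)
  ids <- spore$allele_ids %||% character()
  alleles <- cross_alleles(cross)
  known <- vapply(alleles, `[[`, character(1), "id")
  if (!all(ids %in% known)) {
    abort(sprintf("Spore carries alleles unknown to the cross: %s",
                  paste(setdiff(ids, known), collapse = ", ")))
  }
  survival_from_ids(ids, alleles)
}

phenotype_label <- function(markers) {
  markers <- markers[!is.na(markers)]
  if (length(markers) == 0) return("no-marker")
  paste(sort(unique(unlist(strsplit(markers, "/", fixed = TRUE)))), collapse = "/")
}

hap_content <- function(hap, loci) {
  ids <- unlist(lapply(loci, function(i) {
    vapply(hap$alleles[[i]], `[[`, character(1), "id")
  }))
  list(ids = unique(ids %||% character()), markers = hap$markers[loci])
}

# Per-product outcome table of one meiosis; `prob` is the unconditional
# probability that a random spore of the cross is this product.
meiosis_products <- function(cross) {
  n_loci <- length(cross$hapA$alleles)
  m <- cross$misseg_prob
  u <- if (cross$map$rec12_active) cross$uneq_xo_prob else 0
  rec <- if (cross$map$rec12_active) cross$map$rec_fractions else rep(0, n_loci)

  rows <- list()
  add <- function(branch, klass, ids, markers, chr3, prob) {
    ids <- as.character(ids %||% character())
    rows[[length(rows) + 1L]] <<- list(
      branch = branch, klass = klass, allele_ids = list(unique(ids)),
      markers = list(markers), chr3_copies = chr3, prob = prob)
  }

  content_A <- hap_content(cross$hapA, seq_len(n_loci))
  content_B <- hap_content(cross$hapB, seq_len(n_loci))

  if (m > 0) {
    add("nondisjunction", "disome",
        c(content_A$ids, content_B$ids),
        c(content_A$markers, content_B$markers), 2L, m / 2)
    add("nondisjunction", "nullisome", character(), rep(NA_character_, 0), 0L, m / 2)
  }

  if (u > 0) {
    d <- cross$dup_locus
    others <- setdiff(seq_len(n_loci), d)
    dup_ids <- c(hap_content(cross$hapA, others)$ids,
                 vapply(cross$hapA$alleles[[d]], `[[`, character(1), "id"),
                 vapply(cross$hapB$alleles[[d]], `[[`, character(1), "id"))
    dup_markers <- cross$hapA$markers
    d_marks <- c(cross$hapA$markers[d], cross$hapB$markers[d])
    d_marks <- d_marks[!is.na(d_marks)]
    dup_markers[d] <- if (length(d_marks)) paste(sort(d_marks), collapse = "/") else NA_character_
    rec_ids <- hap_content(cross$hapB, others)$ids
    rec_markers <- cross$hapB$markers
    rec_markers[d] <- NA_character_
    w <- (1 - m) * u / 4
    add("unequal_xo", "haploid_duplication", dup_ids, dup_markers, 1L, w)
    add("unequal_xo", "haploid_recombinant", rec_ids, rec_markers, 1L, w)
    add("unequal_xo", "haploid_parental", content_A$ids, content_A$markers, 1L, w)
    add("unequal_xo", "haploid_parental", content_B$ids, content_B$markers, 1L, w)
  }

  w_norm <- (1 - m) * (1 - u)
  if (w_norm > 0) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), n_loci)))
    for (k in seq_len(nrow(patterns))) {
      pat <- patterns[k, ]
      # parent at locus 1 is equally likely A or B (the centromere-flanking
      # interval does not affect locus patterns); switches between adjacent
      # loci occur with the interval's recombination fraction
      p_pat <- 0.5
      if (n_loci > 1) {
        for (j in 2:n_loci) {
          p_pat <- p_pat * if (pat[j] != pat[j - 1]) rec[j] else 1 - rec[j]
        }
      }
      if (p_pat == 0) next
      ids <- character(); markers <- rep(NA_character_, n_loci)
      for (j in seq_len(n_loci)) {
        hap <- if (pat[j] == 0) cross$hapA else cross$hapB
        ids <- c(ids, vapply(hap$alleles[[j]], `[[`, character(1), "id"))
        markers[j] <- hap$markers[j]
      }
      klass <- if (length(unique(pat)) > 1) "haploid_recombinant" else "haploid_parental"
      add("normal", klass, ids, markers, 1L, w_norm * p_pat)
    }
  }

  bind_rows(lapply(rows, as_tibble))
}

new_spore_census <- function(tbl, type, total, cross) {
  structure(
    tbl,
    class = c("spore_census", class(tibble())),
    census_type = type,
    census_total = total,
    marker_pairs = marker_pairs(cross),
    dup_locus = cross$dup_locus
  )
}

#' Exact spore census of a diploid cross
#'
#' Enumerates every possible spore of the cross together with its probability,
#' splitting each genotype into a viable and a dead entry according to the
#' poison/antidote survival rule. Probabilities sum to 1 over all entries.
#'
#' @param cross A [diploid_cross()]. Exhaustive enumeration is limited to
#'   crosses with at most 8 loci.
#' @return A `spore_census` tibble with columns `klass` (one of
#'   `haploid_parental`, `haploid_recombinant`, `haploid_duplication`,
#'   `disome`, `nullisome`), `phenotype` (marker-phenotype label),
#'   `chr3_copies`, `viable`, and `prob`; marker sets are kept in the
#'   list-column `markers`.
#' @seealso [simulate_meioses()] for the Monte-Carlo counterpart,
#'   [summarise_census()] for assay-level summaries.
#' @examples
#' cross <- diploid_cross(
#'   hapA = haplotype(list(driver_allele("wtf4", 1)), markers = "kanMX4"),
#'   hapB = haplotype(list(driver_allele("wtf28", 1)), markers = "hphMX6"),
#'   misseg_prob = 0.05
#' )
#' enumerate_meiosis(cross)
#' @export
enumerate_meiosis <- function(cross) {
  if (!inherits(cross, "diploid_cross")) abort("`cross` must be a diploid_cross.")
  if (length(cross$hapA$alleles) > 8) {
    abort("Exact enumeration supports at most 8 loci; use simulate_meioses().")
  }
  prods <- meiosis_products(cross)
  alleles <- cross_alleles(cross)
  prods$surv <- vapply(seq_len(nrow(prods)), function(i) {
    if (prods$chr3_copies[i] == 0) 0 else
      survival_from_ids(prods$allele_ids[[i]], alleles)
  }, numeric(1))
  prods$phenotype <- vapply(prods$markers, phenotype_label, character(1))

  census <- bind_rows(
    prods |> mutate(viable = TRUE, p = .data$prob * .data$surv),
    prods |> mutate(viable = FALSE, p = .data$prob * (1 - .data$surv))
  ) |>
    filter(.data$p > 0) |>
    group_by(.data$klass, .data$phenotype, .data$chr3_copies, .data$viable) |>
    summarise(prob = sum(.data$p), markers = .data$markers[1], .groups = "drop") |>
    arrange(desc(.data$prob))

  stopifnot(abs(sum(census$prob) - 1) < 1e-12)
  new_spore_census(census, "exact", 1, cross)
}
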