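#' Define a wtf driver allele
#'
#' A *wtf* element is a poison/antidote pair: every spore of the ascus is
#' exposed to the poison, and only spores inheriting the element express the
#' matching antidote. Separation-of-function alleles express the poison but not
#' the antidote, so they kill carrier and non-carrier spores alike.
#'
#' @param id Character label. Antidote specificity key: an antidote neutralises
#'   only the poison with the same `id`.
#' @param kill_prob Probability in \[0, 1\] that a spore lacking the matching
#'   antidote is destroyed (the drive strength of this element).
#' @param has_antidote Logical; `FALSE` for poison-only alleles.
#' @return An object of class `driver_allele`.
#' @examples
#' driver_allele("wtf4", kill_prob = 0.95)
#' driver_allele("wtf28_poison", kill_prob = 0.95, has_antidote = FALSE)
#' @export
driver_allele <- function(id, kill_prob = 0.95, has_antidote = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort("`id` must be a single non-empty string.")
  }
  if (!is.numeric(kill_prob) || length(kill_prob) != 1L ||
      kill_prob < 0 || kill_prob > 1) {
    abort("`kill_prob` must be a single probability in [0, 1].")
  }
  structure(
    list(id = id, kill_prob = as.numeric(kill_prob),
         has_antidote = isTRUE(has_antidote)),
    class = "driver_allele"
  )
}

#' @export
print.driver_allele <- function(x, ...) {
  cat(sprintf("<driver_allele> %s  kill_prob = %g  antidote = %s\n",
              x$id, x$kill_prob, if (x$has_antidote) "yes" else "no"))
  invisible(x)
}

#' Define one chromosome-3 haplotype
#'
#' A haplotype is an ordered list of locus slots along chromosome 3. Each slot
#' holds zero, one, or two driver alleles (two alleles in one slot represent a
#' tandem duplication created by an unequal crossover) plus an optional
#' scoreable marker (`ade6+`, `hphMX6`, `kanMX4`, ...).
#'
#' @param alleles A list with one element per locus. Each element is `NULL`, a
#'   [driver_allele()], or a list of driver alleles with distinct ids.
#' @param markers Character vector of marker labels, one per locus (`NA` for an
#'   unmarked locus). Recycled from `NA` if omitted.
#' @return An object of class `haplotype`.
#' @examples
#' haplotype(
#'   alleles = list(driver_allele("wtf4"), NULL),
#'   markers = c("kanMX4", "ura4+")
#' )
#' @export
haplotype <- function(alleles, markers = NULL) {
  if (!is.list(alleles)) abort("`alleles` must be a list (one element per locus).")
  alleles <- lapply(alleles, function(a) {
    if (is.null(a)) return(list())
    if (inherits(a, "driver_allele")) return(list(a))
    if (is.list(a) && all(vapply(a, inherits, logical(1), "driver_allele"))) {
      ids <- vapply(a, `[[`, character(1), "id")
      if (anyDuplicated(ids)) abort("A locus slot cannot hold two alleles with the same id.")
      if (length(a) > 2L) abort("A locus slot holds at most two alleles.")
      return(a)
    }
    abort("Each locus slot must be NULL, a driver_allele, or a list of driver_alleles.")
  })
  n_loci <- length(alleles)
  if (is.null(markers)) markers <- rep(NA_character_, n_loci)
  markers <- as.character(markers)
  if (length(markers) != n_loci) {
    abort(sprintf("`markers` must have one entry per locus (%d).", n_loci))
  }
  structure(list(alleles = alleles, markers = markers), class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> %d loci\n", length(x$alleles)))
  for (i in seq_along(x$alleles)) {
    ids <- vapply(x$alleles[[i]], `[[`, character(1), "id")
    cat(sprintf("  locus %d: [%s] marker = %s\n", i,
                paste(ids, collapse = ", "),
                if (is.na(x$markers[i])) "-" else x$markers[i]))
  }
  invisible(x)
}

#' Define the recombination map of a cross
#'
#' Per-interval recombination probabilities along chromosome 3. The first
#' interval separates the centromere from the first locus; interval `i > 1`
#' separates locus `i - 1` from locus `i`. Setting `rec12_active = FALSE`
#' models a *rec12* deletion, which abolishes induced meiotic crossovers: all
#' effective recombination fractions become 0, as does the unequal-crossover
#' rate of the cross.
#'
#' @param rec_fractions Numeric vector of recombination fractions in
#'   \[0, 0.5\], one per interval (length = number of loci).
#' @param rec12_active Logical; `FALSE` silences all recombination.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(rec_fractions, rec12_active = TRUE) {
  rec_fractions <- as.numeric(rec_fractions)
  if (any(rec_fractions < 0 | rec_fractions > 0.5)) {
    abort("Recombination fractions must lie in [0, 0.5].")
  }
  structure(list(rec_fractions = rec_fractions,
                 rec12_active = isTRUE(rec12_active)),
            class = "genetic_map")
}

#' Define a diploid cross
#'
#' Two chromosome-3 haplotypes plus the meiosis parameters of the model: the
#' probability `misseg_prob` that a meiosis undergoes meiosis I nondisjunction
#' of chromosome 3 (yielding two heterozygous disomes and two inviable
#' nullisomes), and the probability `uneq_xo_prob` that an otherwise normal
#' meiosis experiences an unequal interhomolog crossover at `dup_locus`,
#' placing both of that locus's alleles on one product and neither on its
#' reciprocal.
#'
#' @param hapA,hapB [haplotype()] objects sharing the same locus list.
#' @param map A [genetic_map()]; defaults to no recombination.
#' @param misseg_prob Probability in \[0, 1\] of whole-meiosis MI
#'   nondisjunction of chromosome 3.
#' @param uneq_xo_prob Probability in \[0, 1\] of an unequal crossover at
#'   `dup_locus`, conditional on a normal meiosis. Requires Rec12.
#' @param dup_locus Locus index at which unequal crossovers occur. Defaults to
#'   the first locus at which both haplotypes carry alleles with different ids;
#'   required only when `uneq_xo_prob > 0`.
#' @return An object of class `diploid_cross`.
#' @examples
#' cross <- diploid_cross(
#'   hapA = haplotype(list(driver_allele("wtf4")), markers = "kanMX4"),
#'   hapB = haplotype(list(driver_allele("wtf28")), markers = "hphMX6"),
#'   misseg_prob = 0.1
#' )
#' @export
diploid_cross <- function(hapA, hapB, map = NULL, misseg_prob = 0,
                          uneq_xo_prob = 0, dup_locus = NULL) {
  if (!inherits(hapA, "haplotype") || !inherits(hapB, "haplotype")) {
    abort("`hapA` and `hapB` must be haplotype objects.")
  }
  n_loci <- length(hapA$alleles)
  if (length(hapB$alleles) != n_loci) {
    abort("`hapA` and `hapB` must share the same locus list.")
  }
  if (is.null(map)) map <- genetic_map(rep(0, n_loci))
  if (!inherits(map, "genetic_map")) abort("`map` must be a genetic_map.")
  if (length(map$rec_fractions) != n_loci) {
    abort(sprintf("`map` must have %d intervals (one per locus).", n_loci))
  }
  for (p in list(misseg_prob, uneq_xo_prob)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      abort("`misseg_prob` and `uneq_xo_prob` must be probabilities in [0, 1].")
    }
  }
  if (is.null(dup_locus)) {
    for (i in seq_len(n_loci)) {
      idsA <- vapply(hapA$alleles[[i]], `[[`, character(1), "id")
      idsB <- vapply(hapB$alleles[[i]], `[[`, character(1), "id")
      if (length(idsA) > 0 && length(idsB) > 0 && !setequal(idsA, idsB)) {
        dup_locus <- i
        break
      }
    }
  }
  if (uneq_xo_prob > 0 && is.null(dup_locus)) {
    abort("`uneq_xo_prob` > 0 requires a `dup_locus` (no heterozygous driver locus found).")
  }
  if (!is.null(dup_locus) &&
      (dup_locus < 1 || dup_locus > n_loci || dup_locus != round(dup_locus))) {
    abort("`dup_locus` must index one of the cross's loci.")
  }
  structure(
    list(hapA = hapA, hapB = hapB, map = map,
         misseg_prob = as.numeric(misseg_prob),
         uneq_xo_prob = as.numeric(uneq_xo_prob),
         dup_locus = dup_locus),
    class = "diploid_cross"
  )
}

#' @export
print.diploid_cross <- function(x, ...) {
  cat(sprintf("<diploid_cross> %d loci  m = %g  u = %g  rec12 = %s\n",
              length(x$hapA$alleles), x$misseg_prob, x$uneq_xo_prob,
              if (x$map$rec12_active) "+" else "deleted"))
  invisible(x)
}

# All distinct driver alleles segregating in the cross, deduplicated by id.
cross_alleles <- function(cross) {
  all <- c(unlist(cross$hapA$alleles, recursive = FALSE),
           unlist(cross$hapB$alleles, recursive = FALSE))
  ids <- vapply(all, `[[`, character(1), "id")
  all[!duplicated(ids)]
}

# Marker pair (hapA label, hapB label) per locus; NA where unmarked.
marker_pairs <- function(cross) {
  lapply(seq_along(cross$hapA$markers), function(i) {
    c(A = cross$hapA$markers[i], B = cross$hapB$markers[i])
  })
}
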