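#' Monte-Carlo spore census
#'
#' Samples `n_meioses` meioses of the cross and tallies the resulting spores by
#' class, phenotype and viability. Class frequencies converge to the exact
#' probabilities of [enumerate_meiosis()]; identical inputs and seed give
#' identical counts.
#'
#' @param cross A [diploid_cross()].
#' @param n_meioses Number of meioses to sample (each yields four spores).
#' @param seed Integer seed; the single source of randomness for the run.
#' @return A `spore_census` tibble like [enumerate_meiosis()]'s, with a `count`
#'   column in place of `prob` (and `prob` as the realised frequency). Counts
#'   sum to `4 * n_meioses`.
#' @examples
#' cross <- diploid_cross(
#'   hapA = haplotype(list(driver_allele("wtf4", 1)), markers = "kanMX4"),
#'   hapB = haplotype(list(driver_allele("wtf28", 1)), markers = "hphMX6"),
#'   misseg_prob = 0.05
#' )
#' simulate_meioses(cross, n_meioses = 1000, seed = 1)
#' @export
simulate_meioses <- function(cross, n_meioses, seed) {
  if (!inherits(cross, "diploid_cross")) abort("`cross` must be a diploid_cross.")
  if (!is.numeric(n_meioses) || length(n_meioses) != 1L || n_meioses < 1) {
    abort("`n_meioses` must be a single count >= 1.")
  }
  n_meioses <- as.integer(round(n_meioses))
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied.")

  withr::with_seed(as.integer(seed), {
    m <- cross$misseg_prob
    u <- if (cross$map$rec12_active) cross$uneq_xo_prob else 0
    branch_n <- as.vector(rmultinom(1, n_meioses,
                                    c(m, (1 - m) * u, (1 - m) * (1 - u))))
    names(branch_n) <- c("nondisjunction", "unequal_xo", "normal")

    prods <- meiosis_products(cross)
    alleles <- cross_alleles(cross)
    prods$surv <- vapply(seq_len(nrow(prods)), function(i) {
      if (prods$chr3_copies[i] == 0) 0 else
        survival_from_ids(prods$allele_ids[[i]], alleles)
    }, numeric(1))
    prods$phenotype <- vapply(prods$markers, phenotype_label, character(1))

    prods$count <- 0L
    # nondisjunction meioses: deterministically 2 disomes + 2 nullisomes each
    nd <- prods$branch == "nondisjunction"
    prods$count[nd] <- 2L * branch_n[["nondisjunction"]]
    # unequal-crossover meioses: one of each of the four listed products
    ux <- prods$branch == "unequal_xo"
    prods$count[ux] <- branch_n[["unequal_xo"]]
    # normal meioses: 4 independent products drawn from the pattern distribution
    nm <- which(prods$branch == "normal")
    if (length(nm) > 0 && branch_n[["normal"]] > 0) {
      p <- prods$prob[nm]
      prods$count[nm] <- as.vector(rmultinom(1, 4L * branch_n[["normal"]], p / sum(p)))
    }

    viable_count <- rbinom(nrow(prods), prods$count, prods$surv)
    detail <- prods |>
      mutate(viable_count = viable_count) |>
      select("branch", "klass", "phenotype", "prob", "surv", "count", "viable_count")
    census <- bind_rows(
      prods |> mutate(viable = TRUE, n = viable_count),
      prods |> mutate(viable = FALSE, n = .data$count - viable_count)
    ) |>
      group_by(.data$klass, .data$phenotype, .data$chr3_copies, .data$viable) |>
      summarise(count = sum(.data$n), markers = .data$markers[1], .groups = "drop") |>
      filter(.data$count > 0) |>
      mutate(prob = .data$count / (4 * n_meioses)) |>
      arrange(desc(.data$count))

    stopifnot(sum(census$count) == 4L * n_meioses)
    out <- new_spore_census(census, "sampled", 4L * n_meioses, cross)
    attr(out, "seed") <- as.integer(seed)
    attr(out, "branch_counts") <- branch_n
    attr(out, "draw_detail") <- detail
    out
  })
}

#' Goodness-of-fit of the sampler against exact enumeration
#'
#' Runs [simulate_meioses()] and tests the draw against the exact meiosis
#' model with a chi-square statistic that respects the sampling structure:
#' meiosis branch counts are multinomial over (nondisjunction,
#' unequal-crossover, normal), products within the normal branch are
#' multinomial over the recombination patterns, and viable counts per product
#' class are binomial in the class's survival probability. The component
#' Pearson statistics are independent given the conditioning, so their sum is
#' chi-square on the summed degrees of freedom. Components with expected
#' counts below `min_expected` are pooled or skipped.
#'
#' @param cross A [diploid_cross()].
#' @param n_meioses,seed Passed to [simulate_meioses()].
#' @param min_expected Minimum expected count for a cell to stand alone.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
simulation_gof <- function(cross, n_meioses, seed, min_expected = 5) {
  census <- simulate_meioses(cross, n_meioses, seed)
  detail <- attr(census, "draw_detail")
  branch_n <- attr(census, "branch_counts")
  m <- cross$misseg_prob
  u <- if (cross$map$rec12_active) cross$uneq_xo_prob else 0
  branch_p <- c(nondisjunction = m, unequal_xo = (1 - m) * u,
                normal = (1 - m) * (1 - u))

  pearson <- function(obs, p) {
    keep <- p > 0
    obs <- obs[keep]; p <- p[keep] / sum(p[keep])
    E <- sum(obs) * p
    # pool cells with small expectation into one combined cell
    small <- E < min_expected
    if (any(small)) {
      obs <- c(obs[!small], sum(obs[small]))
      E <- c(E[!small], sum(E[small]))
    }
    if (length(E) < 2) return(c(0, 0))
    c(sum((obs - E)^2 / E), length(E) - 1)
  }

  stat <- 0; df <- 0
  b <- pearson(branch_n, branch_p)
  stat <- stat + b[1]; df <- df + b[2]

  nm <- detail$branch == "normal"
  if (sum(nm) > 1 && branch_n[["normal"]] > 0) {
    b <- pearson(detail$count[nm], detail$prob[nm])
    stat <- stat + b[1]; df <- df + b[2]
  }
  # viability: binomial per product class where both outcomes are well populated
  for (i in seq_len(nrow(detail))) {
    s <- detail$surv[i]; n <- detail$count[i]
    if (s > 0 && s < 1 && n * s >= min_expected && n * (1 - s) >= min_expected) {
      v <- detail$viable_count[i]
      stat <- stat + (v - n * s)^2 / (n * s * (1 - s))
      df <- df + 1
    }
  }
  tibble(statistic = stat, df = df,
         p.value = pchisq(stat, df = df, lower.tail = FALSE))
}
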