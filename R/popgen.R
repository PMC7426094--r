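# Deterministic infinite-population recursion for a chromosome-segregation
# infidelity mutant in a population segregating n equally frequent
# whole-chromosome drivers of equal strength t.
#
# Lifecycle: haploid pool -> random union -> diploid -> meiosis -> spore
# selection -> next haploid pool. The mutant locus is unlinked to chromosome 3,
# so mutant transmission among a heterozygote's viable spores is 1/2 regardless
# of chromosome-3 fate. A random diploid is driver-homozygous with probability
# 1/n (all four spores carry the needed antidote) and driver-heterozygous with
# probability (n-1)/n (each haploid spore is killed with probability t). A
# mutant meiosis missegregates with probability phi (0 / h*f / f by genotype),
# yielding 2 viable heterozygous disomes (times 1 - s_s) and 2 inviable
# nullisomes; disomes survive drive because they carry both chromosome-3
# haplotypes and shed the extra chromosome afterwards, preserving driver
# symmetry. Mutation costs are multiplicative on the carrier's total meiotic
# output (h*s_m in heterozygotes, s_m in homozygotes).

#' Parameters of the driver-invasion model
#'
#' @param n Integer >= 2; number of driving alleles in the population, each at
#'   frequency 1/n.
#' @param t Drive strength in \[0, 1\]: probability that a spore lacking the
#'   matching antidote is killed.
#' @param f Missegregation level in \[0, 1\] caused by the mutation (1 means
#'   every mutant meiosis yields 50% heterozygous disomes, 50% inviable
#'   nullisomes).
#' @param h Dominance of the mutation in \[0, 1\].
#' @param s_m Additional fitness cost of the mutation in \[0, 1\].
#' @param s_s Additional fitness cost borne by disomic spores in \[0, 1\].
#' @param p0 Initial mutant allele frequency in \[0, 1\].
#' @return An object of class `model_params`.
#' @examples
#' model_params(n = 3, t = 0.95)
#' @export
model_params <- function(n, t, f = 1, h = 0.5, s_m = 0, s_s = 0, p0 = 0.1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.")
  }
  for (nm in c("t", "f", "h", "s_m", "s_s", "p0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1].", nm))
    }
  }
  structure(list(n = as.integer(n), t = t, f = f, h = h,
                 s_m = s_m, s_s = s_s, p0 = p0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> n = %d, t = %g, f = %g, h = %g, s_m = %g, s_s = %g, p0 = %g\n",
              x$n, x$t, x$f, x$h, x$s_m, x$s_s, x$p0))
  invisible(x)
}

#' Cost-free critical drive strength
#'
#' The drive strength above which a cost-free segregation-infidelity mutant
#' invades a population of `n` equally frequent drivers: `n / (2 * (n - 1))`.
#' Strictly decreasing in `n`, approaching 1/2 as `n` grows.
#'
#' @param n Integer vector of driver counts, each >= 2.
#' @return Numeric vector of critical drive strengths.
#' @examples
#' critical_drive_strength(2:6)
#' @export
critical_drive_strength <- function(n) {
  if (any(n < 2 | n != round(n))) abort("`n` must contain integers >= 2.")
  n / (2 * (n - 1))
}

#' Expected meiotic output by mutant genotype
#'
#' For a diploid of the given mutant genotype mated at random with respect to
#' drivers, returns the expected number of viable spores per meiosis and the
#' fraction of those spores carrying the mutant allele.
#'
#' @param genotype One or more of `"wt"`, `"het"`, `"hom"`.
#' @param params A [model_params()] object.
#' @return A tibble with columns `genotype`, `output`, `mutant_fraction`.
#' @examples
#' meiotic_output(c("wt", "het", "hom"), model_params(n = 3, t = 0.95))
#' @export
meiotic_output <- function(genotype, params) {
  if (!inherits(params, "model_params")) abort("`params` must be model_params.")
  genotype <- match.arg(genotype, c("wt", "het", "hom"), several.ok = TRUE)
  phi <- c(wt = 0, het = params$h * params$f, hom = params$f)[genotype]
  cost <- c(wt = 1, het = 1 - params$h * params$s_m, hom = 1 - params$s_m)[genotype]
  mutfrac <- c(wt = 0, het = 0.5, hom = 1)[genotype]
  # expected viable haploids of a faithful meiosis: all 4 survive in a
  # driver-homozygous diploid (prob 1/n), each survives with 1 - t otherwise
  k <- 1 / params$n + ((params$n - 1) / params$n) * (1 - params$t)
  output <- cost * ((1 - phi) * 4 * k + phi * 2 * (1 - params$s_s))
  tibble(genotype = genotype, output = unname(output),
         mutant_fraction = unname(mutfrac))
}

#' Can a rare segregation-infidelity mutant invade?
#'
#' Compares the expected viable meiotic output of a rare mutant heterozygote
#' against the wild type (the marginal-fitness condition as the mutant
#' frequency tends to 0). In the cost-free case with `f > 0` and `h > 0` this
#' reduces exactly to `t > n / (2 * (n - 1))`.
#'
#' @param params A [model_params()] object.
#' @return `TRUE` if the mutant invades.
#' @examples
#' mutant_invades(model_params(n = 3, t = 0.8))   # 0.8 > 0.75
#' mutant_invades(model_params(n = 3, t = 0.7))   # 0.7 < 0.75
#' @export
mutant_invades <- function(params) {
  out <- meiotic_output(c("wt", "het"), params)
  out$output[out$genotype == "het"] > out$output[out$genotype == "wt"]
}

#' One generation of the allele-frequency recursion
#'
#' Haploids unite at random (diploid genotype frequencies `p^2`, `2p(1-p)`,
#' `(1-p)^2`); each genotype class contributes viable spores in proportion to
#' its expected meiotic output, and the next haploid pool's mutant frequency is
#' the output-weighted mutant fraction.
#'
#' @param p Mutant allele frequency (vectorised).
#' @param params A [model_params()] object.
#' @return Next-generation frequency, in \[0, 1\]; 0 and 1 are fixed points.
#' @export
next_frequency <- function(p, params) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  out <- meiotic_output(c("wt", "het", "hom"), params)
  W <- setNames(out$output, out$genotype)
  mf <- setNames(out$mutant_fraction, out$genotype)
  vapply(p, function(pp) {
    freq <- c(wt = (1 - pp)^2, het = 2 * pp * (1 - pp), hom = pp^2)
    denom <- sum(freq * W)
    if (denom <= 0) abort("Total viable output is zero: population extinct.")
    min(max(sum(freq * W * mf) / denom, 0), 1)
  }, numeric(1))
}

#' Deterministic trajectory of the mutant frequency
#'
#' Iterates [next_frequency()] from `params$p0` until the mutant is lost
#' (`p < eps`), fixed (`p > 1 - eps`), reaches an interior fixed point, or
#' `max_gen` generations elapse.
#'
#' @param params A [model_params()] object.
#' @param max_gen Maximum number of generations.
#' @param eps Loss/fixation tolerance on the allele frequency.
#' @return A `drive_trajectory` object; use [tidy()] for the per-generation
#'   tibble and [glance()] for the outcome summary.
#' @examples
#' traj <- drive_trajectory(model_params(n = 3, t = 0.95))
#' glance(traj)
#' @export
drive_trajectory <- function(params, max_gen = 1e5, eps = 1e-6) {
  if (!inherits(params, "model_params")) abort("`params` must be model_params.")
  if (max_gen < 1) abort("`max_gen` must be >= 1.")
  p <- params$p0
  ps <- numeric(max_gen + 1)
  ps[1] <- p
  outcome <- "undecided"
  gen <- 0L
  while (gen < max_gen) {
    p_next <- next_frequency(p, params)
    gen <- gen + 1L
    ps[gen + 1] <- p_next
    if (p_next < eps) { outcome <- "lost"; p <- p_next; break }
    if (p_next > 1 - eps) { outcome <- "fixed"; p <- p_next; break }
    if (p_next == p) break  # interior fixed point (e.g. t exactly critical)
    p <- p_next
  }
  structure(
    list(states = tibble(generation = 0:gen, p = ps[1:(gen + 1)]),
         outcome = outcome, params = params, eps = eps),
    class = "drive_trajectory"
  )
}

#' @export
print.drive_trajectory <- function(x, ...) {
  cat(sprintf("<drive_trajectory> n = %d, t = %g: %s after %d generations (p = %.4g)\n",
              x$params$n, x$params$t, x$outcome,
              max(x$states$generation), x$states$p[nrow(x$states)]))
  invisible(x)
}

#' @rdname drive_trajectory
#' @param x A `drive_trajectory` object.
#' @param ... Unused.
#' @method tidy drive_trajectory
#' @export
tidy.drive_trajectory <- function(x, ...) x$states

#' @rdname drive_trajectory
#' @method glance drive_trajectory
#' @export
glance.drive_trajectory <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    generations = max(x$states$generation),
    p_final = x$states$p[nrow(x$states)],
    n = x$params$n, t = x$params$t, f = x$params$f, h = x$params$h,
    s_m = x$params$s_m, s_s = x$params$s_s, p0 = x$params$p0,
    t_critical = critical_drive_strength(x$params$n)
  )
}

#' Invasion phase diagram over the (n, t) plane
#'
#' Evaluates the invasion condition on a grid of driver numbers and drive
#' strengths (optionally sweeping costs, missegregation and dominance). In the
#' cost-free case the boundary coincides with [critical_drive_strength()].
#'
#' @param n Integer vector of driver counts.
#' @param t Numeric vector of drive strengths.
#' @param f,h,s_m,s_s Scalars or vectors swept over the grid.
#' @return A `drive_phase` tibble with one row per parameter combination and a
#'   logical `invades` column.
#' @examples
#' phase_grid(n = 2:6, t = seq(0, 1, 0.25))
#' @export
phase_grid <- function(n = 2:10, t = seq(0, 1, length.out = 101),
                       f = 1, h = 0.5, s_m = 0, s_s = 0) {
  grid <- expand_grid(n = n, t = t, f = f, h = h, s_m = s_m, s_s = s_s)
  grid$invades <- vapply(seq_len(nrow(grid)), function(i) {
    mutant_invades(model_params(n = grid$n[i], t = grid$t[i], f = grid$f[i],
                                h = grid$h[i], s_m = grid$s_m[i],
                                s_s = grid$s_s[i]))
  }, logical(1))
  structure(grid, class = c("drive_phase", class(grid)))
}

#' Numerically bracketed invasion boundary
#'
#' Finds the drive strength at which the rare-mutant marginal fitness equals
#' the wild type's by root bracketing on `t` in \[0, 1\], independently of the
#' closed form.
#'
#' @param n Integer >= 2.
#' @param f,h,s_m,s_s Remaining model parameters (cost-free defaults).
#' @param tol Root tolerance.
#' @return The boundary drive strength, or `NA` if no root lies in \[0, 1\].
#' @export
invasion_boundary <- function(n, f = 1, h = 0.5, s_m = 0, s_s = 0, tol = 1e-12) {
  gap <- function(t) {
    out <- meiotic_output(c("wt", "het"),
                          model_params(n = n, t = t, f = f, h = h,
                                       s_m = s_m, s_s = s_s))
    out$output[2] - out$output[1]
  }
  g0 <- gap(0); g1 <- gap(1)
  if (sign(g0) == sign(g1) && g0 != 0 && g1 != 0) return(NA_real_)
  uniroot(gap, c(0, 1), tol = tol)$root
}
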