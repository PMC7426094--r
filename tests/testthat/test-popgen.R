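test_that("the cost-free critical drive strength follows the closed form", {
  expect_equal(critical_drive_strength(2), 1)
  expect_equal(critical_drive_strength(3), 0.75)
  expect_equal(critical_drive_strength(10), 10 / 18)
  tc <- critical_drive_strength(2:50)
  expect_true(all(diff(tc) < 0))
  expect_equal(critical_drive_strength(1e6), 0.5, tolerance = 1e-5)
  expect_error(critical_drive_strength(1), ">= 2")
})

test_that("meiotic output reproduces the anchor cases", {
  # no killing, no missegregation: four viable spores, none mutant
  out <- meiotic_output("wt", model_params(n = 3, t = 0))
  expect_equal(out$output, 4)
  expect_equal(out$mutant_fraction, 0)
  # fully penetrant mutant homozygote: half the spores are viable disomes
  out2 <- meiotic_output("hom", model_params(n = 3, t = 0, f = 1))
  expect_equal(out2$output, 2)
  expect_equal(out2$mutant_fraction, 1)
  # fully recessive mutant is phenotypically wild type when heterozygous
  p <- model_params(n = 4, t = 0.9, f = 1, h = 0)
  out3 <- meiotic_output(c("wt", "het"), p)
  expect_equal(out3$output[1], out3$output[2])
  # costs scale output multiplicatively
  pc <- model_params(n = 3, t = 0.9, f = 1, h = 0.5, s_m = 0.2, s_s = 0.3)
  p0 <- model_params(n = 3, t = 0.9, f = 1, h = 0.5)
  het_c <- meiotic_output("het", pc)$output
  k <- 1 / 3 + (2 / 3) * 0.1
  expect_equal(het_c, (1 - 0.5 * 0.2) * ((1 - 0.5) * 4 * k + 0.5 * 2 * 0.7))
  expect_lt(het_c, meiotic_output("het", p0)$output)
})

test_that("invasion condition matches the threshold and its limits", {
  expect_true(mutant_invades(model_params(n = 3, t = 0.8)))
  expect_false(mutant_invades(model_params(n = 3, t = 0.7)))
  # no drive at all: missegregation only halves output
  expect_false(mutant_invades(model_params(n = 5, t = 0, f = 1, h = 0.5)))
  # numerically bracketed boundary equals the closed form
  for (n in c(2, 3, 5, 17, 50)) {
    expect_equal(invasion_boundary(n), critical_drive_strength(n),
                 tolerance = 1e-9)
  }
})

test_that("one-generation recursion has the right fixed points and direction", {
  p <- model_params(n = 3, t = 0.95)
  expect_equal(next_frequency(0, p), 0)
  expect_equal(next_frequency(1, p), 1)
  # phenotypically null mutant (f = 0, no costs) drifts nowhere
  pnull <- model_params(n = 3, t = 0.9, f = 0)
  for (x in c(0.1, 0.3, 0.7)) expect_equal(next_frequency(x, pnull), x)
  # independent brute-force arithmetic over the three diploid classes
  k <- 1 / 3 + (2 / 3) * (1 - 0.95)
  W <- c(wt = 4 * k, het = 0.5 * 4 * k + 0.5 * 2, hom = 2)
  freq <- c(wt = 0.9^2, het = 2 * 0.1 * 0.9, hom = 0.1^2)
  expected <- sum(freq * W * c(0, 0.5, 1)) / sum(freq * W)
  expect_equal(next_frequency(0.1, p), expected, tolerance = 1e-12)
  expect_gt(next_frequency(0.1, p), 0.1)
})

test_that("trajectories reproduce the printed loss and fixation outcomes", {
  # below threshold (0.55 < 0.75) the mutant is lost
  expect_identical(drive_trajectory(model_params(n = 3, t = 0.55))$outcome, "lost")
  # above threshold (0.95 > 0.75) the mutant is fixed
  expect_identical(drive_trajectory(model_params(n = 3, t = 0.95))$outcome, "fixed")
  # exactly at threshold all genotype outputs are equal: p is stationary
  pcrit <- model_params(n = 3, t = 0.75)
  for (x in c(0.05, 0.1, 0.5)) {
    expect_equal(next_frequency(x, pcrit), x, tolerance = 1e-12)
  }
  traj <- drive_trajectory(pcrit)
  expect_identical(traj$outcome, "undecided")
  expect_true(all(abs(traj$states$p - 0.1) < 1e-12))
  # frequencies remain in [0, 1] along the way
  tr <- tidy(drive_trajectory(model_params(n = 4, t = 0.9, s_m = 0.1, s_s = 0.2)))
  expect_true(all(tr$p >= 0 & tr$p <= 1))
})

test_that("dominance changes the speed but not the fate of a cost-free mutant", {
  for (t in c(0.55, 0.95)) {
    gl <- lapply(c(0.1, 0.5, 0.9), function(h) {
      glance(drive_trajectory(model_params(n = 3, t = t, h = h)))
    })
    outcomes <- vapply(gl, `[[`, character(1), "outcome")
    gens <- vapply(gl, `[[`, numeric(1), "generations")
    expect_length(unique(outcomes), 1)
    expect_gt(length(unique(gens)), 1)
  }
})

test_that("a Wright-Fisher forward simulation tracks the recursion", {
  params <- model_params(n = 3, t = 0.95)
  N <- 1e6
  withr::with_seed(101, {
    p_det <- p_wf <- params$p0
    v <- 0
    for (gen in 1:50) {
      # deterministic step and its local slope, for the drift envelope
      g <- next_frequency(p_det, params)
      eps <- 1e-6
      slope <- (next_frequency(min(p_wf + eps, 1), params) -
                  next_frequency(max(p_wf - eps, 0), params)) / (2 * eps)
      mean_wf <- next_frequency(p_wf, params)
      p_wf <- rbinom(1, N, mean_wf) / N
      p_det <- g
      v <- slope^2 * v + mean_wf * (1 - mean_wf) / N
      expect_lt(abs(p_wf - p_det), 3 * sqrt(v) + 1e-9)
    }
  })
})

test_that("the phase grid boundary matches the closed form and cost monotonicity", {
  grid <- phase_grid(n = 2:10, t = seq(0, 1, by = 0.005))
  # n = 2 needs t > 1: no invasion anywhere on the grid
  expect_false(any(grid$invades[grid$n == 2]))
  for (nn in 3:10) {
    sub <- grid[grid$n == nn, ]
    t_min <- min(sub$t[sub$invades])
    expect_lt(abs(t_min - critical_drive_strength(nn)), 0.005 + 1e-9)
  }
  # a mutation lethal to its carriers (dominant, s_m = 1) never invades
  expect_false(any(phase_grid(n = 2:10, t = seq(0, 1, by = 0.1),
                              h = 1, s_m = 1)$invades))
  # the invasion region shrinks as the disome cost grows
  sizes <- vapply(c(0, 0.2, 0.4, 0.6), function(ss) {
    sum(phase_grid(n = 2:10, t = seq(0, 1, by = 0.02), s_s = ss)$invades)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
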