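test_that("mutation input has the expected count and starting frequency", {
  expect_equal(mutation_input(10000, 0.02),
               c(mean_new_snps = 400, init_freq = 5e-5))
  expect_equal(mutation_input(1250, 0.02),
               c(mean_new_snps = 50, init_freq = 4e-4))
})

test_that("lost and fixed alleles are absorbing without mutation", {
  set.seed(1)
  f <- wf_generation(c(0, 1, 0, 1), N = 100, u = 0)
  expect_equal(f, c(0, 1, 0, 1))
  expect_length(wf_generation(numeric(0), N = 100, u = 0), 0)
})

test_that("heterozygosity decays by (1 - 1/2N) per generation", {
  set.seed(42)
  N <- 50; p0 <- 0.5; L <- 40000; gens <- 20
  f <- rep(p0, L)
  for (g in seq_len(gens)) f <- rbinom(L, 2 * N, f) / (2 * N)
  h <- mean(2 * f * (1 - f))
  expected <- 2 * p0 * (1 - p0) * (1 - 1 / (2 * N))^gens
  se <- sd(2 * f * (1 - f)) / sqrt(L)
  expect_lt(abs(h - expected), 4 * se)
})

test_that("burn-in reaches the neutral segregating-site equilibrium", {
  n_anc <- 200; u <- 0.02
  expected <- 4 * n_anc * u * sum(1 / seq_len(2 * n_anc - 1))
  set.seed(5)
  # from an empty locus set, 10N generations reach stationarity
  counts_empty <- replicate(3, length(wf_burn_in(n_anc, u, init = "empty")))
  expect_lt(abs(mean(counts_empty) - expected) / expected, 0.25)
  # spectrum initialization agrees with the from-scratch run
  counts_sfs <- replicate(3, length(wf_burn_in(n_anc, u, init = "spectrum")))
  expect_lt(abs(mean(counts_sfs) - expected) / expected, 0.25)
  expect_length(wf_burn_in(50, 0, generations = 100, init = "empty"), 0)
})

test_that("neutral fixation probability equals the allele frequency", {
  set.seed(9)
  out <- drift_to_absorption(p0 = 0.1, N = 50, n_loci = 3000)
  expect_equal(out$remaining, 0)
  se <- sqrt(0.1 * 0.9 / 3000)
  expect_lt(abs(mean(out$fixed) - 0.1), 3 * se)
})

test_that("conditional fixation time matches -4N((1-p)/p)log(1-p)", {
  set.seed(13)
  N <- 50; p0 <- 0.5
  out <- drift_to_absorption(p0, N, n_loci = 2000)
  t_fix <- out$t_fix[out$fixed]
  expected <- expected_fixation_time(p0, N)  # 200 log 2 ~ 138.6
  expect_equal(expected, -4 * N * ((1 - p0) / p0) * log(1 - p0))
  se <- sd(t_fix) / sqrt(length(t_fix))
  expect_lt(abs(mean(t_fix) - expected), 3 * se)
})

test_that("fixation-time formula has the classical limits", {
  expect_equal(expected_fixation_time(1 - 1e-12, 500), 0, tolerance = 1e-6)
  N <- 1e6
  expect_equal(expected_fixation_time(1 / (2 * N), N) / (4 * N), 1,
               tolerance = 1e-3)
  expect_error(expected_fixation_time(0, 50), "inside")
  expect_error(expected_fixation_time(1, 50), "inside")
})

test_that("migration mixes cave frequencies deterministically", {
  f_cf <- c(0, 0.5, 1); f_sf <- c(0.5, 0.5, 0.5)
  expect_equal(wf_migrate(f_cf, f_sf, 0), f_cf)
  expect_equal(wf_migrate(f_cf, f_sf, 1), f_sf)
  expect_equal(wf_migrate(0, 0.5, 0.01), 0.005)
  expect_error(wf_migrate(f_cf, f_sf, 1.5))
})

test_that("lab sampling matches the compounded drift-variance recursion", {
  set.seed(21)
  expect_equal(wf_lab_sample(rep(0, 10)), rep(0, 10))
  p <- 0.3; L <- 40000
  # no lab generations: a plain binomial sample of 20 alleles
  f0 <- wf_lab_sample(rep(p, L), lab_n_fish = 10, lab_gens = 0)
  expect_lt(abs(mean(f0) - p), 4 * sqrt(p * (1 - p) / 20 / L))
  expect_lt(abs(var(f0) - p * (1 - p) / 20) / (p * (1 - p) / 20), 0.05)
  # initial draw plus 10 generations at Ne = 10: 11 drift steps of 20 alleles
  f10 <- wf_lab_sample(rep(p, L), lab_n_fish = 10, lab_ne = 10, lab_gens = 10)
  expected_var <- p * (1 - p) * (1 - (1 - 1 / 20)^11)
  expect_lt(abs(var(f10) - expected_var) / expected_var, 0.05)
})

test_that("simulated lab classification handles the degenerate patterns", {
  s <- classify_lab(rep(0, 100), rep(1, 100))
  expect_equal(unname(s$class_freqs[1]), 1)
  s7 <- classify_lab(rep(0.5, 50), rep(0.5, 50))
  expect_equal(unname(s7$class_freqs[7]), 1)
  # monomorphic-identical loci are excluded
  s0 <- classify_lab(c(0, 1, 0.5), c(0, 1, 0.5))
  expect_equal(attr(s0, "n_excluded"), 2)
  expect_equal(s0$total, 1)
  # singletons in 20 alleles count as fixed
  expect_equal(unname(classify_lab(0.05, 1)$class_freqs[1]), 1)
})

test_that("the divergent-polymorphism class is structurally empty in simulation", {
  p <- small_params(max_years = 1000, mig_prob_per_year = 0.01,
                    mig_frac = 0.01)
  traj <- wf_run_split(p, seed = 3)
  expect_true(all(traj$checkpoints$n_classified > 0))
  # classify_lab tabulates over 8 classes; class 8 never occurs
  s <- traj$final_summary
  expect_equal(unname(s$counts[8]), 0)
  expect_equal(sum(s$counts[1:7]), s$total)
})

test_that("checkpoints advance the year clock in fixed steps", {
  p <- small_params(max_years = 1000)
  traj <- wf_run_split(p, seed = 2)
  expect_equal(traj$checkpoints$year, seq(100, 1000, by = 100))
  expect_error(wf_run_split(small_params(max_years = 50)), "horizon")
})

test_that("runs are reproducible given the seed", {
  p <- small_params(max_years = 500)
  a <- wf_run_split(p, seed = 31)
  b <- wf_run_split(p, seed = 31)
  expect_identical(a$checkpoints, b$checkpoints)
})

test_that("class frequencies do not depend on the mutation rate", {
  p1 <- small_params(max_years = 2000, u = 0.02)
  p2 <- small_params(max_years = 2000, u = 0.06)
  mean_freqs <- function(p, seeds) {
    runs <- lapply(seeds, function(s) {
      cp <- wf_run_split(p, seed = s)$checkpoints
      colMeans(cp[cp$year >= 1000, paste0("class", 1:7)])
    })
    Reduce(`+`, runs) / length(runs)
  }
  f1 <- mean_freqs(p1, 101:103)
  f2 <- mean_freqs(p2, 201:203)
  expect_lt(max(abs(f1 - f2)), 0.05)
})

test_that("fixation is transiently faster in the small population", {
  # shortly after an equal-start split with n_cf << n_sf, fixed derived
  # alleles accumulate faster in the cave than in the surface population
  p <- small_params(max_years = 2500)
  traj <- wf_run_split(p, seed = 17)
  cp <- traj$checkpoints
  mid <- cp$year >= 500 & cp$year <= 2500
  expect_gt(sum(cp$fixed_derived_cf[mid]), sum(cp$fixed_derived_sf[mid]))
})

test_that("exchangeable populations give symmetric class frequencies", {
  p <- small_params(n_cf = 1000, g_cf = 2, g_sf = 2, max_years = 1500)
  runs <- lapply(1:4, function(s) {
    cp <- wf_run_split(p, seed = 300 + s)$checkpoints
    colMeans(cp[, paste0("class", 1:7)])
  })
  f <- Reduce(`+`, runs) / length(runs)
  # class 1 vs 2, 3 vs 5, 4 vs 6 agree within Monte-Carlo error
  expect_lt(abs(f[1] - f[2]), 0.04)
  expect_lt(abs(f[3] - f[5]), 0.04)
  expect_lt(abs(f[4] - f[6]), 0.04)
})
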