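#' Demographic parameters for the isolation-with-migration simulation
#'
#' Bundles every knob of the forward simulation: effective sizes of the
#' ancestral, surface (SF) and cave (CF) populations; generation times in
#' years; the per-haploid-genome per-generation probability `u` of a new SNP
#' arising at a new locus; the surface-to-cave pulse-migration law (a pulse
#' occurs in a given year with probability `mig_prob_per_year` and then
#' replaces a fraction `mig_frac` of the cave gene pool by the surface pool);
#' and the laboratory observation model (sample `lab_n_fish` diploids, then
#' `lab_gens` Wright-Fisher generations at effective size `lab_ne`).
#'
#' The checkpoint interval must be a common multiple of both generation times
#' so every checkpoint falls just after a reproduction of each population
#' (with the defaults, 100 years = 50 SF generations = 20 CF generations).
#'
#' @param n_anc,n_sf,n_cf Diploid effective sizes (ancestral, surface, cave).
#' @param g_sf,g_cf Generation times in years (defaults 2 and 5).
#' @param u New-SNP probability per haploid genome per generation
#'   (default 0.02), giving a mean mutation input of `2*N*u` new loci per
#'   generation, each starting at frequency `1/(2*N)`.
#' @param mig_prob_per_year Probability of a migration pulse in a given year.
#' @param mig_frac Fraction of the cave gene pool replaced per pulse.
#' @param lab_n_fish,lab_ne,lab_gens Lab observation model (defaults 10/10/10).
#' @param checkpoint_years Years between summary-statistic evaluations
#'   (default 100).
#' @param max_years Simulation horizon in years.
#' @param maf_min Minor-allele-frequency threshold used when classifying lab
#'   samples (default 0.05; with 20 sampled alleles a singleton counts as
#'   fixed).
#' @return An object of class `"demographic_params"`.
#' @examples
#' demographic_params(n_anc = 10000, n_sf = 10000, n_cf = 1250,
#'                    mig_prob_per_year = 0.001, mig_frac = 0.01,
#'                    max_years = 50000)
#' @export
demographic_params <- function(n_anc, n_sf, n_cf, g_sf = 2, g_cf = 5,
                               u = 0.02, mig_prob_per_year = 0, mig_frac = 0,
                               lab_n_fish = 10, lab_ne = 10, lab_gens = 10,
                               checkpoint_years = 100, max_years = 50000,
                               maf_min = 0.05) {
  stopifnot(n_anc >= 1, n_sf >= 1, n_cf >= 1, g_sf >= 1, g_cf >= 1,
            u >= 0, mig_prob_per_year >= 0, mig_prob_per_year <= 1,
            mig_frac >= 0, mig_frac <= 1,
            lab_n_fish >= 1, lab_ne >= 1, lab_gens >= 0,
            checkpoint_years >= 1, max_years >= 1,
            maf_min >= 0, maf_min < 0.5)
  if (checkpoint_years %% g_sf != 0 || checkpoint_years %% g_cf != 0)
    stop("checkpoint_years must be a multiple of both generation times")
  structure(list(n_anc = n_anc, n_sf = n_sf, n_cf = n_cf,
                 g_sf = g_sf, g_cf = g_cf, u = u,
                 mig_prob_per_year = mig_prob_per_year, mig_frac = mig_frac,
                 lab_n_fish = lab_n_fish, lab_ne = lab_ne,
                 lab_gens = lab_gens, checkpoint_years = checkpoint_years,
                 max_years = max_years, maf_min = maf_min),
            class = "demographic_params")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters\n")
  cat(sprintf("  sizes: ancestral %g, surface %g, cave %g\n",
              x$n_anc, x$n_sf, x$n_cf))
  cat(sprintf("  generation times: SF %g yr, CF %g yr; u = %g\n",
              x$g_sf, x$g_cf, x$u))
  cat(sprintf("  migration: pulse prob %g / yr, fraction %g\n",
              x$mig_prob_per_year, x$mig_frac))
  cat(sprintf("  lab model: %g fish, Ne %g, %g generations\n",
              x$lab_n_fish, x$lab_ne, x$lab_gens))
  cat(sprintf("  checkpoints every %g yr up to %g yr\n",
              x$checkpoint_years, x$max_years))
  invisible(x)
}

#' Expected number and initial frequency of new mutations
#'
#' Mean mutation input per generation under the infinite-sites model: a
#' population of diploid size `N` gains on average `2*N*u` new segregating
#' loci per generation, each starting at frequency `1/(2*N)`.
#'
#' @param N Diploid population size.
#' @param u New-SNP probability per haploid genome per generation.
#' @return Named numeric vector with `mean_new_snps` and `init_freq`.
#' @examples
#' mutation_input(10000, 0.02)  # 400 new SNPs at frequency 5e-5
#' @export
mutation_input <- function(N, u) {
  stopifnot(N >= 1, u >= 0)
  c(mean_new_snps = 2 * N * u, init_freq = 1 / (2 * N))
}

#' One Wright-Fisher generation with mutation input
#'
#' Resamples each locus frequency as a binomial draw of `2*N` trials at the
#' current frequency, then appends a Poisson(`2*N*u`) number of new loci at
#' frequency `1/(2*N)`. Frequencies 0 and 1 are absorbing (no pruning is done
#' here).
#'
#' @param freqs Numeric vector of derived-allele frequencies in `[0, 1]`.
#' @param N Diploid population size.
#' @param u New-SNP probability per haploid genome per generation.
#' @return The next generation's frequency vector (possibly longer).
#' @export
wf_generation <- function(freqs, N, u = 0) {
  stopifnot(N >= 1, u >= 0)
  two_n <- 2 * N
  f <- if (length(freqs)) stats::rbinom(length(freqs), two_n, freqs) / two_n
       else numeric(0)
  k <- stats::rpois(1, two_n * u)
  if (k > 0) f <- c(f, rep.int(1 / two_n, k))
  f
}

#' Ancestral burn-in to mutation/drift equilibrium
#'
#' Produces the segregating-locus frequency vector of an ancestral population
#' of diploid size `n_anc` at mutation/drift equilibrium. By default the
#' locus set is initialized from the analytic neutral infinite-sites spectrum
#' (a Poisson(`4*n_anc*u/i`) number of loci at each derived count
#' `i = 1..2N-1`) and then evolved for `generations` Wright-Fisher
#' generations (default 1000) to let sampling noise equilibrate;
#' `init = "empty"` instead starts from no variation and runs
#' `10 * n_anc` generations, long enough for the segregating-site count to
#' reach its stationary value `4*n_anc*u * sum(1/i)`.
#'
#' Loci fixed (frequency 1) or lost (frequency 0) are pruned each generation;
#' fixed loci are substitutions and carry no further polymorphism signal.
#'
#' @param n_anc Ancestral diploid size.
#' @param u New-SNP probability per haploid genome per generation.
#' @param generations Number of burn-in generations (`NULL` for the default
#'   of the chosen `init`).
#' @param init `"spectrum"` (default) or `"empty"`.
#' @return Numeric vector of segregating derived-allele frequencies.
#' @examples
#' f <- wf_burn_in(200, 0.02, init = "spectrum")
#' length(f)  # fluctuates around 4*200*0.02*sum(1/(1:399)) ~ 103
#' @export
wf_burn_in <- function(n_anc, u, generations = NULL,
                       init = c("spectrum", "empty")) {
  init <- match.arg(init)
  stopifnot(n_anc >= 1, u >= 0)
  two_n <- 2 * n_anc
  if (init == "spectrum") {
    i <- seq_len(two_n - 1)
    counts <- stats::rpois(two_n - 1, 4 * n_anc * u / i)
    freqs <- rep.int(i / two_n, counts)
    if (is.null(generations)) generations <- 1000L
  } else {
    freqs <- numeric(0)
    if (is.null(generations)) generations <- 10L * n_anc
  }
  for (g in seq_len(generations)) {
    freqs <- wf_generation(freqs, n_anc, u)
    freqs <- freqs[freqs > 0 & freqs < 1]
  }
  freqs
}

#' Deterministic surface-to-cave admixture
#'
#' A migration pulse replaces a fraction `mig_frac` of the cave gene pool by
#' the surface gene pool: `freq_cf' = (1 - mig_frac) * freq_cf + mig_frac *
#' freq_sf` per locus. The surface population is unchanged (cave-to-surface
#' migration is taken as negligible); drift acts at the next cave
#' reproduction.
#'
#' @param freq_cf,freq_sf Aligned frequency vectors.
#' @param mig_frac Migrant fraction in `[0, 1]`.
#' @return The post-pulse cave frequency vector.
#' @export
wf_migrate <- function(freq_cf, freq_sf, mig_frac) {
  stopifnot(mig_frac >= 0, mig_frac <= 1,
            length(freq_cf) == length(freq_sf))
  (1 - mig_frac) * freq_cf + mig_frac * freq_sf
}

#' Laboratory sampling and drift observation model
#'
#' Simulates establishing a lab stock from the wild: per locus,
#' `2 * lab_n_fish` alleles are drawn binomially from the wild frequency, and
#' the stock then drifts for `lab_gens` Wright-Fisher generations at constant
#' effective size `lab_ne` with no mutation. The wild population is
#' unchanged (the draw is virtual).
#'
#' @param freqs Wild derived-allele frequencies.
#' @param lab_n_fish Number of diploid founders sampled (default 10).
#' @param lab_ne Lab effective size (default 10).
#' @param lab_gens Lab generations (default 10).
#' @return Vector of lab derived-allele frequencies.
#' @export
wf_lab_sample <- function(freqs, lab_n_fish = 10, lab_ne = 10, lab_gens = 10) {
  stopifnot(lab_n_fish >= 1, lab_ne >= 1, lab_gens >= 0)
  n <- length(freqs)
  if (n == 0L) return(numeric(0))
  f <- stats::rbinom(n, 2 * lab_n_fish, freqs) / (2 * lab_n_fish)
  two_ne <- 2 * lab_ne
  for (g in seq_len(lab_gens)) f <- stats::rbinom(n, two_ne, f) / two_ne
  f
}

#' Classify simulated lab samples into the seven SNP classes
#'
#' For loci whose derived allele is known by construction (the simulator's
#' mutant allele), assigns each locus to the joint polymorphism classes of
#' [classify_site()] from its lab-sample derived-allele frequencies. A
#' population is fixed ancestral when the derived frequency is `<= maf_min`,
#' fixed derived when it is `>= 1 - maf_min`, and polymorphic otherwise. Loci
#' monomorphic for the same allele in both lab samples are excluded. Under
#' the infinite-sites model each locus has exactly two alleles, so the
#' divergent-polymorphism class 8 is structurally empty.
#'
#' @param lab_sf,lab_cf Aligned lab derived-allele frequency vectors.
#' @param maf_min Polymorphism-calling threshold (default 0.05).
#' @return A `"class_summary"` object (see [class_summary()]) with an
#'   `n_excluded` attribute counting monomorphic-identical loci.
#' @export
classify_lab <- function(lab_sf, lab_cf, maf_min = 0.05) {
  stopifnot(length(lab_sf) == length(lab_cf))
  # 0 = fixed ancestral, 1 = fixed derived, 2 = polymorphic
  state <- function(f) ifelse(f <= maf_min, 0L, ifelse(f >= 1 - maf_min, 1L, 2L))
  s_sf <- state(lab_sf); s_cf <- state(lab_cf)
  # class lookup by 3 * sf_state + cf_state
  lut <- c(NA, 1L, 3L,   # sf anc: cf anc (excluded), cf der, cf poly
           2L, NA, 4L,   # sf der: cf anc, cf der (excluded), cf poly
           5L, 6L, 7L)   # sf poly: cf anc, cf der, cf poly
  cls <- lut[3L * s_sf + s_cf + 1L]
  counts <- tabulate(cls, nbins = 8L)
  out <- .summary_from_counts(counts)
  attr(out, "n_excluded") <- sum(is.na(cls))
  out
}

#' Forward simulation of a population split with migration and lab sampling
#'
#' Runs the isolation-with-migration model forward on a one-year clock: an
#' ancestral population at mutation/drift equilibrium splits into surface and
#' cave populations that inherit its frequency vector and reproduce every
#' `g_sf` and `g_cf` years at sizes `n_sf` and `n_cf` (binomial drift plus
#' Poisson mutation input at new loci). Each year a surface-to-cave migration
#' pulse occurs with probability `mig_prob_per_year` (evaluated before any
#' reproduction that year). Loci lost in both populations are pruned; loci
#' fixed in both are pruned and counted as shared substitutions. At every
#' checkpoint (`checkpoint_years`), both populations are virtually sampled
#' through the lab observation model ([wf_lab_sample()]), classified
#' ([classify_lab()]) and the summary statistics recorded; when `observed`
#' class frequencies are supplied each checkpoint also gets a goodness-of-fit
#' score ([gof_score()]).
#'
#' @param params A [demographic_params()] object.
#' @param observed Optional observed 7-class frequency vector or
#'   `"class_summary"` object to score against.
#' @param ancestral_freqs Optional pre-computed ancestral frequency vector;
#'   by default [wf_burn_in()] is run.
#' @param seed Optional integer seed (sets R's RNG for a reproducible run).
#' @return An object of class `"wf_trajectory"`: a list with `checkpoints`
#'   (data frame of year, the seven class frequencies, classified-locus
#'   count, polymorphism and fixed-derived counts and ratios, and `score` if
#'   `observed` was given), `params`, `shared_substitutions` and
#'   `n_loci_final`.
#' @examples
#' p <- demographic_params(n_anc = 500, n_sf = 500, n_cf = 60,
#'                         max_years = 2000)
#' traj <- wf_run_split(p, seed = 1)
#' head(traj$checkpoints)
#' @export
wf_run_split <- function(params, observed = NULL, ancestral_freqs = NULL,
                         seed = NULL) {
  stopifnot(inherits(params, "demographic_params"))
  if (!is.null(seed)) set.seed(seed)
  if (params$max_years < params$checkpoint_years)
    stop("simulation horizon shorter than one checkpoint interval")
  obs <- if (is.null(observed)) NULL else .as_freq7(observed)

  if (is.null(ancestral_freqs))
    ancestral_freqs <- wf_burn_in(params$n_anc, params$u)
  f_sf <- ancestral_freqs
  f_cf <- ancestral_freqs

  n_cp <- params$max_years %/% params$checkpoint_years
  cp <- matrix(NA_real_, nrow = n_cp, ncol = 16,
               dimnames = list(NULL, c(
                 "year", paste0("class", 1:7), "n_classified",
                 "poly_sf", "poly_cf", "ratio_sf_cf",
                 "fixed_derived_sf", "fixed_derived_cf", "ratio_cf_sf",
                 "score")))
  shared_subs <- 0L
  two_sf <- 2 * params$n_sf
  two_cf <- 2 * params$n_cf
  do_mig <- params$mig_prob_per_year > 0 && params$mig_frac > 0
  row <- 0L
  last_summary <- NULL

  for (year in seq_len(params$max_years)) {
    if (do_mig && stats::runif(1) < params$mig_prob_per_year)
      f_cf <- wf_migrate(f_cf, f_sf, params$mig_frac)
    repro <- FALSE
    if (year %% params$g_sf == 0) {
      f_sf <- stats::rbinom(length(f_sf), two_sf, f_sf) / two_sf
      k <- stats::rpois(1, two_sf * params$u)
      if (k > 0) {
        f_sf <- c(f_sf, rep.int(1 / two_sf, k))
        f_cf <- c(f_cf, numeric(k))
      }
      repro <- TRUE
    }
    if (year %% params$g_cf == 0) {
      f_cf <- stats::rbinom(length(f_cf), two_cf, f_cf) / two_cf
      k <- stats::rpois(1, two_cf * params$u)
      if (k > 0) {
        f_cf <- c(f_cf, rep.int(1 / two_cf, k))
        f_sf <- c(f_sf, numeric(k))
      }
      repro <- TRUE
    }
    if (repro) {
      lost <- f_sf == 0 & f_cf == 0
      fixed <- f_sf == 1 & f_cf == 1
      if (any(lost) || any(fixed)) {
        shared_subs <- shared_subs + sum(fixed)
        keep <- !(lost | fixed)
        f_sf <- f_sf[keep]
        f_cf <- f_cf[keep]
      }
    }
    if (year %% params$checkpoint_years == 0) {
      row <- row + 1L
      lab_sf <- wf_lab_sample(f_sf, params$lab_n_fish, params$lab_ne,
                              params$lab_gens)
      lab_cf <- wf_lab_sample(f_cf, params$lab_n_fish, params$lab_ne,
                              params$lab_gens)
      s <- classify_lab(lab_sf, lab_cf, params$maf_min)
      last_summary <- s
      cp[row, ] <- c(year, s$class_freqs, sum(s$counts[1:7]),
                     s$poly_sf, s$poly_cf, s$ratio_sf_cf,
                     s$fixed_derived_sf, s$fixed_derived_cf, s$ratio_cf_sf,
                     if (is.null(obs)) NA_real_
                     else gof_score(s$class_freqs, obs))
    }
  }
  checkpoints <- as.data.frame(cp[seq_len(row), , drop = FALSE])
  if (is.null(obs)) checkpoints$score <- NULL
  structure(list(checkpoints = checkpoints, params = params,
                 observed = obs, shared_substitutions = shared_subs,
                 n_loci_final = length(f_sf), final_summary = last_summary),
            class = "wf_trajectory")
}

#' @export
print.wf_trajectory <- function(x, ...) {
  cat("Wright-Fisher split trajectory:", nrow(x$checkpoints),
      "checkpoints over", max(x$checkpoints$year), "years\n")
  cat("  tracked loci at end:", x$n_loci_final,
      "; shared substitutions pruned:", x$shared_substitutions, "\n")
  invisible(x)
}

#' Plot class-frequency and summary-statistic trajectories
#'
#' @param x A `"wf_trajectory"` object.
#' @param which Panels to draw: 1 = the seven class frequencies through time
#'   (with dotted observed frequencies if available), 2 = polymorphic-site
#'   counts, 3 = SF/CF polymorphism and CF/SF fixed-derived ratios.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.wf_trajectory <- function(x, which = 1, ...) {
  cp <- x$checkpoints
  if (1 %in% which) {
    graphics::matplot(cp$year, as.matrix(cp[paste0("class", 1:7)]),
                      type = "l", lty = 1, col = 1:7,
                      xlab = "age of the cave population (years)",
                      ylab = "SNP class frequency", ...)
    if (!is.null(x$observed))
      graphics::abline(h = x$observed, col = 1:7, lty = 3)
    graphics::legend("topright", legend = paste("class", 1:7),
                     col = 1:7, lty = 1, cex = 0.7)
  }
  if (2 %in% which) {
    graphics::matplot(cp$year, cbind(cp$poly_sf, cp$poly_cf), type = "l",
                      lty = 1, col = c(4, 2),
                      xlab = "age (years)", ylab = "polymorphic loci", ...)
    graphics::legend("topright", c("SF", "CF"), col = c(4, 2), lty = 1)
  }
  if (3 %in% which) {
    graphics::matplot(cp$year, cbind(cp$ratio_sf_cf, cp$ratio_cf_sf),
                      type = "l", lty = 1, col = c(4, 2),
                      xlab = "age (years)", ylab = "ratio", ...)
    graphics::legend("topright", c("polymorphism SF/CF", "fixed derived CF/SF"),
                     col = c(4, 2), lty = 1)
  }
  invisible(x)
}

#' Mean time to fixation of a neutral allele, conditional on fixation
#'
#' Diffusion approximation for a neutral allele at frequency `p` in a
#' Wright-Fisher population of diploid size `N`:
#' `t1(p) = -4 * N * ((1 - p) / p) * log(1 - p)` generations. As `p` tends to
#' `1/(2N)` this approaches the classical `4N` generations for a new
#' mutation; as `p` tends to 1 it approaches 0.
#'
#' @param p Initial allele frequency, strictly inside (0, 1); vectorized.
#' @param N Diploid population size.
#' @return Expected generations to fixation conditional on fixation.
#' @examples
#' expected_fixation_time(0.5, 50)  # 200 * log(2)
#' @export
expected_fixation_time <- function(p, N) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  stopifnot(N >= 1)
  -4 * N * ((1 - p) / p) * log(1 - p)
}

# coerce observed input to a normalized 7-class frequency vector
.as_freq7 <- function(observed) {
  if (inherits(observed, "class_summary")) observed <- observed$class_freqs
  if (length(observed) == 8L) observed <- observed[1:7] / sum(observed[1:7])
  stopifnot(length(observed) == 7L, all(observed >= 0))
  if (abs(sum(observed) - 1) > 1e-6)
    stop("observed class frequencies must sum to 1")
  as.numeric(observed)
}
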