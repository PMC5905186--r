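#' Goodness-of-fit score between simulated and observed class frequencies
#'
#' Chi-square-type distance between two 7-class frequency vectors:
#' `sum((sim - obs)^2 / pmax(obs, eps))`. It is zero iff the vectors are
#' equal, non-negative, and invariant under any permutation applied to both
#' vectors. The distance is isolated behind this one function so that
#' alternatives (Euclidean, Hellinger) can be swapped without touching the
#' fitting machinery; the estimated age, being an argmin, is robust to the
#' choice among sensible distances while the absolute score scale is not
#' comparable across distances.
#'
#' @param sim,obs Numeric frequency vectors of equal length, each summing to
#'   1 (checked to 1e-6).
#' @param eps Floor applied to `obs` in the denominator (default 1e-6).
#' @return A non-negative score.
#' @examples
#' gof_score(rep(1/7, 7), rep(1/7, 7))     # 0
#' gof_score(c(1, rep(0, 6)), rep(1/7, 7)) # 6
#' @export
gof_score <- function(sim, obs, eps = 1e-6) {
  if (length(sim) != length(obs))
    stop("sim and obs must have the same length")
  if (abs(sum(sim) - 1) > 1e-6 || abs(sum(obs) - 1) > 1e-6)
    stop("sim and obs must each sum to 1")
  sum((sim - obs)^2 / pmax(obs, eps))
}

#' Estimate the divergence age of the cave population
#'
#' Fits the isolation-with-migration model to observed SNP class frequencies
#' by forward simulation: the model is simulated once over the full horizon
#' ([wf_run_split()]), the goodness-of-fit score ([gof_score()]) between the
#' simulated and observed 7-class frequencies is evaluated at every
#' checkpoint age, and the divergence age is estimated as the checkpoint age
#' minimizing the score. Ties resolve to the earliest (youngest) age. In long
#' runs the score profile is U-shaped: ancestral shared polymorphism makes
#' young ages fit poorly, while past the optimum the populations keep
#' diverging and the fit degrades again.
#'
#' @param observed Observed class frequencies: a `"class_summary"` object
#'   (e.g. `class_summary(observed_snp_classes()[, "synonymous"])`), an
#'   8-vector of class counts, or a normalized 7-vector of frequencies.
#' @param params A [demographic_params()] object.
#' @param max_years Optional override of `params$max_years`.
#' @param seed Optional integer seed; the fit is deterministic given
#'   `(params, seed)`.
#' @param ancestral_freqs Optional precomputed ancestral frequency vector
#'   (skips the burn-in).
#' @return An object of class `"divfit"` with components `ages`, `scores`,
#'   `best_age`, `best_score`, `observed`, `trajectory`, `params` and
#'   `seed`. Supported methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `plot` and `simulate`.
#' @examples
#' \donttest{
#' obs <- class_summary(observed_snp_classes()[, "synonymous"])
#' p <- demographic_params(n_anc = 1000, n_sf = 1000, n_cf = 125,
#'                         max_years = 6000)
#' fit <- fit_divergence_age(obs, p, seed = 1)
#' coef(fit)
#' }
#' @export
fit_divergence_age <- function(observed, params, max_years = NULL,
                               seed = NULL, ancestral_freqs = NULL) {
  stopifnot(inherits(params, "demographic_params"))
  if (!is.null(max_years)) {
    params$max_years <- max_years
    if (max_years < params$checkpoint_years)
      stop("max_years is shorter than one checkpoint interval")
  }
  obs <- .as_freq7(observed)
  traj <- wf_run_split(params, observed = obs,
                       ancestral_freqs = ancestral_freqs, seed = seed)
  cp <- traj$checkpoints
  best <- which.min(cp$score)  # earliest age on ties
  structure(list(ages = cp$year, scores = cp$score,
                 best_age = cp$year[best], best_score = cp$score[best],
                 observed = obs, trajectory = traj, params = params,
                 seed = seed, call = match.call()),
            class = "divfit")
}

#' @export
print.divfit <- function(x, ...) {
  cat("Divergence-age fit by forward Wright-Fisher simulation\n")
  cat(sprintf("  best-fit age: %g years (score %.4g) over %d checkpoint ages\n",
              x$best_age, x$best_score, length(x$ages)))
  invisible(x)
}

#' @export
coef.divfit <- function(object, ...) {
  c(divergence_age = object$best_age)
}

#' @export
fitted.divfit <- function(object, ...) {
  cp <- object$trajectory$checkpoints
  f <- as.numeric(cp[cp$year == object$best_age, paste0("class", 1:7)])
  stats::setNames(f, paste0("class", 1:7))
}

#' @export
residuals.divfit <- function(object, ...) {
  stats::fitted(object) - stats::setNames(object$observed, paste0("class", 1:7))
}

#' @export
summary.divfit <- function(object, ...) {
  tab <- cbind(observed = object$observed, simulated = stats::fitted(object),
               residual = stats::residuals(object))
  rownames(tab) <- paste0("class", 1:7)
  structure(list(fit = object, comparison = tab), class = "summary.divfit")
}

#' @export
print.summary.divfit <- function(x, ...) {
  print(x$fit)
  p <- x$fit$params
  cat(sprintf("  model: N = %g/%g/%g (anc/SF/CF), g = %g/%g yr, mig %g/yr x %g\n",
              p$n_anc, p$n_sf, p$n_cf, p$g_sf, p$g_cf,
              p$mig_prob_per_year, p$mig_frac))
  cat("  class frequencies at the best-fit age:\n")
  print(round(x$comparison, 4))
  invisible(x)
}

#' Plot a divergence-age fit
#'
#' @param x A `"divfit"` object.
#' @param which Panels: 1 = score against candidate age with the best-fit age
#'   marked; 2 = simulated class-frequency trajectories with the observed
#'   frequencies as dotted lines.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.divfit <- function(x, which = 1, ...) {
  if (1 %in% which) {
    graphics::plot(x$ages, x$scores, type = "l",
                   xlab = "age of the cave population (years)",
                   ylab = "goodness-of-fit score", ...)
    graphics::abline(v = x$best_age, lty = 2)
    graphics::mtext(sprintf("best fit at %g years", x$best_age),
                    side = 3, line = 0.2, cex = 0.8)
  }
  if (2 %in% which) plot(x$trajectory, which = 1, ...)
  invisible(x)
}

#' Replicate a divergence-age fit under new seeds
#'
#' Re-runs the full simulate-and-score procedure `nsim` times with seeds
#' derived from `seed`, returning the replicate best-fit ages and scores.
#'
#' @param object A `"divfit"` object.
#' @param nsim Number of replicate fits.
#' @param seed Master seed for deriving replicate seeds.
#' @param ... Unused.
#' @return Data frame with columns `replicate`, `best_age`, `best_score`.
#' @export
simulate.divfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  out <- lapply(seq_len(nsim), function(i) {
    fit <- fit_divergence_age(object$observed, object$params, seed = seeds[i])
    data.frame(replicate = i, best_age = fit$best_age,
               best_score = fit$best_score)
  })
  do.call(rbind, out)
}

#' Sweep a grid of demographic parameters
#'
#' Runs [fit_divergence_age()] for every row of a parameter grid, with
#' `replicates` independent seeds per grid point. Replicate seeds are drawn
#' up-front from the master seed, so results are reproducible given `seed`
#' regardless of evaluation order.
#'
#' @param grid Data frame whose columns are [demographic_params()] argument
#'   names; each row overrides `base`.
#' @param observed Observed class frequencies (as in [fit_divergence_age()]).
#' @param base A [demographic_params()] object providing values not in the
#'   grid.
#' @param replicates Independent fits per grid point (default 1).
#' @param seed Master seed.
#' @return Data frame: the grid columns plus `replicate`, `best_age`,
#'   `best_score`, sortable by `best_score`.
#' @export
sweep_divergence_fits <- function(grid, observed, base, replicates = 1,
                                  seed = NULL) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0, replicates >= 1,
            inherits(base, "demographic_params"))
  bad <- setdiff(names(grid), names(base))
  if (length(bad))
    stop("unknown parameter columns: ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * replicates),
                  nrow = nrow(grid))
  rows <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    p <- base
    for (col in names(grid)) p[[col]] <- grid[[col]][i]
    p <- do.call(demographic_params, unclass(p))
    for (r in seq_len(replicates)) {
      fit <- fit_divergence_age(observed, p, seed = seeds[i, r])
      k <- k + 1L
      rows[[k]] <- cbind(grid[i, , drop = FALSE],
                         data.frame(replicate = r, best_age = fit$best_age,
                                    best_score = fit$best_score))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
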