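#' Generate a synthetic SNP site table with known class structure
#'
#' Draws site class labels multinomially and materializes allele counts
#' consistent with each class (fixed vs polymorphic per population, outgroup
#' set to the ancestral allele), plus pooled depths, contig e-values and
#' positions spaced beyond the isolation threshold. Optionally injects
#' controlled fractions of filter-violating sites: shallow depth, e-value
#' above threshold, clustered positions (placed near another injected site so
#' the violating set is exactly the injected set), and sub-threshold minor
#' allele frequency.
#'
#' Within polymorphic populations the minor allele frequency is drawn
#' uniformly just above `maf_min` up to 0.5, and the derived allele is the
#' minor or major allele with equal probability; class membership, not the
#' within-class frequency, drives every downstream statistic.
#'
#' The biallelic site-table schema cannot represent a three-allele divergent
#' polymorphism, so `class_probs[8]` must be 0.
#'
#' @param n_sites Number of sites: a single count (annotated `"synonymous"`)
#'   or a named vector of counts per annotation category.
#' @param class_probs Probabilities of classes 1--8 (normalized internally;
#'   class 8 must be 0). Default: the observed synonymous class proportions
#'   with class 8 zeroed.
#' @param frac_fail Named numeric vector of fractions of sites to inject per
#'   filter rule, with names among `depth`, `evalue`, `spacing`, `maf`.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (defaults `log(800)` and 0.4, floored at 120 for passing sites).
#' @param maf_min MAF threshold the generated polymorphisms must exceed.
#' @param min_isolation_bp Spacing threshold the generated positions respect.
#' @param seed Optional integer seed.
#' @return A site-table data frame (see [read_sites()]) with attributes
#'   `true_class` (integer class per site, `NA` for injected filter-failing
#'   sites) and `fail_rule` (`""` or the injected rule).
#' @examples
#' tab <- make_site_table(n_sites = 200, seed = 1)
#' table(attr(tab, "true_class"))
#' @export
make_site_table <- function(n_sites = 1000, class_probs = NULL,
                            frac_fail = c(depth = 0, evalue = 0,
                                          spacing = 0, maf = 0),
                            depth_meanlog = log(800), depth_sdlog = 0.4,
                            maf_min = 0.05, min_isolation_bp = 50,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(class_probs)) {
    class_probs <- observed_snp_classes()[, "synonymous"]
    class_probs[8] <- 0
  }
  stopifnot(length(class_probs) == 8L, all(class_probs >= 0),
            sum(class_probs) > 0)
  if (class_probs[8] != 0)
    stop("class 8 (divergent polymorphism) needs three alleles and cannot ",
         "be represented in the biallelic site-table schema; set its ",
         "probability to 0")
  class_probs <- class_probs / sum(class_probs)
  if (is.null(names(n_sites))) names(n_sites) <- rep("synonymous", length(n_sites))
  fr <- c(depth = 0, evalue = 0, spacing = 0, maf = 0)
  fr[names(frac_fail)] <- frac_fail
  stopifnot(all(fr >= 0), sum(fr) < 1)

  n <- sum(n_sites)
  annotation <- rep(names(n_sites), n_sites)
  cls <- sample.int(8L, n, replace = TRUE, prob = class_probs)

  ancestral <- sample(.NUC, n, replace = TRUE)
  derived <- vapply(ancestral, function(a) sample(setdiff(.NUC, a), 1L),
                    character(1))

  draw_poly <- function(k) {
    m <- stats::runif(k, maf_min + 0.01, 0.5)
    ifelse(stats::runif(k) < 0.5, m, 1 - m)
  }
  p_sf <- numeric(n); p_cf <- numeric(n)
  p_sf[cls == 1] <- 0; p_cf[cls == 1] <- 1
  p_sf[cls == 2] <- 1; p_cf[cls == 2] <- 0
  p_sf[cls == 3] <- 0; p_cf[cls == 3] <- draw_poly(sum(cls == 3))
  p_sf[cls == 4] <- 1; p_cf[cls == 4] <- draw_poly(sum(cls == 4))
  p_sf[cls == 5] <- draw_poly(sum(cls == 5)); p_cf[cls == 5] <- 0
  p_sf[cls == 6] <- draw_poly(sum(cls == 6)); p_cf[cls == 6] <- 1
  p_sf[cls == 7] <- draw_poly(sum(cls == 7))
  p_cf[cls == 7] <- draw_poly(sum(cls == 7))

  depth <- function(k) pmax(120, round(stats::rlnorm(k, depth_meanlog,
                                                     depth_sdlog)))
  sf_depth <- depth(n); cf_depth <- depth(n)

  # contigs of ~20 sites; gaps comfortably beyond the isolation threshold
  contig <- sprintf("ctg%05d", (seq_len(n) - 1L) %/% 20L + 1L)
  gap <- sample((min_isolation_bp + 20L):1500L, n, replace = TRUE)
  pos <- stats::ave(gap, contig, FUN = cumsum)
  evalue <- 10^-stats::runif(n, 6, 30)

  fail_rule <- rep("", n)
  k_fail <- round(fr * n)
  if (sum(k_fail) > 0) {
    flagged <- sample.int(n, sum(k_fail))
    split_idx <- split(flagged, rep(names(k_fail), k_fail))
    # shallow depth in one population
    for (i in split_idx$depth) {
      sf_depth[i] <- sample(10:99, 1L)
      fail_rule[i] <- "depth"
    }
    for (i in split_idx$evalue) {
      evalue[i] <- 10^-stats::runif(1, 0, 4.5)
      fail_rule[i] <- "evalue"
    }
    # clustered positions: satellites moved next to an anchor, so only
    # injected sites violate the spacing rule
    sp <- split_idx$spacing
    if (length(sp) == 1L) {
      warning("a single spacing-failing site needs a partner; none injected")
    } else if (length(sp) > 1L) {
      anchors <- sp[seq(1L, length(sp) - 1L, by = 2L)]
      sats <- sp[seq(2L, length(sp), by = 2L)]
      if (length(sp) %% 2L == 1L) sats <- c(sats, sp[length(sp)])
      for (j in seq_along(sats)) {
        a <- anchors[min(j, length(anchors))]
        s <- sats[j]
        contig[s] <- contig[a]
        off <- sample(5:19, 1L)
        pos[s] <- if (j > length(anchors)) pos[a] - off else pos[a] + off
      }
      fail_rule[sp] <- "spacing"
    }
    # sub-threshold MAF: the only non-monomorphic population has MAF <= maf_min
    for (i in split_idx$maf) {
      p_sf[i] <- 0
      p_cf[i] <- max(1, round(0.6 * maf_min * cf_depth[i])) / cf_depth[i]
      fail_rule[i] <- "maf"
    }
  }

  sf_der <- round(p_sf * sf_depth)
  cf_der <- round(p_cf * cf_depth)
  swap <- stats::runif(n) < 0.5
  allele1 <- ifelse(swap, derived, ancestral)
  allele2 <- ifelse(swap, ancestral, derived)
  out <- data.frame(
    contig = contig, pos = as.integer(pos),
    allele1 = allele1, allele2 = allele2,
    sf_count1 = as.integer(ifelse(swap, sf_der, sf_depth - sf_der)),
    sf_count2 = as.integer(ifelse(swap, sf_depth - sf_der, sf_der)),
    cf_count1 = as.integer(ifelse(swap, cf_der, cf_depth - cf_der)),
    cf_count2 = as.integer(ifelse(swap, cf_depth - cf_der, cf_der)),
    sf_depth = as.integer(sf_depth), cf_depth = as.integer(cf_depth),
    outgroup = ancestral, annotation = annotation, evalue = evalue,
    stringsAsFactors = FALSE
  )
  true_class <- cls
  true_class[fail_rule != ""] <- NA_integer_
  attr(out, "true_class") <- true_class
  attr(out, "fail_rule") <- fail_rule
  out
}

#' Simulator-generated observed statistics with known truth
#'
#' Runs the forward simulation to a known divergence age and returns the
#' summary statistics of its final checkpoint together with the generating
#' parameters, enabling parameter-recovery tests of [fit_divergence_age()].
#'
#' @param params A [demographic_params()] object.
#' @param true_age Divergence age in years (a multiple of
#'   `params$checkpoint_years`).
#' @param seed Optional integer seed.
#' @return List with `observed` (a `"class_summary"` object from the final
#'   checkpoint) and `truth` (list of `params`, `true_age`, `seed`).
#' @export
make_truth_observed <- function(params, true_age, seed = NULL) {
  stopifnot(inherits(params, "demographic_params"), true_age >= 1)
  if (true_age %% params$checkpoint_years != 0)
    stop("true_age must be a multiple of the checkpoint interval")
  params$max_years <- true_age
  params <- do.call(demographic_params, unclass(params))
  traj <- wf_run_split(params, seed = seed)
  list(observed = traj$final_summary,
       truth = list(params = params, true_age = true_age, seed = seed))
}

#' Generate a quartet alignment with known topology
#'
#' Builds a four-taxon alignment whose parsimony-informative sites all
#' support one requested topology, with no homoplasy. Uninformative columns
#' are constant or singleton (one taxon differing), neither of which carries
#' topological signal.
#'
#' @param topology The supported split: 1, 2 or 3, or one of `"12|34"`,
#'   `"13|24"`, `"14|23"` (taxon indices refer to the order of `ids`).
#' @param n_informative,n_uninformative Numbers of columns of each type.
#' @param ids Taxon names (default `t1`..`t4`).
#' @param seed Optional integer seed.
#' @return A [quartet_alignment()] object (columns are shuffled).
#' @examples
#' topology_support(make_quartet("12|34", 5, 20, seed = 1))$counts
#' @export
make_quartet <- function(topology, n_informative, n_uninformative,
                         ids = paste0("t", 1:4), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(topology))
    topology <- match(topology, c("12|34", "13|24", "14|23"))
  stopifnot(length(topology) == 1L, topology %in% 1:3,
            n_informative >= 0, n_uninformative >= 0, length(ids) == 4L)
  partner <- topology + 1L  # taxon sharing taxon 1's state
  L <- n_informative + n_uninformative
  mat <- matrix("", nrow = 4L, ncol = L, dimnames = list(ids, NULL))
  for (j in seq_len(L)) {
    base <- sample(.NUC, 1L)
    col <- rep(base, 4L)
    if (j <= n_informative) {
      alt <- sample(setdiff(.NUC, base), 1L)
      col[setdiff(2:4, partner)] <- alt
    } else if (stats::runif(1) < 0.3) {
      tx <- sample.int(4L, 1L)
      col[tx] <- sample(setdiff(.NUC, base), 1L)
    }
    mat[, j] <- col
  }
  if (L > 1L) mat <- mat[, sample.int(L), drop = FALSE]
  quartet_alignment(apply(mat, 1, paste, collapse = ""), gene = "synthetic")
}
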