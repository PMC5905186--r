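test_that("outgroup polarization identifies ancestral and derived alleles", {
  res <- polarize(c("A", "A", "A", "G"), c("G", "G", "G", "T"),
                  c("A", "C", "polymorphic", "T"))
  expect_equal(res$ancestral, c("A", NA, NA, "T"))
  expect_equal(res$derived, c("G", NA, NA, "G"))
  expect_error(polarize("A", "X", "A"), "alleles")
  expect_error(polarize("A", "A", "A"), "distinct")
  expect_error(polarize("A", "G", "Q"), "outgroup")
})

test_that("classify_site reproduces the eight joint polymorphism patterns", {
  f <- function(p) c(A = 1 - p, G = p)  # derived = G, ancestral = A
  expect_equal(classify_site(f(0), f(1), "A"), 1L)
  expect_equal(classify_site(f(1), f(0), "A"), 2L)
  expect_equal(classify_site(f(0), f(0.4), "A"), 3L)
  expect_equal(classify_site(f(1), f(0.4), "A"), 4L)
  expect_equal(classify_site(f(0.4), f(0), "A"), 5L)
  expect_equal(classify_site(f(0.4), f(1), "A"), 6L)
  expect_equal(classify_site(f(0.4), f(0.6), "A"), 7L)
  # both populations fixed for the same allele: not a SNP
  expect_true(is.na(classify_site(f(0), f(0), "A")))
  expect_true(is.na(classify_site(f(1), f(1), "A")))
  # divergent polymorphism: different allele pairs, three alleles overall
  expect_equal(classify_site(c(A = 0.6, T = 0.4, G = 0),
                             c(A = 0.6, T = 0, G = 0.4), "A"), 8L)
  # more than two alleles above threshold within one population: discarded
  expect_true(is.na(classify_site(c(A = 0.4, T = 0.3, G = 0.3),
                                  c(A = 1, T = 0, G = 0), "A")))
  # sub-threshold minor allele counts as fixed
  expect_equal(classify_site(f(0.04), f(1), "A"), 1L)
})

test_that("classification is symmetric under population exchange", {
  perm <- c(2L, 1L, 5L, 6L, 3L, 4L, 7L, 8L)  # class map under SF<->CF swap
  set.seed(11)
  for (i in 1:200) {
    anc <- sample(c("A", "C", "G", "T"), 1)
    der <- sample(setdiff(c("A", "C", "G", "T"), anc), 2)
    mk <- function() {
      p <- sample(c(0, 1, runif(1, 0.06, 0.94)), 1)
      q <- if (runif(1) < 0.15) runif(1, 0.06, 0.5) * (p < 1) else 0
      v <- c(1 - p - q, p, q)
      names(v) <- c(anc, der)
      v
    }
    sf <- mk(); cf <- mk()
    a <- classify_site(sf, cf, anc)
    b <- classify_site(cf, sf, anc)
    if (is.na(a)) expect_true(is.na(b)) else expect_identical(b, perm[a])
  }
})

test_that("site tables classify to their constructed classes and tally adds up", {
  tab <- make_site_table(n_sites = c(synonymous = 300, non_coding = 100),
                         seed = 7)
  cls <- classify_sites(tab)
  expect_identical(cls$class, attr(tab, "true_class"))
  tally <- class_tally(cls)
  expect_identical(sort(colnames(tally)), c("non_coding", "synonymous"))
  expect_identical(sum(tally), sum(!is.na(cls$class)))
  # summary computed from class sums agrees with a direct recount of sites
  s <- class_summary(tally, "synonymous")
  syn <- cls[cls$annotation == "synonymous" & !is.na(cls$class), ]
  maf <- function(c1, c2) pmin(c1, c2) / (c1 + c2)
  sf_poly <- maf(syn$sf_count1, syn$sf_count2) > 0.05
  cf_poly <- maf(syn$cf_count1, syn$cf_count2) > 0.05
  expect_equal(s$poly_sf, sum(sf_poly))
  expect_equal(s$poly_cf, sum(cf_poly))
  der1 <- ifelse(syn$allele1 == syn$derived, syn$sf_count1, syn$sf_count2)
  sf_fixed_der <- !sf_poly & der1 / syn$sf_depth > 0.5
  expect_equal(s$fixed_derived_sf, sum(sf_fixed_der))
})

test_that("summary statistics reproduce the published worked example", {
  s <- class_summary(observed_snp_classes()[, "synonymous"])
  expect_equal(s$poly_sf, 2788)
  expect_equal(s$poly_cf, 904)
  expect_equal(round(s$ratio_sf_cf, 2), 3.08)
  expect_equal(s$fixed_derived_cf, 933)
  expect_equal(s$fixed_derived_sf, 399)
  expect_equal(round(s$ratio_cf_sf, 2), 2.34)
  expect_equal(sum(s$class_freqs), 1, tolerance = 1e-9)
})

test_that("equal class counts give unit ratios; empty tallies are signalled", {
  s <- class_summary(rep(5, 8))
  expect_equal(s$ratio_sf_cf, 1)
  expect_equal(s$ratio_cf_sf, 1)
  expect_warning(s0 <- class_summary(rep(0, 8)), "undefined")
  expect_true(is.na(s0$ratio_sf_cf))
  expect_true(all(is.na(s0$class_freqs)))
})

test_that("site tables round-trip through TSV with identical tallies", {
  tab <- make_site_table(n_sites = 150, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_sites(tab, path)
  back <- read_sites(path)
  t1 <- class_tally(classify_sites(tab))
  t2 <- class_tally(classify_sites(back))
  expect_identical(unclass(t1), unclass(t2))
})
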