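test_that("each filter rule discards exactly its constructed violation", {
  thr <- filter_thresholds()
  base <- rbind(
    site_row(pos = 1000L, sf_count1 = 0L, sf_count2 = 400L,
             cf_count1 = 400L, cf_count2 = 0L),        # clean class 1/2 site
    site_row(pos = 2000L, sf_count1 = 60L, sf_count2 = 340L,
             cf_count1 = 400L, cf_count2 = 0L))        # clean polymorphic SF

  # depth just below the threshold in one population
  shallow <- site_row(pos = 3000L, sf_count1 = 0L, sf_count2 = 99L,
                      cf_count1 = 400L, cf_count2 = 0L)
  res <- apply_filters(rbind(base, shallow), thr)
  expect_equal(unname(res$counts), c(1L, 0L, 0L, 0L))
  expect_equal(res$discarded$discard_rule, "depth")
  expect_equal(nrow(res$retained), 2L)
  # depth exactly at the threshold is kept (>= 100)
  at100 <- site_row(pos = 3000L, sf_count1 = 0L, sf_count2 = 100L,
                    cf_count1 = 400L, cf_count2 = 0L)
  expect_equal(nrow(apply_filters(rbind(base, at100), thr)$retained), 3L)

  # e-value at the threshold fails (strict <)
  bad_e <- site_row(pos = 3000L, evalue = 1e-5)
  res <- apply_filters(rbind(base, bad_e), thr)
  expect_equal(unname(res$counts), c(0L, 1L, 0L, 0L))
  expect_equal(res$discarded$discard_rule, "evalue")

  # two SNPs 30 bp apart: both discarded by spacing
  pair <- rbind(site_row(pos = 3000L), site_row(pos = 3030L))
  res <- apply_filters(rbind(base, pair), thr)
  expect_equal(unname(res$counts), c(0L, 0L, 2L, 0L))
  expect_true(all(res$discarded$pos %in% c(3000L, 3030L)))
  # exactly 51 bp apart passes (strict > 50)
  pair51 <- rbind(site_row(pos = 3000L), site_row(pos = 3051L))
  expect_equal(nrow(apply_filters(rbind(base, pair51), thr)$retained), 4L)

  # MAF 0.04 in the only polymorphic population: no SNP left
  low_maf <- site_row(pos = 3000L, sf_count1 = 16L, sf_count2 = 384L,
                      cf_count1 = 0L, cf_count2 = 400L)
  res <- apply_filters(rbind(base, low_maf), thr)
  expect_equal(unname(res$counts), c(0L, 0L, 0L, 1L))
  expect_equal(res$discarded$discard_rule, "maf")
})

test_that("sub-threshold MAF still leaves between-population SNPs", {
  # SF has MAF 0.04 (called fixed for G), CF fixed for A: still a class-1/2 SNP
  site <- site_row(sf_count1 = 16L, sf_count2 = 384L,
                   cf_count1 = 400L, cf_count2 = 0L)
  res <- apply_filters(site, filter_thresholds())
  expect_equal(nrow(res$retained), 1L)
})

test_that("a site failing several rules is attributed to the first rule", {
  site <- site_row(sf_count1 = 0L, sf_count2 = 50L, evalue = 1)
  res <- apply_filters(site, filter_thresholds())
  expect_equal(res$discarded$discard_rule, "depth")
})

test_that("spacing is evaluated among sites passing depth and e-value", {
  # the shallow neighbour does not count against the good site's isolation
  good <- site_row(pos = 1000L)
  shallow_neighbor <- site_row(pos = 1020L, sf_count1 = 0L, sf_count2 = 50L)
  res <- apply_filters(rbind(good, shallow_neighbor), filter_thresholds())
  expect_equal(unname(res$counts), c(1L, 0L, 0L, 0L))
  expect_equal(res$retained$pos, 1000L)
})

test_that("filtering is idempotent", {
  tab <- make_site_table(n_sites = 400,
                         frac_fail = c(depth = 0.05, evalue = 0.05,
                                       spacing = 0.06, maf = 0.05),
                         seed = 19)
  thr <- filter_thresholds()
  first <- apply_filters(tab, thr)
  second <- apply_filters(first$retained, thr)
  expect_identical(second$retained, first$retained)
  expect_equal(sum(second$counts), 0L)
})

test_that("injected violations are discarded by exactly the intended rule", {
  frac <- c(depth = 0.08, evalue = 0.06, spacing = 0.06, maf = 0.05)
  tab <- make_site_table(n_sites = 500, frac_fail = frac, seed = 23)
  res <- apply_filters(tab, filter_thresholds())
  rule <- attr(tab, "fail_rule")
  kept_key <- paste(res$retained$contig, res$retained$pos)
  all_key <- paste(tab$contig, tab$pos)
  expect_setequal(kept_key, all_key[rule == ""])
  disc_key <- paste(res$discarded$contig, res$discarded$pos)
  expect_identical(res$discarded$discard_rule,
                   rule[match(disc_key, all_key)])
})
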