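# shared fixtures for the test suite

# one site-table row with sensible defaults; override any field
site_row <- function(contig = "c1", pos = 1000L, allele1 = "A", allele2 = "G",
                     sf_count1 = 400L, sf_count2 = 0L,
                     cf_count1 = 0L, cf_count2 = 400L,
                     sf_depth = NULL, cf_depth = NULL,
                     outgroup = "A", annotation = "synonymous",
                     evalue = 1e-20) {
  if (is.null(sf_depth)) sf_depth <- sf_count1 + sf_count2
  if (is.null(cf_depth)) cf_depth <- cf_count1 + cf_count2
  data.frame(contig = contig, pos = pos, allele1 = allele1,
             allele2 = allele2, sf_count1 = sf_count1, sf_count2 = sf_count2,
             cf_count1 = cf_count1, cf_count2 = cf_count2,
             sf_depth = sf_depth, cf_depth = cf_depth, outgroup = outgroup,
             annotation = annotation, evalue = evalue,
             stringsAsFactors = FALSE)
}

# reduced-scale demographic configuration used throughout the properties
small_params <- function(...) {
  args <- list(n_anc = 1000, n_sf = 1000, n_cf = 125, max_years = 3000)
  over <- list(...)
  args[names(over)] <- over
  do.call(demographic_params, args)
}

# iterate pure drift (u = 0) to absorption; returns fixation flag and time
drift_to_absorption <- function(p0, N, n_loci, max_gens = 10000) {
  f <- rep(p0, n_loci)
  t_fix <- rep(NA_real_, n_loci)
  alive <- rep(TRUE, n_loci)
  for (g in seq_len(max_gens)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    f[idx] <- rbinom(length(idx), 2 * N, f[idx]) / (2 * N)
    hit1 <- alive & f == 1
    t_fix[hit1] <- g
    alive <- alive & f > 0 & f < 1
  }
  list(fixed = !is.na(t_fix), t_fix = t_fix, remaining = sum(alive))
}
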