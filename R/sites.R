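#' Observed joint SNP classification of surface vs Pachon cave populations
#'
#' Published classification of biallelic SNPs from pooled RNA-seq of an
#' *Astyanax mexicanus* Texas surface population and the Pachon cave
#' population, polarized with *Hyphessobrycon anisitsi* as outgroup and
#' filtered at depth >= 100, MAF > 5\%, contig e-value < 1e-5 and > 50 bp
#' isolation. Rows are the eight joint polymorphism classes (see
#' [classify_site()]), columns the annotation categories.
#'
#' The non-synonymous class-2 count is 211, the value implied by the
#' published marginal totals (polymorphism and fixed-derived sums and the
#' category total of 2110).
#'
#' @return Integer matrix with 8 rows (`class1`..`class8`) and columns
#'   `synonymous`, `non_coding`, `non_synonymous`.
#' @examples
#' observed_snp_classes()[, "synonymous"]
#' @export
observed_snp_classes <- function() {
  m <- cbind(
    synonymous     = c(540L, 280L, 476L, 119L, 2086L, 393L, 309L, 1L),
    non_coding     = c(157L, 111L, 146L,  57L,  601L,  87L,  80L, 0L),
    non_synonymous = c(301L, 211L, 302L,  91L,  923L, 159L, 123L, 0L)
  )
  rownames(m) <- paste0("class", 1:8)
  m
}

.NUC <- c("A", "C", "G", "T")

#' Polarize biallelic sites with an outgroup allele
#'
#' Infers the ancestral and derived allele of each biallelic site from the
#' allele observed in the outgroup: if the outgroup carries exactly one of the
#' two site alleles, that allele is ancestral and the other derived. Sites
#' whose outgroup state is unknown, polymorphic, or matches neither allele
#' cannot be polarized and are flagged as discarded (`NA` alleles).
#'
#' @param allele1,allele2 Character vectors of nucleotides (`A`, `C`, `G`,
#'   `T`); recycled to a common length.
#' @param outgroup Character vector: a nucleotide, or one of `"unknown"`,
#'   `"polymorphic"`, `"other"` for sites without a usable outgroup state.
#' @return A data frame with columns `ancestral` and `derived` (`NA` where the
#'   site is discarded).
#' @examples
#' polarize(c("A", "A", "A"), c("G", "G", "G"), c("A", "C", "polymorphic"))
#' @export
polarize <- function(allele1, allele2, outgroup) {
  n <- max(length(allele1), length(allele2), length(outgroup))
  allele1 <- toupper(rep_len(as.character(allele1), n))
  allele2 <- toupper(rep_len(as.character(allele2), n))
  outgroup <- rep_len(as.character(outgroup), n)
  og_up <- toupper(outgroup)
  special <- tolower(outgroup) %in% c("unknown", "polymorphic", "other", "n", ".", "na", "")
  if (!all(allele1 %in% .NUC) || !all(allele2 %in% .NUC))
    stop("site alleles must be one of A, C, G, T")
  if (!all(special | og_up %in% .NUC))
    stop("outgroup must be a nucleotide or one of 'unknown', 'polymorphic', 'other'")
  if (any(allele1 == allele2))
    stop("the two site alleles must be distinct")
  anc <- ifelse(!special & og_up == allele1, allele1,
         ifelse(!special & og_up == allele2, allele2, NA_character_))
  der <- ifelse(is.na(anc), NA_character_,
         ifelse(anc == allele1, allele2, allele1))
  data.frame(ancestral = anc, derived = der, stringsAsFactors = FALSE)
}

# Population state at one site from per-allele frequencies: fixed for the
# major allele when the minor allele frequency is <= maf_min, polymorphic
# when two alleles exceed maf_min, NULL (unclassifiable) when more than two do.
.pop_state <- function(freqs, maf_min) {
  present <- names(freqs)[freqs > maf_min]
  if (length(present) > 2L) return(NULL)
  if (length(present) == 0L) present <- names(freqs)[which.max(freqs)]
  list(polymorphic = length(present) == 2L, alleles = present)
}

#' Classify one site into the eight joint polymorphism classes
#'
#' Given per-allele frequencies in the surface (SF) and cave (CF) populations
#' and the ancestral allele, assigns one of eight classes describing the joint
#' polymorphism pattern. A population is polymorphic iff its minor allele
#' frequency exceeds `maf_min`, otherwise it is treated as fixed for its major
#' allele:
#'
#' \describe{
#'   \item{1}{different fixed alleles, derived allele fixed in CF}
#'   \item{2}{different fixed alleles, derived allele fixed in SF}
#'   \item{3}{polymorphism in CF, ancestral allele fixed in SF}
#'   \item{4}{polymorphism in CF, derived allele fixed in SF}
#'   \item{5}{polymorphism in SF, ancestral allele fixed in CF}
#'   \item{6}{polymorphism in SF, derived allele fixed in CF}
#'   \item{7}{shared polymorphism (same allele pair in both)}
#'   \item{8}{divergent polymorphism (different allele pairs)}
#' }
#'
#' Returns `NA` (discarded) when both populations are fixed for the same
#' allele (no SNP), when both are fixed for different alleles neither of which
#' is ancestral, or when more than two alleles exceed `maf_min` within one
#' population.
#'
#' @param sf_freqs,cf_freqs Named numeric vectors of allele frequencies
#'   (names are nucleotides; each vector sums to 1).
#' @param ancestral Single nucleotide: the ancestral allele.
#' @param maf_min Minor allele frequency above which a population is called
#'   polymorphic (default 0.05, strict `>`).
#' @return Integer class 1--8, or `NA` for a discarded site.
#' @examples
#' classify_site(c(A = 1, G = 0), c(A = 0, G = 1), "A")          # class 1
#' classify_site(c(A = 0.6, G = 0.4), c(A = 0.7, G = 0.3), "A")  # class 7
#' @export
classify_site <- function(sf_freqs, cf_freqs, ancestral, maf_min = 0.05) {
  stopifnot(is.numeric(sf_freqs), is.numeric(cf_freqs),
            !is.null(names(sf_freqs)), !is.null(names(cf_freqs)),
            length(ancestral) == 1L)
  sf <- .pop_state(sf_freqs, maf_min)
  cf <- .pop_state(cf_freqs, maf_min)
  if (is.null(sf) || is.null(cf)) return(NA_integer_)
  if (!sf$polymorphic && !cf$polymorphic) {
    if (sf$alleles == cf$alleles) return(NA_integer_)
    if (sf$alleles == ancestral) return(1L)
    if (cf$alleles == ancestral) return(2L)
    return(NA_integer_)
  }
  if (cf$polymorphic && !sf$polymorphic)
    return(if (sf$alleles == ancestral) 3L else 4L)
  if (sf$polymorphic && !cf$polymorphic)
    return(if (cf$alleles == ancestral) 5L else 6L)
  if (setequal(sf$alleles, cf$alleles)) 7L else 8L
}

#' Polarize and classify a site table
#'
#' Applies [polarize()] and [classify_site()] to every row of a site table
#' (see [read_sites()] for the column layout). Per-population allele
#' frequencies are taken from the pooled allele counts.
#'
#' @param sites A site-table data frame.
#' @param maf_min Polymorphism-calling minor allele frequency threshold.
#' @return `sites` with added columns `ancestral`, `derived` and `class`
#'   (integer 1--8, `NA` for discarded sites).
#' @export
classify_sites <- function(sites, maf_min = 0.05) {
  .check_sites(sites)
  pol <- polarize(sites$allele1, sites$allele2, sites$outgroup)
  sites$ancestral <- pol$ancestral
  sites$derived <- pol$derived
  n <- nrow(sites)
  cls <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(sites$ancestral[i])) next
    sf_tot <- sites$sf_count1[i] + sites$sf_count2[i]
    cf_tot <- sites$cf_count1[i] + sites$cf_count2[i]
    if (sf_tot <= 0 || cf_tot <= 0) next
    al <- c(sites$allele1[i], sites$allele2[i])
    sf <- c(sites$sf_count1[i], sites$sf_count2[i]) / sf_tot
    cf <- c(sites$cf_count1[i], sites$cf_count2[i]) / cf_tot
    names(sf) <- names(cf) <- al
    cls[i] <- classify_site(sf, cf, sites$ancestral[i], maf_min)
  }
  sites$class <- cls
  sites
}

#' Filter thresholds for SNP selection
#'
#' Bundles the four site-selection thresholds: minimum pooled read depth per
#' population (inclusive `>=`), polymorphism-calling minor allele frequency
#' (strict `>`), maximum contig annotation e-value (strict `<`), and minimum
#' distance to the nearest other SNP on each side (strict `>`).
#'
#' @param min_depth Minimum read depth per population (default 100).
#' @param maf_min MAF threshold (default 0.05).
#' @param max_evalue Contig e-value ceiling (default 1e-5).
#' @param min_isolation_bp Minimum SNP isolation in bp (default 50).
#' @return An object of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_depth = 100, maf_min = 0.05,
                              max_evalue = 1e-5, min_isolation_bp = 50) {
  stopifnot(min_depth >= 0, maf_min >= 0, maf_min < 0.5,
            max_evalue >= 0, min_isolation_bp >= 0)
  structure(list(min_depth = min_depth, maf_min = maf_min,
                 max_evalue = max_evalue,
                 min_isolation_bp = min_isolation_bp),
            class = "filter_thresholds")
}

#' Apply depth, e-value, spacing and MAF filters to a site table
#'
#' Sites are retained iff (in this order of attribution) both pooled depths
#' are at least `min_depth`; the contig e-value is strictly below
#' `max_evalue`; no other SNP lies within `min_isolation_bp` on either side
#' (distances computed per contig among the sites passing the depth and
#' e-value rules); and the site is still a SNP once sub-threshold minor
#' alleles are treated as absent, i.e. the two populations are not both fixed
#' for the same allele at MAF threshold `maf_min`. A site failing several
#' rules is counted against the first failing rule in the order depth,
#' e-value, spacing, MAF.
#'
#' @param sites A site-table data frame (see [read_sites()]).
#' @param thr A [filter_thresholds()] object.
#' @return A list with elements `retained` (data frame), `discarded` (data
#'   frame with a `discard_rule` column) and `counts` (named integer vector of
#'   per-rule discard counts in the order depth, evalue, spacing, maf).
#' @examples
#' tab <- make_site_table(n_sites = 50, frac_fail = c(depth = 0.1), seed = 1)
#' apply_filters(tab, filter_thresholds())$counts
#' @export
apply_filters <- function(sites, thr = filter_thresholds()) {
  .check_sites(sites)
  stopifnot(inherits(thr, "filter_thresholds"))
  n <- nrow(sites)
  rule <- rep(NA_character_, n)

  fail_depth <- sites$sf_depth < thr$min_depth | sites$cf_depth < thr$min_depth
  fail_eval <- !(sites$evalue < thr$max_evalue)

  # spacing: among sites passing depth and e-value, within each contig
  cand <- which(!fail_depth & !fail_eval)
  fail_space <- rep(FALSE, n)
  if (length(cand) > 1L) {
    for (ctg in unique(sites$contig[cand])) {
      idx <- cand[sites$contig[cand] == ctg]
      if (length(idx) < 2L) next
      ord <- idx[order(sites$pos[idx])]
      gaps <- diff(sites$pos[ord])
      close_left <- c(FALSE, gaps <= thr$min_isolation_bp)
      close_right <- c(gaps <= thr$min_isolation_bp, FALSE)
      fail_space[ord] <- close_left | close_right
    }
  }

  # MAF: no SNP left once sub-threshold minor alleles are called fixed
  sf_tot <- sites$sf_count1 + sites$sf_count2
  cf_tot <- sites$cf_count1 + sites$cf_count2
  sf_maf <- pmin(sites$sf_count1, sites$sf_count2) / sf_tot
  cf_maf <- pmin(sites$cf_count1, sites$cf_count2) / cf_tot
  sf_poly <- sf_maf > thr$maf_min
  cf_poly <- cf_maf > thr$maf_min
  sf_major <- ifelse(sites$sf_count1 >= sites$sf_count2, sites$allele1, sites$allele2)
  cf_major <- ifelse(sites$cf_count1 >= sites$cf_count2, sites$allele1, sites$allele2)
  fail_maf <- !sf_poly & !cf_poly & sf_major == cf_major
  fail_maf[is.na(fail_maf)] <- FALSE

  rule[fail_maf] <- "maf"
  rule[fail_space] <- "spacing"
  rule[fail_eval] <- "evalue"
  rule[fail_depth] <- "depth"

  keep <- is.na(rule)
  discarded <- sites[!keep, , drop = FALSE]
  discarded$discard_rule <- rule[!keep]
  counts <- vapply(c("depth", "evalue", "spacing", "maf"),
                   function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(retained = sites[keep, , drop = FALSE],
       discarded = discarded,
       counts = counts)
}

#' Tally classified sites per class and annotation category
#'
#' @param sites A site table with `class` and `annotation` columns, as
#'   returned by [classify_sites()]. Sites with `NA` class are ignored.
#' @return An object of class `"class_tally"`: an 8 x categories integer
#'   matrix of site counts with a `totals` attribute.
#' @export
class_tally <- function(sites) {
  stopifnot(is.data.frame(sites), "class" %in% names(sites),
            "annotation" %in% names(sites))
  ok <- !is.na(sites$class)
  cats <- unique(sites$annotation[ok])
  if (length(cats) == 0L) cats <- "synonymous"
  m <- vapply(cats, function(ct)
    tabulate(sites$class[ok & sites$annotation == ct], nbins = 8L),
    integer(8))
  m <- matrix(as.integer(m), nrow = 8L,
              dimnames = list(paste0("class", 1:8), cats))
  structure(m, totals = colSums(m), class = c("class_tally", "matrix", "array"))
}

#' @export
print.class_tally <- function(x, ...) {
  cat("Joint SNP class tally\n")
  m <- unclass(x)
  attr(m, "totals") <- NULL
  print(rbind(m, total = colSums(m)))
  invisible(x)
}

#' Write a class tally as a TSV of counts and percentages
#'
#' @param tally A [class_tally()] object or an 8-row count matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tally <- function(tally, path) {
  m <- unclass(tally)
  attr(m, "totals") <- NULL
  tot <- colSums(m)
  pct <- sweep(m, 2, pmax(tot, 1L), "/") * 100
  out <- data.frame(class = rownames(m), m, check.names = FALSE)
  for (j in colnames(m)) out[[paste0(j, "_pct")]] <- round(pct[, j], 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared constructor for the summary statistics derived from 8-class counts
.summary_from_counts <- function(counts) {
  stopifnot(length(counts) == 8L, all(counts >= 0))
  counts <- as.numeric(counts)
  total <- sum(counts)
  poly_sf <- counts[5] + counts[6] + counts[7]
  poly_cf <- counts[3] + counts[4] + counts[7]
  fds <- counts[2] + counts[4]
  fdc <- counts[1] + counts[6]
  tot7 <- sum(counts[1:7])
  freqs <- if (tot7 > 0) counts[1:7] / tot7 else rep(NA_real_, 7)
  names(freqs) <- paste0("class", 1:7)
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  if (total == 0)
    warning("empty tally: summary ratios are undefined", call. = FALSE)
  structure(list(
    counts = stats::setNames(counts, paste0("class", 1:8)),
    total = total,
    class_freqs = freqs,
    poly_sf = poly_sf, poly_cf = poly_cf,
    ratio_sf_cf = ratio(poly_sf, poly_cf),
    fixed_derived_sf = fds, fixed_derived_cf = fdc,
    ratio_cf_sf = ratio(fdc, fds)
  ), class = "class_summary")
}

#' Summary statistics of a class tally
#'
#' Derives, for one annotation category, the summary statistics used for
#' divergence dating: relative class frequencies over classes 1--7 (the
#' divergent-polymorphism class 8 is excluded from the frequency vector), the
#' polymorphism counts per population (SF: classes 5+6+7; CF: classes 3+4+7)
#' and their ratio, and the fixed-derived counts (SF: 2+4; CF: 1+6) and their
#' ratio. Ratios are reported rounded to two decimals by the print method but
#' stored at full precision.
#'
#' @param tally A [class_tally()] object, or a bare numeric vector of 8 class
#'   counts.
#' @param category Column of the tally to summarize (defaults to the first).
#' @return An object of class `"class_summary"`.
#' @examples
#' s <- class_summary(observed_snp_classes()[, "synonymous"])
#' round(s$ratio_sf_cf, 2)  # 3.08
#' @export
class_summary <- function(tally, category = NULL) {
  if (is.numeric(tally) && is.null(dim(tally))) {
    counts <- tally
  } else {
    m <- unclass(tally)
    attr(m, "totals") <- NULL
    if (is.null(category)) category <- colnames(m)[1]
    stopifnot(category %in% colnames(m))
    counts <- m[, category]
  }
  .summary_from_counts(counts)
}

#' @export
print.class_summary <- function(x, digits = 2, ...) {
  cat("SNP class summary (", format(x$total), " sites)\n", sep = "")
  cat("  class frequencies (1-7):",
      paste(sprintf("%.3f", x$class_freqs), collapse = " "), "\n")
  cat("  polymorphism SF:", x$poly_sf, " CF:", x$poly_cf,
      " ratio SF/CF:", round(x$ratio_sf_cf, digits), "\n")
  cat("  fixed derived SF:", x$fixed_derived_sf, " CF:", x$fixed_derived_cf,
      " ratio CF/SF:", round(x$ratio_cf_sf, digits), "\n")
  invisible(x)
}

.SITE_COLS <- c("contig", "pos", "allele1", "allele2", "sf_count1",
                "sf_count2", "cf_count1", "cf_count2", "sf_depth",
                "cf_depth", "outgroup", "annotation", "evalue")

.check_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  missing <- setdiff(.SITE_COLS, names(sites))
  if (length(missing))
    stop("site table lacks columns: ", paste(missing, collapse = ", "))
  invisible(sites)
}

#' Read and write SNP site tables
#'
#' Site tables are TSV files with header columns `contig`, `pos`, `allele1`,
#' `allele2`, `sf_count1`, `sf_count2`, `cf_count1`, `cf_count2`, `sf_depth`,
#' `cf_depth`, `outgroup`, `annotation`, `evalue`. Positions are 1-based
#' within contigs; counts are pooled allele counts per population.
#'
#' @param path File path.
#' @return `read_sites()` returns the site table as a data frame;
#'   `write_sites()` returns `path` invisibly.
#' @export
read_sites <- function(path) {
  sites <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_sites(sites)
  sites
}

#' @rdname read_sites
#' @param sites A site-table data frame.
#' @export
write_sites <- function(sites, path) {
  .check_sites(sites)
  utils::write.table(sites[, .SITE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table from a VCF plus an outgroup sidecar
#'
#' Ingests biallelic SNP records from a VCF whose two pool samples carry
#' allelic depths in the `AD` format field, and joins outgroup alleles (and
#' optionally annotation categories and contig e-values) from a TSV sidecar
#' with columns `contig`, `pos`, `outgroup` and optionally `annotation`,
#' `evalue`. Coordinates stay 1-based. Requires the `vcfR` package.
#'
#' @param vcf_path Path to a VCF file.
#' @param outgroup_path Path to the outgroup TSV sidecar.
#' @param sf_sample,cf_sample Names of the surface and cave pool columns.
#' @return A site-table data frame (see [read_sites()]). Multi-allelic or
#'   non-SNP records are dropped; sites absent from the sidecar get outgroup
#'   `"unknown"`.
#' @export
read_sites_vcf <- function(vcf_path, outgroup_path, sf_sample, cf_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_sites_vcf() requires the 'vcfR' package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  stopifnot(all(c(sf_sample, cf_sample) %in% colnames(ad)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .NUC & alt %in% .NUC
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE)
    t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  }
  sf <- split_ad(ad[, sf_sample]); cf <- split_ad(ad[, cf_sample])
  sites <- data.frame(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    allele1 = ref, allele2 = alt,
    sf_count1 = sf[, 1], sf_count2 = sf[, 2],
    cf_count1 = cf[, 1], cf_count2 = cf[, 2],
    sf_depth = sf[, 1] + sf[, 2], cf_depth = cf[, 1] + cf[, 2],
    outgroup = "unknown", annotation = "unannotated", evalue = 0,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  side <- utils::read.delim(outgroup_path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "outgroup") %in% names(side)))
  key <- paste(sites$contig, sites$pos)
  skey <- paste(side$contig, side$pos)
  hit <- match(key, skey)
  ok <- !is.na(hit)
  sites$outgroup[ok] <- side$outgroup[hit[ok]]
  if ("annotation" %in% names(side)) sites$annotation[ok] <- side$annotation[hit[ok]]
  if ("evalue" %in% names(side)) sites$evalue[ok] <- side$evalue[hit[ok]]
  sites
}
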