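#' Four-taxon alignments
#'
#' A quartet alignment holds exactly four aligned nucleotide sequences. It is
#' the input of the parsimony-informative-site incongruence analysis: for
#' four taxa there are three unrooted tree topologies, and every informative
#' site supports exactly one of them.
#'
#' @param seqs Named character vector of four aligned sequences (equal
#'   length; gaps `-` and ambiguity codes are tolerated but excluded from
#'   informative sites).
#' @param gene Gene label (defaults to `"gene"`).
#' @return An object of class `"quartet_alignment"` with fields `ids`, `mat`
#'   (a 4 x L uppercase character matrix) and `gene`.
#' @examples
#' quartet_alignment(c(a = "AAGGA", b = "AAGGA", c = "AGCGA", d = "AGCGA"))
#' @export
quartet_alignment <- function(seqs, gene = "gene") {
  stopifnot(length(seqs) == 4L, is.character(seqs))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("the four sequences must carry distinct names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must be aligned (equal lengths)")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  structure(list(ids = names(seqs), mat = mat, gene = gene),
            class = "quartet_alignment")
}

#' Read a quartet alignment from a FASTA file
#'
#' @param path Path to a FASTA file with exactly four aligned sequences.
#' @param gene Gene label (defaults to the file name without extension).
#' @return A [quartet_alignment()] object.
#' @export
read_quartet <- function(path, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) != 4L)
    stop("expected exactly 4 sequences, found ", length(dna))
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  quartet_alignment(seqs, gene = gene)
}

#' Write a quartet alignment to FASTA
#'
#' @param aln A [quartet_alignment()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quartet <- function(aln, path) {
  stopifnot(inherits(aln, "quartet_alignment"))
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  dna <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  names(dna) <- aln$ids
  ape::write.FASTA(dna, path)
  invisible(path)
}

# canonical label of the split pairing taxon 1 with `partner` (2, 3 or 4)
.partition_label <- function(ids, partner) {
  side1 <- sort(ids[c(1L, partner)])
  side2 <- sort(ids[setdiff(2:4, partner)])
  sides <- sort(c(paste(side1, collapse = ","), paste(side2, collapse = ",")))
  paste(sides, collapse = "|")
}

#' Parsimony-informative sites of a quartet alignment
#'
#' A column is parsimony-informative for four taxa iff it shows exactly two
#' states, each carried by exactly two taxa (an `xxyy`-type pattern); such a
#' column supports exactly one of the three unrooted topologies. Columns with
#' a gap or ambiguity code in any taxon are skipped.
#'
#' @param aln A [quartet_alignment()] object.
#' @return Data frame with columns `position`, `partner` (the taxon index
#'   sharing taxon 1's state: 2, 3 or 4) and `partition` (the supported
#'   split, labelled by taxon ids).
#' @examples
#' a <- quartet_alignment(c(t1 = "AAG", t2 = "AAG", t3 = "AGC", t4 = "AGC"))
#' informative_sites(a)
#' @export
informative_sites <- function(aln) {
  stopifnot(inherits(aln, "quartet_alignment"))
  m <- aln$mat
  n <- ncol(m)
  pos <- integer(0); partner <- integer(0)
  for (j in seq_len(n)) {
    col <- m[, j]
    if (!all(col %in% .NUC)) next
    tab <- table(col)
    if (length(tab) != 2L || any(tab != 2L)) next
    pos <- c(pos, j)
    partner <- c(partner, which(col[2:4] == col[1]) + 1L)
  }
  data.frame(position = pos, partner = partner,
             partition = vapply(partner, function(p)
               .partition_label(aln$ids, p), character(1)),
             stringsAsFactors = FALSE)
}

#' Topology support of a quartet alignment
#'
#' Counts the informative sites supporting each of the three unrooted
#' quartet topologies. The winning topology is the one with the maximum
#' count; ties (including zero informative sites) are reported as
#' unresolved.
#'
#' @param aln A [quartet_alignment()] object.
#' @return Object of class `"topology_support"`: a list with `gene`, `counts`
#'   (named by taxon-id partitions), `winner` (a partition label or
#'   `"unresolved"`) and `sites` (the [informative_sites()] table).
#' @export
topology_support <- function(aln) {
  stopifnot(inherits(aln, "quartet_alignment"))
  sites <- informative_sites(aln)
  labels <- vapply(2:4, function(p) .partition_label(aln$ids, p), character(1))
  counts <- stats::setNames(
    vapply(2:4, function(p) sum(sites$partner == p), integer(1)), labels)
  winner <- if (sum(counts == max(counts)) != 1L || max(counts) == 0L)
    "unresolved" else labels[which.max(counts)]
  structure(list(gene = aln$gene, counts = counts, winner = winner,
                 sites = sites),
            class = "topology_support")
}

#' @export
print.topology_support <- function(x, ...) {
  cat("Quartet topology support for", x$gene, "\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  %-30s %d\n", names(x$counts)[i], x$counts[i]))
  cat("  winner:", x$winner, "\n")
  invisible(x)
}

#' Are two genes' quartet topologies congruent?
#'
#' Two genes are congruent iff their winning topologies coincide (compared as
#' taxon-id partitions, so input order does not matter). If either gene is
#' unresolved the comparison is `NA`.
#'
#' @param a,b `"topology_support"` objects.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
is_congruent <- function(a, b) {
  stopifnot(inherits(a, "topology_support"), inherits(b, "topology_support"))
  if (a$winner == "unresolved" || b$winner == "unresolved") return(NA)
  a$winner == b$winner
}

#' Tabulate winning topologies over a directory of quartet FASTA files
#'
#' @param dir Directory containing per-gene FASTA files (4 sequences each).
#' @param pattern File pattern (default `"\\.fa(sta)?$"`).
#' @return Data frame with one row per gene: `gene`, the three support
#'   counts, `n_informative` and `winner`.
#' @export
quartet_dir_support <- function(dir, pattern = "\\.fa(sta)?$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  rows <- lapply(files, function(f) {
    ts <- topology_support(read_quartet(f))
    data.frame(gene = ts$gene, t(ts$counts),
               n_informative = sum(ts$counts), winner = ts$winner,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
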