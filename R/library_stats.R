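# Library-quality statistics for insertion libraries: normalization,
# ECDF/KS bias comparison, coverage curves, reading-frame/direction and 1-bp
# deletion enrichment, and insertion-context (two-sample logo) matrices.

#' Construct an insertion count table
#'
#' Per-residue insertion read counts for one gene/sample.
#'
#' @param position 1-based residue positions (1..N, complete).
#' @param count Non-negative read counts.
#' @param gene,sample Labels.
#' @return An `insertion_counts` data.frame.
#' @export
insertion_counts <- function(position, count, gene = "gene", sample = "s1") {
  stopifnot(length(position) == length(count), all(count >= 0),
            !anyNA(count))
  out <- data.frame(position = as.integer(position), count = as.integer(count))
  attr(out, "gene") <- gene
  attr(out, "sample") <- sample
  class(out) <- c("insertion_counts", "data.frame")
  out
}

#' Read an insertion count table from TSV
#' @param path TSV with columns `position`, `count`.
#' @param ... Passed to [insertion_counts()].
#' @return An `insertion_counts` table.
#' @export
read_insertion_counts <- function(path, ...) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  insertion_counts(tab$position, tab$count, ...)
}

#' Normalized insertions per residue
#'
#' Each position's read count is divided by the gene's total reads and
#' multiplied by the number of residues, so a perfectly even library has the
#' value one at every position (and any library averages to one).
#'
#' @param table An `insertion_counts` table.
#' @return Numeric vector of per-position normalized values.
#' @export
normalized_insertions_per_residue <- function(table) {
  t_j <- sum(table$count)
  if (t_j <= 0) stop("zero total reads")
  (table$count / t_j) * nrow(table)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value is
#' the asymptotic two-sample approximation (exact enumeration is unnecessary
#' at library scale).
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p_value = res$p.value)
}

#' Library coverage at increasing read-depth thresholds
#'
#' The table is first rescaled by seeded multinomial resampling to
#' `normalize_to` reads per position (as a gene-wide total), then the
#' fraction of positions with at least each threshold's coverage is
#' reported; the curve is non-increasing in the threshold.
#'
#' @param table An `insertion_counts` table.
#' @param thresholds Integer read-depth thresholds.
#' @param normalize_to Target mean reads per position (`NULL` to skip
#'   resampling).
#' @param seed Seed for the multinomial resampling.
#' @return data.frame with `threshold` and `fraction_covered`.
#' @export
coverage_curve <- function(table, thresholds = c(1, 5, 10, 20, 50, 100),
                           normalize_to = 300L, seed = 1L) {
  counts <- table$count
  if (!is.null(normalize_to)) {
    tot <- sum(counts)
    if (tot <= 0) stop("zero total reads")
    target <- as.integer(normalize_to) * nrow(table)
    if (tot != target)   # already on target: resampling is the identity
      counts <- .with_seed(seed,
        as.integer(stats::rmultinom(1L, target, counts / tot)))
  }
  data.frame(threshold = thresholds,
             fraction_covered = vapply(thresholds, function(th)
               mean(counts >= th), numeric(1)))
}

.six_classes <- function() {
  data.frame(frame = rep(c(0L, 1L, 2L), each = 2L),
             direction = rep(c("+", "-"), 3L), stringsAsFactors = FALSE)
}

#' Per-class frequencies of an insertion call table
#'
#' Calls are partitioned into six classes by reading frame (0/+1/+2) and
#' direction (+/-); frequencies are read counts per class over total reads.
#' Duplicated calls (same position, frame and direction reported twice) are
#' collapsed before normalization.
#'
#' @param calls data.frame with `position`, `frame`, `direction`, `count`.
#' @return data.frame with `frame`, `direction`, `count`, `frequency`
#'   (summing to one).
#' @export
frame_direction_frequencies <- function(calls) {
  stopifnot(all(c("frame", "direction", "count") %in% names(calls)))
  if (all(c("position") %in% names(calls))) {
    dup <- duplicated(calls[, c("position", "frame", "direction")])
    calls <- calls[!dup, , drop = FALSE]
  }
  cls <- .six_classes()
  cls$count <- mapply(function(f, d)
    sum(calls$count[calls$frame == f & calls$direction == d]),
    cls$frame, cls$direction)
  tot <- sum(cls$count)
  if (tot <= 0) stop("no calls")
  cls$frequency <- cls$count / tot
  cls
}

#' Frame/direction enrichment of a sorted sample versus its control
#'
#' Each of the six class frequencies in the sorted dataset is divided by the
#' corresponding control frequency. Classes with zero control frequency give
#' `NA` (reported as missing, never infinity).
#'
#' @param sorted,control Call tables (see [frame_direction_frequencies()]).
#' @return data.frame with class columns, `freq_sorted`, `freq_control`,
#'   `enrichment`.
#' @export
frame_direction_enrichment <- function(sorted, control) {
  fs <- frame_direction_frequencies(sorted)
  fc <- frame_direction_frequencies(control)
  out <- fs[, c("frame", "direction")]
  out$freq_sorted <- fs$frequency
  out$freq_control <- fc$frequency
  out$enrichment <- ifelse(fc$frequency > 0,
                           fs$frequency / fc$frequency, NA_real_)
  out
}

# minimal plain-text SAM reader: flag + CIGAR of mapped records
.read_sam_cigars <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(data.frame(flag = integer(), cigar = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(flag = as.integer(vapply(parts, `[[`, character(1), 2L)),
             cigar = vapply(parts, `[[`, character(1), 6L),
             stringsAsFactors = FALSE)
}

# does a CIGAR contain at least one deletion op of length exactly 1?
.has_1bp_deletion <- function(cigar) {
  m <- regmatches(cigar, gregexpr("[0-9]+D", cigar))
  vapply(m, function(x) any(x == "1D"), logical(1))
}

#' Single-base-deletion frequency of aligned reads
#'
#' Counts reads whose alignment contains a deletion of exactly one base
#' (from the CIGAR); reads with several such deletions count once. The
#' frequency is that count over all aligned reads.
#'
#' @param x SAM file path, character vector of SAM lines, or a data.frame
#'   with columns `flag` and `cigar`.
#' @return List with `n_reads`, `n_deletion_reads`, `frequency`.
#' @export
deletion_frequency <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    tab <- .read_sam_cigars(x)
  } else if (is.character(x)) {
    tmp <- x[!startsWith(x, "@")]
    parts <- strsplit(tmp, "\t", fixed = TRUE)
    tab <- data.frame(flag = as.integer(vapply(parts, `[[`, character(1), 2L)),
                      cigar = vapply(parts, `[[`, character(1), 6L),
                      stringsAsFactors = FALSE)
  } else tab <- x
  aligned <- tab$cigar != "*" & bitwAnd(tab$flag, 4L) == 0L
  n <- sum(aligned)
  if (n == 0L) stop("no aligned reads")
  nd <- sum(.has_1bp_deletion(tab$cigar[aligned]))
  list(n_reads = n, n_deletion_reads = nd, frequency = nd / n)
}

#' 1-bp deletion enrichment of sorted samples versus control
#'
#' @param sorted,control Inputs accepted by [deletion_frequency()].
#' @return List with `freq_sorted`, `freq_control`, `enrichment`
#'   (`NA` when the control frequency is zero).
#' @export
deletion_enrichment <- function(sorted, control) {
  fs <- deletion_frequency(sorted)
  fc <- deletion_frequency(control)
  list(freq_sorted = fs$frequency, freq_control = fc$frequency,
       enrichment = if (fc$frequency > 0) fs$frequency / fc$frequency
                    else NA_real_)
}

#' Insertion-context nucleotide count matrices (two-sample logo input)
#'
#' Builds a position-by-base count matrix over windows centered at insertion
#' sites (foreground) and over all positions of the gene (background), plus
#' their frequency difference — the input of background-corrected
#' ("two-sample") sequence logos.
#'
#' @param sites 1-based nucleotide positions of insertion sites.
#' @param gene_seq Gene (or context) DNA string.
#' @param k Window half-width in nt (default 5; window is `2k+1` wide,
#'   clipped at the sequence ends).
#' @return List of matrices `foreground`, `background` (4 x 2k+1 counts) and
#'   `difference` (foreground minus background column frequencies).
#' @export
insertion_context_matrices <- function(sites, gene_seq, k = 5L) {
  if (!length(sites)) stop("empty site list")
  L <- nchar(gene_seq)
  stopifnot(all(sites >= 1L), all(sites <= L))
  bases <- c("A", "C", "G", "T")
  offs <- -k:k
  count_mat <- function(centers) {
    m <- matrix(0L, nrow = 4L, ncol = length(offs),
                dimnames = list(bases, as.character(offs)))
    ch <- strsplit(gene_seq, "", fixed = TRUE)[[1]]
    for (ci in seq_along(offs)) {
      pos <- centers + offs[ci]
      ok <- pos >= 1L & pos <= L
      tb <- table(factor(ch[pos[ok]], levels = bases))
      m[, ci] <- as.integer(tb)
    }
    m
  }
  fg <- count_mat(as.integer(sites))
  bg <- count_mat(seq_len(L))
  freq <- function(m) sweep(m, 2L, pmax(colSums(m), 1L), "/")
  list(foreground = fg, background = bg,
       difference = freq(fg) - freq(bg))
}

#' Export logo matrices as TSV
#' @param mats List from [insertion_context_matrices()].
#' @param path Output file (the difference matrix).
#' @return `path`, invisibly.
#' @export
write_context_matrices <- function(mats, path) {
  utils::write.table(mats$difference, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Replicate agreement of z-scored insertion profiles
#'
#' Spearman rank correlation of z-scored normalized insertions per residue
#' between replicates; with `na_as_zero`, positions missing (NA) in a
#' replicate are set to zero rather than dropped (dropping would discard
#' most of the data when coverage is sparse). For more than two replicates
#' the mean of all pairwise coefficients is returned.
#'
#' @param tables List of `insertion_counts` tables over the same gene.
#' @param na_as_zero Replace NA values by zero.
#' @return Spearman correlation coefficient (NA when undefined).
#' @export
replicate_spearman <- function(tables, na_as_zero = TRUE) {
  stopifnot(length(tables) >= 2L)
  ns <- vapply(tables, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("replicates differ in length")
  zs <- lapply(tables, function(tb) {
    v <- normalized_insertions_per_residue(tb)
    if (na_as_zero) v[is.na(v)] <- 0
    if (stats::sd(v) == 0) return(NULL)
    (v - mean(v)) / stats::sd(v)
  })
  if (any(vapply(zs, is.null, logical(1)))) return(NA_real_)
  pairs <- utils::combn(length(zs), 2L)
  mean(apply(pairs, 2L, function(ij)
    stats::cor(zs[[ij[1]]], zs[[ij[2]]], method = "spearman")))
}

#' Recompute percentage columns of a clone-error tally
#'
#' Given per-category clone counts and the number of clones sequenced,
#' returns percentages rounded to one decimal (the convention of published
#' error-rate tables).
#'
#' @param counts Named integer vector of category counts.
#' @param n_total Number of clones sequenced.
#' @return Named numeric vector of percentages.
#' @export
clone_error_percentages <- function(counts, n_total) {
  stopifnot(n_total > 0)
  round(100 * counts / n_total, 1L)
}
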