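# Seeded generators for every input class the package consumes: synthetic
# plasmids with embedded ORFs, insertion count/call tables under several bias
# models, sorted-population (surface / non-surface) count tables with known
# ground-truth permissibility, and aligned reads carrying 1-bp deletions
# (SAM). All generators are pure functions of their configuration and seed.

.sample_codons <- function(n) {
  tab <- .codon_table()
  ok <- names(tab)[tab != "*"]
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic circular plasmid with an embedded ORF
#'
#' The ORF (ATG + random sense codons + TAA) is placed inside a random
#' backbone. By default the whole molecule is scrubbed of BsaI/BsmBI sites
#' (silent swaps inside the ORF, point changes outside); alternatively a
#' stated number of BsmBI sites can be salted into the backbone.
#'
#' @param n_codons ORF length in codons (ATG and stop included on top).
#' @param backbone_len Backbone length (nt) outside the ORF.
#' @param seed RNG seed.
#' @param forbid_sites Scrub all BsaI/BsmBI sites.
#' @param salt_bsmbi Number of BsmBI sites to plant in the backbone (only
#'   when `forbid_sites = FALSE`).
#' @param name Plasmid name.
#' @return A `plasmid`.
#' @export
make_synthetic_plasmid <- function(n_codons, backbone_len = 2400L, seed = 1L,
                                   forbid_sites = TRUE, salt_bsmbi = 0L,
                                   name = sprintf("syngene%d", seed)) {
  stopifnot(n_codons >= 2L, backbone_len >= 400L)
  .with_seed(seed, {
    orf <- paste0("ATG", .sample_codons(n_codons - 1L), "TAA")
    pre <- backbone_len %/% 2L
    bb <- paste(sample(c("A", "C", "G", "T"), backbone_len, replace = TRUE),
                collapse = "")
    seq <- paste0(substr(bb, 1L, pre), orf, substr(bb, pre + 1L, backbone_len))
    orf_start <- pre
    orf_end <- pre + nchar(orf) - 3L   # stop codon kept outside the ORF span
    p <- plasmid(seq, orf_start, orf_end, circular = TRUE, name = name)
    if (forbid_sites) {
      p <- domesticate_plasmid(p)$plasmid
    } else if (salt_bsmbi > 0L) {
      p <- domesticate_plasmid(p)$plasmid
      # plant non-overlapping plus-strand BsmBI sites in the backbone
      slots <- seq(50L, orf_start - 100L, by = 40L)
      at <- sample(slots, salt_bsmbi)
      s2 <- p$sequence
      for (a in at) substr(s2, a + 1L, a + 6L) <- "CGTCTC"
      p <- plasmid(s2, p$orf_start, p$orf_end, TRUE, name)
    }
    p
  })
}

#' Simulate an insertion count table (and frame/direction call table)
#'
#' Draws insertion events over the residues of a gene under one of three
#' bias models: `uniform` (idealized random library), `hotspot` (a few
#' positions carry a large weight multiple), or `trinucleotide` (positions
#' whose local codon context matches a preferred 3-mer, CGG by default, are
#' up-weighted — mimicking transposase bias). The call table assigns reading
#' frame (0/+1/+2) and direction (+/-) uniformly over the six classes.
#'
#' @param n_residues Number of residues.
#' @param total_reads Total insertion reads to distribute.
#' @param bias `"uniform"`, `"hotspot"` or `"trinucleotide"`.
#' @param weight Weight multiple for biased positions.
#' @param n_hotspots Number of hotspot positions (hotspot model).
#' @param gene_seq Gene CDS (required for the trinucleotide model).
#' @param trinucleotide Preferred 3-mer (default `"CGG"`).
#' @param seed RNG seed.
#' @param calls Also simulate a frame/direction call table.
#' @return List with `counts` (an `insertion_counts` data.frame: `position`,
#'   `count`) and, when `calls`, `calls` (data.frame `position`, `frame`,
#'   `direction`, `count`).
#' @export
simulate_insertion_counts <- function(n_residues, total_reads = 300L * n_residues,
                                      bias = c("uniform", "hotspot",
                                               "trinucleotide"),
                                      weight = 10, n_hotspots = 5L,
                                      gene_seq = NULL, trinucleotide = "CGG",
                                      seed = 1L, calls = FALSE) {
  bias <- match.arg(bias)
  .with_seed(seed, {
    w <- rep(1, n_residues)
    if (bias == "hotspot") {
      w[sample(n_residues, n_hotspots)] <- weight
    } else if (bias == "trinucleotide") {
      if (is.null(gene_seq)) stop("gene_seq required for trinucleotide bias")
      codons <- substring(gene_seq, seq(1L, 3L * n_residues, 3L),
                          seq(3L, 3L * n_residues, 3L))
      w[codons == trinucleotide] <- weight
    }
    counts <- as.integer(stats::rmultinom(1L, total_reads, w / sum(w)))
    out <- list(counts = insertion_counts(seq_len(n_residues), counts))
    if (calls) {
      frames <- c(0L, 0L, 1L, 1L, 2L, 2L)
      dirs <- c("+", "-", "+", "-", "+", "-")
      cls <- sample(6L, total_reads, replace = TRUE)
      pos <- sample(n_residues, total_reads, replace = TRUE, prob = w / sum(w))
      agg <- stats::aggregate(list(count = rep(1L, total_reads)),
                              by = list(position = 3L * pos, class = cls),
                              FUN = sum)
      out$calls <- data.frame(
        position = agg$position,
        frame = frames[agg$class], direction = dirs[agg$class],
        count = agg$count, stringsAsFactors = FALSE)
    }
    out
  })
}

#' Simulate sorted-population count tables with known permissibility
#'
#' Each position receives reads (uniform multinomial coverage); every read is
#' assigned to the surface-expressed (SE) population with probability equal
#' to the position's true permissibility, otherwise to the non-surface
#' (NSE) population.
#'
#' @param permissibility Numeric vector in `[0, 1]`, one value per residue
#'   (the ground truth).
#' @param reads_per_position Mean coverage.
#' @param seed RNG seed.
#' @return List with `se` and `nse` (`insertion_counts` tables) and `truth`.
#' @export
simulate_sort_counts <- function(permissibility, reads_per_position = 250L,
                                 seed = 1L) {
  stopifnot(all(permissibility >= 0), all(permissibility <= 1))
  N <- length(permissibility)
  .with_seed(seed, {
    n_i <- as.integer(stats::rmultinom(1L, reads_per_position * N,
                                       rep(1 / N, N)))
    se <- stats::rbinom(N, n_i, permissibility)
    nse <- n_i - se
    list(se = insertion_counts(seq_len(N), se),
         nse = insertion_counts(seq_len(N), nse),
         truth = permissibility)
  })
}

#' Simulate aligned reads carrying single-base deletions (SAM text)
#'
#' Emits plain-text SAM alignment records against a reference gene; a stated
#' fraction of reads carries exactly one 1-nt deletion (encoded in the
#' CIGAR), the rest align full-length.
#'
#' @param reference Reference DNA string.
#' @param n_reads Number of reads.
#' @param deletion_rate Fraction of reads with a single 1-bp deletion.
#' @param read_len Read length.
#' @param seed RNG seed.
#' @param path Optional file to write; when `NULL` the SAM lines are
#'   returned invisibly as a character vector.
#' @return Character vector of SAM lines (header + records), invisibly when
#'   written to `path`.
#' @export
simulate_deletion_alignments <- function(reference, n_reads = 1000L,
                                         deletion_rate = 0.1, read_len = 50L,
                                         seed = 1L, path = NULL) {
  stopifnot(deletion_rate >= 0, deletion_rate <= 1)
  L <- nchar(reference)
  stopifnot(L >= read_len + 1L)
  .with_seed(seed, {
    has_del <- stats::runif(n_reads) < deletion_rate
    starts <- sample(L - read_len, n_reads, replace = TRUE)  # 1-based
    recs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      st <- starts[i]
      if (has_del[i]) {
        k <- sample(read_len - 2L, 1L)  # deletion after k matched bases
        cigar <- sprintf("%dM1D%dM", k, read_len - k)
        sq <- paste0(substr(reference, st, st + k - 1L),
                     substr(reference, st + k + 1L, st + read_len))
      } else {
        cigar <- sprintf("%dM", read_len)
        sq <- substr(reference, st, st + read_len - 1L)
      }
      recs[i] <- paste("read", i, "\t0\tref\t", st, "\t60\t", cigar,
                       "\t*\t0\t0\t", sq, "\t*", sep = "")
    }
    out <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:ref\tLN:%d", L), recs)
    if (!is.null(path)) {
      writeLines(out, path)
      return(invisible(out))
    }
    out
  })
}
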