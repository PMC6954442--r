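# Sequence model, FASTA I/O, codon arithmetic, type-IIS site scanning and
# silent codon swapping. Coordinates are 0-based half-open on the plus strand
# internally; residue numbers are 1-based in user-facing output.

#' Type-IIS enzyme registry
#'
#' Built-in definitions of the two Golden Gate enzymes used throughout the
#' design engine. Both cut 1 nt downstream of their 6-nt recognition sequence
#' and leave 4-nt 5' overhangs.
#'
#' @param enzyme Optional enzyme name; if given, return that single entry.
#' @return A list of enzyme definitions (recognition sequence, spacer length,
#'   overhang length), or one entry when `enzyme` is supplied.
#' @export
enzyme_registry <- function(enzyme = NULL) {
  reg <- list(
    BsaI  = list(name = "BsaI",  recognition = "GGTCTC", spacer = 1L, overhang = 4L),
    BsmBI = list(name = "BsmBI", recognition = "CGTCTC", spacer = 1L, overhang = 4L)
  )
  if (is.null(enzyme)) return(reg)
  if (!enzyme %in% names(reg)) stop("unknown enzyme: ", enzyme)
  reg[[enzyme]]
}

#' Export the enzyme registry as JSON
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_enzyme_registry <- function(path) {
  jsonlite::write_json(enzyme_registry(), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# recognition motifs (plus + minus) whose creation is forbidden in designs
.banned_motifs <- function(enzymes = c("BsaI", "BsmBI")) {
  unlist(lapply(enzymes, function(e) {
    r <- enzyme_registry(e)$recognition
    c(r, revcomp(r))
  }), use.names = FALSE)
}

.check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq)) stop(what, " must be a single string")
  if (nchar(seq) > 0L && grepl("[^ACGT]", seq))
    stop(what, " contains non-ACGT characters (ambiguity codes are rejected)")
  invisible(seq)
}

#' Reverse complement of a DNA string
#' @param seq DNA string (ACGT).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]), collapse = "")
}

# codon -> amino acid lookup built from the standard code
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- stats::setNames(as.character(gc), names(gc))
    }
    tab
  }
})

#' Translate a coding sequence
#'
#' Standard-table translation; stop codons render as `*`.
#'
#' @param cds DNA string, length divisible by 3, ACGT only.
#' @return Protein string (possibly empty).
#' @export
translate_cds <- function(cds) {
  .check_dna(cds, "cds")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cds length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(.codon_table()[codons], collapse = "")
}

#' Construct a plasmid object
#'
#' A circular (or linear) DNA sequence with the coordinates of the target ORF
#' on the plus strand. The ORF must be codon-complete and translate without an
#' internal stop.
#'
#' @param sequence DNA string; mixed case is uppercased, ambiguity codes are
#'   rejected.
#' @param orf_start,orf_end 0-based half-open nucleotide coordinates of the
#'   ORF (excluding any stop codon is permitted but not required; if the final
#'   codon is a stop it is kept out of the insertion design).
#' @param circular Is the molecule circular?
#' @param name Optional display name.
#' @return An object of class `plasmid`.
#' @export
plasmid <- function(sequence, orf_start, orf_end, circular = TRUE, name = "plasmid") {
  sequence <- toupper(sequence)
  .check_dna(sequence, "plasmid sequence")
  L <- nchar(sequence)
  if (orf_start < 0L || orf_end > L || orf_end <= orf_start)
    stop("ORF coordinates out of range")
  if ((orf_end - orf_start) %% 3L != 0L) stop("ORF length not divisible by 3")
  orf <- substr(sequence, orf_start + 1L, orf_end)
  prot <- translate_cds(orf)
  body <- sub("\\*$", "", prot)
  if (grepl("\\*", body))
    stop("ORF contains an internal stop codon")
  structure(
    list(sequence = sequence, length = L, circular = circular,
         orf_start = as.integer(orf_start), orf_end = as.integer(orf_end),
         name = name),
    class = "plasmid")
}

#' @export
print.plasmid <- function(x, ...) {
  cat(sprintf("<plasmid '%s'>  %d bp, %s\n", x$name, x$length,
              if (x$circular) "circular" else "linear"))
  cat(sprintf("  ORF: [%d, %d) on + strand; %d codons\n",
              x$orf_start, x$orf_end, n_codons(x)))
  invisible(x)
}

#' Number of codons in a plasmid's ORF (stop codon excluded)
#' @param p A `plasmid`.
#' @return Integer codon count.
#' @export
n_codons <- function(p) {
  prot <- translate_cds(orf_sequence(p))
  nchar(sub("\\*$", "", prot))
}

#' Extract the ORF sequence of a plasmid
#' @param p A `plasmid`.
#' @return DNA string of the ORF on the plus strand.
#' @export
orf_sequence <- function(p) substr(p$sequence, p$orf_start + 1L, p$orf_end)

#' Protein encoded by the plasmid's ORF (without trailing stop)
#' @param p A `plasmid`.
#' @return Protein string.
#' @export
orf_protein <- function(p) sub("\\*$", "", translate_cds(orf_sequence(p)))

# plasmid base at 0-based position, wrapping when circular
.plasmid_base <- function(p, pos) {
  if (p$circular) pos <- pos %% p$length
  if (pos < 0L || pos >= p$length) stop("position outside linear plasmid")
  substr(p$sequence, pos + 1L, pos + 1L)
}

# substring [from, to) in 0-based coords with circular wrap
.plasmid_sub <- function(p, from, to) {
  if (to < from) stop("empty/negative span")
  if (!p$circular) {
    if (from < 0L || to > p$length) stop("span outside linear plasmid")
    return(substr(p$sequence, from + 1L, to))
  }
  from <- from %% p$length
  span <- to - from  # may wrap
  dd <- paste0(p$sequence, p$sequence)
  substr(dd, from + 1L, from + span)
}

# all match start positions (0-based) of fixed pattern in subject
.fixed_matches <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Scan a sequence for type-IIS recognition sites
#'
#' Reports every occurrence of the enzyme's recognition sequence on both
#' strands. For circular sequences, sites spanning the origin are also found;
#' positions are reported modulo the sequence length.
#'
#' @param seq DNA string or a `plasmid`.
#' @param enzyme `"BsaI"` or `"BsmBI"`.
#' @param circular Treat `seq` as circular (ignored for `plasmid` input,
#'   which carries its own topology).
#' @return A data.frame with columns `enzyme`, `position` (0-based recognition
#'   start on the plus strand), `strand` (`"+"`/`"-"`).
#' @export
find_restriction_sites <- function(seq, enzyme, circular = FALSE) {
  if (inherits(seq, "plasmid")) {
    circular <- seq$circular
    seq <- seq$sequence
  }
  .check_dna(seq)
  ez <- enzyme_registry(enzyme)
  rec <- ez$recognition
  k <- nchar(rec)
  L <- nchar(seq)
  subject <- if (circular && L >= k) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  plus <- .fixed_matches(rec, subject)
  minus <- .fixed_matches(revcomp(rec), subject)
  if (circular) {
    plus <- unique(plus %% L)
    minus <- unique(minus %% L)
  }
  out <- data.frame(
    enzyme = rep(ez$name, length(plus) + length(minus)),
    position = c(plus, minus),
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

# Human codon usage fractions used to rank synonymous alternatives.
# Ties are broken by GC content (higher first), then alphabetically.
.codon_usage <- c(
  TTT = 0.46, TTC = 0.54, TTA = 0.08, TTG = 0.13,
  CTT = 0.13, CTC = 0.20, CTA = 0.07, CTG = 0.40,
  ATT = 0.36, ATC = 0.47, ATA = 0.17, ATG = 1.00,
  GTT = 0.18, GTC = 0.24, GTA = 0.12, GTG = 0.46,
  TCT = 0.19, TCC = 0.22, TCA = 0.15, TCG = 0.05,
  AGT = 0.15, AGC = 0.24,
  CCT = 0.29, CCC = 0.32, CCA = 0.28, CCG = 0.11,
  ACT = 0.25, ACC = 0.36, ACA = 0.28, ACG = 0.11,
  GCT = 0.27, GCC = 0.40, GCA = 0.23, GCG = 0.11,
  TAT = 0.44, TAC = 0.56, TAA = 0.30, TAG = 0.24, TGA = 0.47,
  CAT = 0.42, CAC = 0.58, CAA = 0.27, CAG = 0.73,
  AAT = 0.47, AAC = 0.53, AAA = 0.43, AAG = 0.57,
  GAT = 0.46, GAC = 0.54, GAA = 0.42, GAG = 0.58,
  TGT = 0.46, TGC = 0.54, TGG = 1.00,
  CGT = 0.08, CGC = 0.18, CGA = 0.11, CGG = 0.20,
  AGA = 0.21, AGG = 0.21,
  GGT = 0.16, GGC = 0.34, GGA = 0.25, GGG = 0.25)

.gc_frac <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

#' Synonymous codons ranked by usage
#'
#' All codons encoding `residue`, ordered by human codon-usage fraction
#' (ties: GC content, then alphabetical).
#'
#' @param residue One-letter amino acid (or `"*"`).
#' @return Character vector of codons, most preferred first.
#' @export
ranked_synonymous_codons <- function(residue) {
  tab <- .codon_table()
  cods <- names(tab)[tab == residue]
  if (length(cods) == 0L) stop("unknown residue: ", residue)
  u <- .codon_usage[cods]
  cods[order(-u, -.gc_frac(cods), cods)]
}

# does any banned motif occurrence in `context` overlap [from, to) (0-based)?
.motif_hits_overlapping <- function(context, motifs, from, to) {
  hits <- 0L
  for (m in motifs) {
    st <- .fixed_matches(m, context)
    if (length(st))
      hits <- hits + sum(st < to & (st + nchar(m)) > from)
  }
  hits
}

#' Replace a codon silently to destroy banned motifs
#'
#' Given a codon embedded in flanking context, find a synonymous codon whose
#' substitution removes every banned-motif match overlapping the codon
#' (without creating a new one overlapping it). Candidates are tried in
#' codon-usage rank order.
#'
#' @param codon 3-mer to replace.
#' @param residue Amino acid the codon must keep encoding.
#' @param banned_motifs Character vector of motifs (e.g. recognition
#'   sequences and their reverse complements).
#' @param upstream,downstream Flanking DNA around the codon (enough context
#'   to detect overlapping motifs; >= max motif length - 1 recommended).
#' @return The replacement codon (may equal the input if the input itself is
#'   clean).
#' @export
silent_codon_swap <- function(codon, residue, banned_motifs,
                              upstream = "", downstream = "") {
  if (nchar(codon) != 3L) stop("codon must be a 3-mer")
  if (.codon_table()[codon] != residue)
    stop("codon ", codon, " does not encode ", residue)
  from <- nchar(upstream)
  to <- from + 3L
  for (cand in ranked_synonymous_codons(residue)) {
    ctx <- paste0(upstream, cand, downstream)
    if (.motif_hits_overlapping(ctx, banned_motifs, from, to) == 0L)
      return(cand)
  }
  stop("no synonymous codon for ", residue,
       " removes the banned motif(s); site cannot be silently destroyed")
}

#' Remove type-IIS sites from a plasmid ORF by silent codon swaps
#'
#' Scans the plasmid for BsaI/BsmBI recognition sites and, for every site that
#' overlaps the ORF, substitutes a synonymous codon that destroys it. Sites
#' entirely outside the ORF are left alone (the design only requires a clean
#' ORF plus clean designed elements) unless `backbone = TRUE`, in which case
#' a single-base substitution is applied outside the ORF.
#'
#' @param p A `plasmid`.
#' @param enzymes Enzymes whose sites must be removed.
#' @param backbone Also scrub sites outside the ORF by point substitution.
#' @return List with elements `plasmid` (the domesticated plasmid) and
#'   `changes` (data.frame of edits).
#' @export
domesticate_plasmid <- function(p, enzymes = c("BsaI", "BsmBI"), backbone = TRUE) {
  motifs <- .banned_motifs(enzymes)
  changes <- list()
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) stop("domestication did not converge")
    sites <- do.call(rbind, lapply(enzymes, function(e)
      find_restriction_sites(p, e)))
    if (is.null(sites) || nrow(sites) == 0L) break
    s <- sites[1L, ]
    span <- c(s$position, s$position + nchar(enzyme_registry(s$enzyme)$recognition))
    # positions relative to ORF (no wrap handling inside ORF needed: ORF is contiguous)
    if (span[2] > p$orf_start && span[1] < p$orf_end && span[2] <= p$length) {
      # overlapping codon range
      c0 <- max(0L, (span[1] - p$orf_start) %/% 3L)
      c1 <- min(n_codons(p) - 1L, (span[2] - 1L - p$orf_start) %/% 3L)
      fixed <- FALSE
      for (ci in c0:c1) {
        nt0 <- p$orf_start + 3L * ci
        cod <- substr(p$sequence, nt0 + 1L, nt0 + 3L)
        res <- .codon_table()[cod]
        up <- .plasmid_sub(p, nt0 - 10L, nt0)
        dn <- .plasmid_sub(p, nt0 + 3L, nt0 + 13L)
        new <- tryCatch(
          silent_codon_swap(cod, res, motifs, up, dn),
          error = function(e) NULL)
        if (!is.null(new) && new != cod) {
          seq2 <- p$sequence
          substr(seq2, nt0 + 1L, nt0 + 3L) <- new
          p <- plasmid(seq2, p$orf_start, p$orf_end, p$circular, p$name)
          changes[[length(changes) + 1L]] <- data.frame(
            type = "codon_swap", position = nt0, from = cod, to = new,
            enzyme = s$enzyme, stringsAsFactors = FALSE)
          fixed <- TRUE
          break
        }
      }
      if (!fixed)
        stop("restriction site at ", s$position,
             " overlaps ORF but no silent swap removes it")
    } else if (backbone) {
      # flip the middle base of the recognition match (outside the ORF)
      pos <- (s$position + 3L) %% p$length
      old <- .plasmid_base(p, pos)
      new <- setdiff(c("A", "C", "G", "T"), old)[1]
      seq2 <- p$sequence
      substr(seq2, pos + 1L, pos + 1L) <- new
      p <- plasmid(seq2, p$orf_start, p$orf_end, p$circular, p$name)
      changes[[length(changes) + 1L]] <- data.frame(
        type = "point", position = pos, from = old, to = new,
        enzyme = s$enzyme, stringsAsFactors = FALSE)
    } else {
      stop("site outside ORF at ", s$position, " and backbone scrubbing disabled")
    }
  }
  list(plasmid = p,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(type = character(), position = integer(),
                                 from = character(), to = character(),
                                 enzyme = character(), stringsAsFactors = FALSE))
}

#' Read a plasmid from a FASTA file
#'
#' Multi-record files are allowed; `record` selects one. The ORF is given
#' explicitly or, if omitted, taken as the longest ATG-initiated open reading
#' frame on the plus strand.
#'
#' @param path FASTA file.
#' @param orf_start,orf_end Optional 0-based half-open ORF coordinates.
#' @param circular Topology flag.
#' @param record Record index (default first).
#' @return A `plasmid`.
#' @export
read_plasmid_fasta <- function(path, orf_start = NULL, orf_end = NULL,
                               circular = TRUE, record = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < record) stop("FASTA record ", record, " not present")
  seq <- toupper(as.character(set[[record]]))
  nm <- names(set)[record]
  if (is.null(orf_start) || is.null(orf_end)) {
    orf <- .longest_orf(seq)
    orf_start <- orf[1]; orf_end <- orf[2]
  }
  plasmid(seq, orf_start, orf_end, circular = circular, name = nm)
}

# longest ATG..stop ORF on the plus strand (0-based half-open, stop excluded)
.longest_orf <- function(seq) {
  best <- c(0L, 0L)
  starts <- .fixed_matches("ATG", seq)
  tab <- .codon_table()
  for (st in starts) {
    pos <- st
    repeat {
      if (pos + 3L > nchar(seq)) break
      cod <- substr(seq, pos + 1L, pos + 3L)
      if (tab[cod] == "*") {
        if (pos - st > best[2] - best[1]) best <- c(st, pos)
        break
      }
      pos <- pos + 3L
    }
  }
  if (best[2] == best[1]) stop("no complete ORF found; supply coordinates")
  best
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
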