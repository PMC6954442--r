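# In silico type-IIS (Golden Gate) digestion and ligation, used to verify
# that every designed oligo reconstitutes the intended insertion product.
#
# Double-stranded fragments are modelled on the top strand: `sequence` spans
# the fragment *including* both 4-nt overhang regions; `left_overhang` is the
# 5' extension at the left end (first 4 bases of `sequence`), `right_overhang`
# the bottom-strand 5' extension at the right end (last 4 bases), both written
# in top-strand orientation. Two fragments ligate when one's right overhang
# equals the other's left overhang exactly (no mismatch ligation).

.digest_fragment <- function(sequence, left = "", right = "") {
  structure(list(sequence = sequence, left_overhang = left,
                 right_overhang = right),
            class = "digest_fragment")
}

#' @export
print.digest_fragment <- function(x, ...) {
  cat(sprintf("<digest_fragment> %d nt  [%s ... %s]\n",
              nchar(x$sequence),
              if (nzchar(x$left_overhang)) x$left_overhang else "blunt",
              if (nzchar(x$right_overhang)) x$right_overhang else "blunt"))
  invisible(x)
}

# 0-based top-strand cut positions for all sites; each cut leaves a 4-nt 5'
# overhang spanning [a, a+4)
.cut_positions <- function(seq, enzyme, circular) {
  ez <- enzyme_registry(enzyme)
  sites <- find_restriction_sites(seq, enzyme, circular = circular)
  if (nrow(sites) == 0L) return(integer(0))
  a <- ifelse(sites$strand == "+",
              sites$position + 6L + ez$spacer,
              sites$position - ez$spacer - ez$overhang)
  L <- nchar(seq)
  if (circular) {
    a <- sort(unique(a %% L))
  } else {
    a <- sort(unique(a[a >= 0L & a + ez$overhang <= L]))
  }
  a
}

#' Digest a sequence with a type-IIS enzyme
#'
#' Cuts at every recognition site (both strands), one nucleotide downstream
#' of the recognition sequence, leaving 4-nt 5' overhangs. Recognition sites
#' stay on the fragment that carries them. A sequence without sites is
#' returned intact (as a single fragment).
#'
#' @param seq DNA string.
#' @param enzyme `"BsaI"` or `"BsmBI"`.
#' @param circular Treat `seq` as circular.
#' @return List of `digest_fragment`s.
#' @export
digest_type_iis <- function(seq, enzyme, circular = FALSE) {
  seq <- toupper(seq)
  .check_dna(seq)
  a <- .cut_positions(seq, enzyme, circular)
  L <- nchar(seq)
  if (length(a) == 0L) {
    return(list(.digest_fragment(seq,
                                 left = if (circular) "" else "",
                                 right = "")))
  }
  frags <- list()
  if (circular) {
    k <- length(a)
    for (i in seq_len(k)) {
      from <- a[i]
      to <- if (i < k) a[i + 1L] else a[1L] + L
      span <- to - from + 4L
      dd <- paste0(seq, seq)
      sq <- substr(dd, from + 1L, from + span)
      frags[[i]] <- .digest_fragment(sq, substr(sq, 1L, 4L),
                                     substr(sq, span - 3L, span))
    }
  } else {
    bounds <- c(0L, a, L)
    for (i in seq_len(length(bounds) - 1L)) {
      from <- bounds[i]
      to <- bounds[i + 1L]
      to_ext <- if (i + 1L <= length(a) + 1L && to != L) to + 4L else to
      sq <- substr(seq, from + 1L, to_ext)
      left <- if (from == 0L) "" else substr(sq, 1L, 4L)
      right <- if (to == L) "" else substr(sq, nchar(sq) - 3L, nchar(sq))
      frags[[i]] <- .digest_fragment(sq, left, right)
    }
  }
  frags
}

# join a cycle of fragments into a circular sequence (top strand), dropping
# the 4-base overlap at every junction
.join_cycle <- function(parts) {
  s <- parts[[1]]$sequence
  if (length(parts) > 1L)
    for (i in 2:length(parts))
      s <- paste0(s, substr(parts[[i]]$sequence, 5L, nchar(parts[[i]]$sequence)))
  substr(s, 1L, nchar(s) - 4L)  # final junction closes onto part 1's left overhang
}

#' Assemble digest fragments by Golden Gate ligation
#'
#' Enumerates circular products formed by joining fragments whose 4-nt
#' overhangs are exactly complementary (modelled as top-strand equality).
#' Cycles of one, two or three parts are enumerated; each part may appear
#' once per product. Products still containing an intact recognition site of
#' the enzyme are flagged re-cuttable (they would be re-digested in a
#' one-pot reaction).
#'
#' @param parts List of `digest_fragment`s.
#' @param enzyme Enzyme used for the re-cut flag.
#' @return List of products: each a list with `sequence` (circular, top
#'   strand), `parts` (indices used) and `recuttable`.
#' @export
assemble_golden_gate <- function(parts, enzyme = "BsmBI") {
  stopifnot(length(parts) >= 1L)
  n <- length(parts)
  lo <- vapply(parts, function(x) x$left_overhang, character(1))
  ro <- vapply(parts, function(x) x$right_overhang, character(1))
  ok <- nzchar(lo) & nzchar(ro)
  products <- list()
  add <- function(idx) {
    seqs <- parts[idx]
    sq <- .join_cycle(seqs)
    rec <- nrow(find_restriction_sites(sq, enzyme, circular = TRUE)) > 0L
    products[[length(products) + 1L]] <<- list(sequence = sq, parts = idx,
                                               recuttable = rec)
  }
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (ro[i] == lo[i]) add(i)                       # self-circularization
    for (j in seq_len(n)) {
      if (j == i || !ok[j]) next
      if (ro[i] == lo[j] && ro[j] == lo[i] && i < j) add(c(i, j))
      for (k in seq_len(n)) {
        if (k == i || k == j || !ok[k]) next
        if (ro[i] == lo[j] && ro[j] == lo[k] && ro[k] == lo[i] &&
            i < j && i < k)                          # canonical rotation
          add(c(i, j, k))
      }
    }
  }
  products
}

# is `circle_a` the same circular sequence as `circle_b` (any rotation)?
.same_circle <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}

# expected plasmid with the gene payload region replaced by `replacement`
# (fragment spans codons [s, e]; payload region is [g(s)-1, g(e)+4))
.expected_product <- function(p, s, e, replacement) {
  g <- function(c) p$orf_start + 3L * (c - 1L)
  from <- g(s) - 1L
  to <- g(e) + 4L
  L <- p$length
  before <- .plasmid_sub(p, 0L, from)
  after <- .plasmid_sub(p, to, L)
  paste0(before, replacement, after)
}

# backbone amplicon of a fragment: inverse-PCR product with BsmBI tails
.backbone_amplicon <- function(p, s, e) {
  g <- function(c) p$orf_start + 3L * (c - 1L)
  jR <- g(e)
  jL <- g(s) - 1L
  arc_len <- (jL + 4L - jR) %% p$length
  if (arc_len == 0L) arc_len <- p$length
  arc <- .plasmid_sub(p, jR, jR + arc_len)
  paste0(.BSMBI_FWD, "A", arc, "A", .BSMBI_REV)
}

#' PCR amplicon of a domain with BsaI tails matching the genetic handle
#'
#' Builds the domain-of-interest amplicon whose BsaI digestion yields an
#' insert with overhangs complementary to the handle's, so that
#' handle-replacement Golden Gate leaves linker + domain + linker in frame.
#'
#' @param domain_seq In-frame domain coding sequence (length divisible by 3,
#'   free of BsaI/BsmBI sites).
#' @param handle The `genetic_handle` used in the design.
#' @return Amplicon DNA string.
#' @export
domain_amplicon <- function(domain_seq, handle) {
  domain_seq <- toupper(domain_seq)
  .check_dna(domain_seq, "domain")
  if (nchar(domain_seq) %% 3L != 0L) stop("domain length not divisible by 3")
  n5 <- nchar(handle$linker5_codons)
  a_left <- n5 - 5L                     # 0-based top-strand cut positions in
  a_right <- n5 + 13L                   # the handle (see build_handle)
  # digested insert (incl. overhangs) spans handle 1-based bases
  # [a_left+1, n5] + domain + [n5+13, a_right+4]
  ins <- paste0(substr(handle$sequence, a_left + 1L, n5),
                domain_seq,
                substr(handle$sequence, n5 + 13L, a_right + 4L))
  paste0(.BSAI_FWD, "A", ins, "A", .BSAI_REV)
}

#' Verify a designed pool by simulated two-step Golden Gate assembly
#'
#' For every oligo: (step 1) the fragment's backbone amplicon and the oligo
#' are digested with BsmBI and assembled; the product must equal the
#' (domesticated) plasmid with the genetic handle inserted after the oligo's
#' residue. (Step 2) that product and the domain amplicon are digested with
#' BsaI and assembled; the product must equal the plasmid with
#' linker + domain + linker at the residue, in frame. The verdict is true
#' iff both steps succeed; on failure the first divergent base is located.
#'
#' @param design An `insertion_design`.
#' @param domain_seq In-frame domain coding sequence (default: none ->
#'   step 2 skipped).
#' @return data.frame with `oligo_id`, `position`, `step1_ok`, `step2_ok`,
#'   `in_frame`, `verdict`, `divergence` (0-based position of the first
#'   divergent base, or NA).
#' @export
verify_pool <- function(design, domain_seq = NULL) {
  p <- design$plasmid
  plan <- design$plan
  handle <- design$handle
  prot <- orf_protein(p)
  handle_aa <- translate_cds(handle$sequence)
  do_step2 <- !is.null(domain_seq)
  if (do_step2) {
    damp <- domain_amplicon(domain_seq, handle)
    dparts <- digest_type_iis(damp, "BsaI")
    domain_aa <- translate_cds(domain_seq)
    ins_aa <- paste0(handle$linker5, domain_aa, handle$linker3)
  }
  bb_cache <- lapply(seq_len(nrow(plan)), function(f) {
    amp <- .backbone_amplicon(p, plan$start_codon[f], plan$end_codon[f])
    digest_type_iis(amp, "BsmBI")
  })
  n <- nrow(design$oligos)
  out <- data.frame(oligo_id = design$oligos$oligo_id,
                    position = design$oligos$position,
                    step1_ok = FALSE, step2_ok = NA, in_frame = NA,
                    verdict = FALSE, divergence = NA_integer_,
                    stringsAsFactors = FALSE)
  first_divergence <- function(a, b) {
    if (nchar(a) != nchar(b)) return(min(nchar(a), nchar(b)))
    ac <- strsplit(a, "", fixed = TRUE)[[1]]
    bc <- strsplit(b, "", fixed = TRUE)[[1]]
    w <- which(ac != bc)
    if (length(w)) w[1] - 1L else NA_integer_
  }
  for (i in seq_len(n)) {
    o <- design$oligos[i, ]
    f <- o$subpool
    s <- plan$start_codon[f]; e <- plan$end_codon[f]
    oligo_parts <- digest_type_iis(o$sequence, "BsmBI")
    parts1 <- c(oligo_parts, bb_cache[[f]])
    prods1 <- assemble_golden_gate(parts1, "BsmBI")
    good1 <- Filter(function(x) !x$recuttable && nchar(x$sequence) > 100L, prods1)
    # expected step-1 product: plasmid with this oligo's payload substituted
    payload <- substr(o$sequence, 20L, nchar(o$sequence) - 19L)
    exp1 <- .expected_product(p, s, e, payload)
    ok1 <- length(good1) == 1L && .same_circle(good1[[1]]$sequence, exp1)
    out$step1_ok[i] <- ok1
    if (!ok1) {
      if (length(good1) >= 1L) {
        rot <- good1[[1]]$sequence
        out$divergence[i] <- first_divergence(rot, exp1)
      }
      next
    }
    if (!do_step2) { out$verdict[i] <- TRUE; next }
    prods2 <- assemble_golden_gate(
      c(digest_type_iis(good1[[1]]$sequence, "BsaI", circular = TRUE), dparts),
      "BsaI")
    good2 <- Filter(function(x) !x$recuttable && nchar(x$sequence) > 100L, prods2)
    hoff_payload <- o$handle_offset - 19L   # handle offset within payload
    payload2 <- paste0(substr(payload, 1L, hoff_payload),
                       handle$linker5_codons, domain_seq,
                       handle$linker3_codons,
                       substr(payload, hoff_payload + handle$length + 1L,
                              nchar(payload)))
    exp2 <- .expected_product(p, s, e, payload2)
    ok2 <- length(good2) == 1L && .same_circle(good2[[1]]$sequence, exp2)
    out$step2_ok[i] <- ok2
    if (!ok2) {
      if (length(good2) >= 1L)
        out$divergence[i] <- first_divergence(good2[[1]]$sequence, exp2)
      next
    }
    # in-frame guarantee: ORF of the final product translates to the wildtype
    # protein with linker+domain+linker inserted after residue `position`
    j <- o$position
    ins_extra <- nchar(handle$linker5_codons) + nchar(domain_seq) +
      nchar(handle$linker3_codons)
    rot <- .rotate_to(p, good2[[1]]$sequence)
    orf2 <- substr(rot, p$orf_start + 1L, p$orf_end + ins_extra)
    exp_prot <- paste0(substr(prot, 1L, j), ins_aa,
                       substr(prot, j + 1L, nchar(prot)))
    got_prot <- translate_cds(orf2)
    out$in_frame[i] <- identical(sub("\\*$", "", got_prot), exp_prot)
    out$verdict[i] <- ok1 && ok2 && isTRUE(out$in_frame[i])
  }
  if (!do_step2) out$verdict <- out$step1_ok
  out
}

# rotate circular sequence so that it aligns with plasmid coordinates
# (anchor on the plasmid's first 40 bases, assumed outside the edited region)
.rotate_to <- function(p, circ) {
  anchor <- substr(p$sequence, 1L, 40L)
  dd <- paste0(circ, circ)
  at <- .fixed_matches(anchor, dd)
  if (!length(at)) stop("cannot anchor product to plasmid coordinates")
  substr(dd, at[1] + 1L, at[1] + nchar(circ))
}

#' Export pool verification verdicts as TSV
#' @param verdicts data.frame from [verify_pool()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
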