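# Design of the replaceable genetic handle, the per-position oligo pool,
# subpool amplification barcodes/primers and inverse-PCR backbone primers.
#
# Oligo layout (5'->3', plus strand):
#   [fwd barcode 12] [CGTCTC] [frame base] [gene payload with handle]
#   [frame base] [GAGACG] [rev barcode 12]
# The gene payload of a fragment spanning codons s..e is
#   [base before codon s] [codons s..e, handle inserted after codon j] [base
#   after codon e]
# so that BsmBI digestion releases an insert whose 4-nt overhangs are the
# fragment's wildtype junction overhangs.

.BSMBI_FWD <- "CGTCTC"
.BSMBI_REV <- "GAGACG"   # minus-strand recognition written on the top strand
.BSAI_FWD  <- "GGTCTC"
.BSAI_REV  <- "GAGACC"

#' Build the replaceable genetic handle
#'
#' The handle is the placeholder inserted at every position; it carries two
#' outward-facing BsaI recognition sites that cut inside flexible linkers, so
#' that the handle's interior can later be replaced by any domain of
#' interest, leaving only the linker residues as scars.
#'
#' @param linker5 N-terminal linker residues (default `"SG"`).
#' @param linker3 C-terminal linker residues (default `"GS"`).
#' @return A `genetic_handle`: list with `sequence`, `linker5`, `linker3`,
#'   `left_overhang`, `right_overhang` (the 4-nt BsaI cut overhangs, both
#'   inside linker codons), and `length`.
#' @export
build_handle <- function(linker5 = "SG", linker3 = "GS") {
  if (nchar(linker5) < 2L || nchar(linker3) < 2L)
    stop("linkers must be at least 2 residues to host a 4-nt overhang")
  motifs <- .banned_motifs()
  # junction safety: the handle is spliced between arbitrary gene codons, so
  # no prefix of a banned motif may appear as a handle suffix (a downstream
  # gene context could then complete the site) and vice versa at the start
  junction_safe <- function(seq) {
    L <- nchar(seq)
    for (k in 1:5) {
      sfx <- substr(seq, L - k + 1L, L)
      pfx <- substr(seq, 1L, k)
      if (any(startsWith(motifs, sfx)) ||
          any(substr(motifs, 7L - k, 6L) == pfx))
        return(FALSE)
    }
    TRUE
  }
  valid <- function(seq, n5, n3) {
    a_left <- n5 - 5L
    a_right <- n5 + 13L
    if (a_left < 0L || a_right + 4L > nchar(seq)) return(NULL)
    left_oh <- substr(seq, a_left + 1L, a_left + 4L)
    right_oh <- substr(seq, a_right + 1L, a_right + 4L)
    if (nrow(find_restriction_sites(seq, "BsaI")) != 2L) return(NULL)
    if (nrow(find_restriction_sites(seq, "BsmBI")) != 0L) return(NULL)
    if (left_oh == right_oh || .is_palindrome(left_oh) ||
        .is_palindrome(right_oh) || left_oh == revcomp(right_oh)) return(NULL)
    if (!junction_safe(seq)) return(NULL)
    list(left = left_oh, right = right_oh)
  }
  choices <- function(aa) lapply(strsplit(aa, "", fixed = TRUE)[[1]],
                                 ranked_synonymous_codons)
  # enumerate linker codon combinations in usage-rank order
  combos <- function(ch) {
    grid <- do.call(expand.grid, c(lapply(rev(ch), seq_along),
                                   list(stringsAsFactors = FALSE)))
    grid <- grid[, rev(seq_along(ch)), drop = FALSE]
    apply(grid, 1L, function(idx)
      paste(mapply(function(cods, i) cods[i], ch, idx), collapse = ""))
  }
  if (nchar(linker5) > 3L || nchar(linker3) > 3L)
    stop("linkers longer than 3 residues are not supported by the search")
  for (l5 in combos(choices(linker5))) {
    for (l3 in combos(choices(linker3))) {
      seq <- paste0(l5, .BSAI_REV, .BSAI_FWD, l3)
      v <- valid(seq, nchar(l5), nchar(l3))
      if (is.null(v)) next
      return(structure(
        list(sequence = seq, linker5 = linker5, linker3 = linker3,
             linker5_codons = l5, linker3_codons = l3,
             left_overhang = v$left, right_overhang = v$right,
             length = nchar(seq)),
        class = "genetic_handle"))
    }
  }
  stop("no codon choice for linkers ", linker5, "/", linker3,
       " yields a valid, junction-safe handle")
}

#' @export
print.genetic_handle <- function(x, ...) {
  cat(sprintf("<genetic_handle>  %d nt  %s\n", x$length, x$sequence))
  cat(sprintf("  linkers %s/%s; BsaI cut overhangs %s / %s\n",
              x$linker5, x$linker3, x$left_overhang, x$right_overhang))
  invisible(x)
}

.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# a barcode is acceptable when it is motif-free on its own and when joined to
# the fixed oligo context on either side
.barcode_clean <- function(bc, motifs) {
  ctx_f <- paste0(bc, .BSMBI_FWD)
  ctx_r <- paste0(.BSMBI_REV, bc)
  for (m in motifs) {
    if (length(.fixed_matches(m, ctx_f)) + length(.fixed_matches(m, ctx_r)) >
        length(.fixed_matches(m, .BSMBI_FWD)) + length(.fixed_matches(m, .BSMBI_REV)))
      return(FALSE)
  }
  TRUE
}

#' Generate subpool amplification barcodes
#'
#' Draws random fixed-length barcodes under a minimum pairwise Hamming
#' distance, with balanced GC, no homopolymer runs of five or more, and no
#' BsaI/BsmBI recognition sequence either alone or when joined to the
#' flanking oligo context. Deterministic under `seed`. A user-supplied list
#' can be passed to the design functions in place of generated barcodes.
#'
#' @param n Number of barcodes.
#' @param length Barcode length (default 12).
#' @param min_distance Minimum pairwise Hamming distance (default 4).
#' @param banned_motifs Motifs that must not occur (default BsaI/BsmBI, both
#'   strands).
#' @param seed RNG seed.
#' @return Character vector of barcodes.
#' @export
generate_barcodes <- function(n, length = 12L, min_distance = 4L,
                              banned_motifs = .banned_motifs(), seed = 1L) {
  if (4^length < n)
    stop("infeasible: ", n, " barcodes of length ", length, " do not exist")
  if (length < min_distance)
    stop("infeasible: barcode length below the minimum pairwise distance")
  out <- character(0)
  .with_seed(seed, {
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 2000L * n)
        stop("barcode search budget exhausted (n=", n, ", length=", length,
             ", min_distance=", min_distance, ")")
      bc <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
      gc <- sum(strsplit(bc, "", fixed = TRUE)[[1]] %in% c("G", "C"))
      if (length >= 8L && (gc < length * 0.3 || gc > length * 0.7)) next
      if (grepl("AAAAA|CCCCC|GGGGG|TTTTT", bc)) next
      if (!.barcode_clean(bc, banned_motifs)) next
      if (length(out) && any(vapply(out, .hamming, integer(1), b = bc) <
                             min_distance)) next
      out <- c(out, bc)
    }
  })
  out
}

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# ---- oligo construction -----------------------------------------------------

# gene payload of fragment [s, e] with the handle inserted after codon j
.payload <- function(p, s, e, j, handle) {
  g <- function(c) p$orf_start + 3L * (c - 1L)
  ext_l <- .plasmid_sub(p, g(s) - 1L, g(s))
  ext_r <- .plasmid_sub(p, g(e) + 3L, g(e) + 4L)
  left <- .plasmid_sub(p, g(s), g(j) + 3L)       # codons s..j
  right <- .plasmid_sub(p, g(j + 1L), g(e) + 3L) # codons j+1..e
  paste0(ext_l, left, handle$sequence, right, ext_r)
}

.oligo_seq <- function(bc_fwd, f1, payload, f2, bc_rev) {
  paste0(bc_fwd, .BSMBI_FWD, f1, payload, f2, .BSMBI_REV, bc_rev)
}

#' Design the oligos of one fragment subpool
#'
#' One oligo per insertion position of the fragment: the handle is placed
#' after codon `j` for every `j` from the fragment's first codon to the codon
#' before its last (the junction at the fragment's right edge belongs to the
#' next fragment). Together the subpools of a gene cover every interior
#' inter-codon junction exactly once.
#'
#' @param p Domesticated `plasmid`.
#' @param plan A `fragment_plan`.
#' @param fragment Fragment index into `plan`.
#' @param handle A `genetic_handle`.
#' @param bc_fwd,bc_rev The subpool's barcode pair.
#' @param frame_bases Two single bases completing the 7-nt site cost and
#'   keeping the cut in frame (default `c("A", "A")`).
#' @return data.frame with one row per oligo: `oligo_id`, `gene`, `subpool`,
#'   `position` (residue after which the handle sits), `sequence`,
#'   `handle_offset` (0-based offset of the handle in the oligo).
#' @export
design_subpool_oligos <- function(p, plan, fragment, handle, bc_fwd, bc_rev,
                                  frame_bases = c("A", "A")) {
  row <- plan[plan$fragment == fragment, ]
  if (nrow(row) != 1L) stop("no such fragment in plan")
  s <- row$start_codon; e <- row$end_codon
  js <- seq(s, e - 1L)
  seqs <- vapply(js, function(j)
    .oligo_seq(bc_fwd, frame_bases[1], .payload(p, s, e, j, handle),
               frame_bases[2], bc_rev), character(1))
  oligo_max <- attr(plan, "oligo_max")
  if (!is.null(oligo_max) && any(nchar(seqs) > oligo_max))
    stop("oligo exceeds the length budget (planner bug)")
  data.frame(
    oligo_id = sprintf("%s|sp%02d|pos%04d", p$name, fragment, js),
    gene = p$name, subpool = fragment, position = js,
    sequence = seqs,
    handle_offset = 19L + 1L + 3L * (js - s + 1L),
    stringsAsFactors = FALSE)
}

# ---- primers ----------------------------------------------------------------

.primer_row <- function(name, fragment, role, sequence, anneal_len, tm, offtarget) {
  data.frame(name = name, fragment = fragment, role = role,
             sequence = sequence, anneal_len = anneal_len,
             tm_sugimoto = tm$tm_sugimoto, tm_santalucia = tm$tm_santalucia,
             tm_mean = tm$tm_mean, max_offtarget = offtarget,
             specific = TRUE, stringsAsFactors = FALSE)
}

# choose a spacer base that leaves exactly the intended recognition sites in seq
.frame_base_options <- c("A", "T", "G", "C")

.count_sites <- function(seq) {
  nrow(find_restriction_sites(seq, "BsaI")) +
    nrow(find_restriction_sites(seq, "BsmBI"))
}

#' Design the inverse-PCR backbone primer pair of a fragment
#'
#' The pair amplifies the whole plasmid minus the fragment. Non-annealing 5'
#' tails add inward-facing BsmBI sites whose cut overhangs equal the
#' fragment's plan overhangs. Annealing length is grown one base at a time at
#' the 3' end until the combined (mean of both nearest-neighbor models)
#' melting temperature lies in `tm_window` and the primer has no off-target
#' annealing above `offtarget_max` anywhere else in the plasmid.
#'
#' @param p Domesticated `plasmid`.
#' @param plan A `fragment_plan`.
#' @param fragment Fragment index.
#' @param tm_window Accepted combined-Tm window in degrees C.
#' @param offtarget_max Off-target annealing ceiling in degrees C.
#' @param anneal_range Annealing-length search range (nt). The upper bound
#'   is generous because AT-rich junctions (especially at gene edges, where
#'   the boundary cannot move) need long primers to reach the Tm window.
#' @return data.frame of two primer rows (`backbone_fwd`, `backbone_rev`).
#' @export
design_backbone_primers <- function(p, plan, fragment, tm_window = c(55, 61),
                                    offtarget_max = 35,
                                    anneal_range = c(11L, 45L)) {
  row <- plan[plan$fragment == fragment, ]
  s <- row$start_codon; e <- row$end_codon
  g <- function(c) p$orf_start + 3L * (c - 1L)
  jR <- g(e)            # fwd primer anneals from the first base of codon e
  xL <- g(s) + 3L       # rev primer anneal region ends after codon s
  mk <- function(role) {
    for (La in seq(anneal_range[1], anneal_range[2])) {
      anneal <- if (role == "backbone_fwd") .plasmid_sub(p, jR, jR + La)
                else revcomp(.plasmid_sub(p, xL - La, xL))
      tm <- melting_temperature(anneal)
      if (tm$tm_mean < tm_window[1] || tm$tm_mean > tm_window[2]) {
        if (tm$tm_mean > tm_window[2]) break else next
      }
      for (fb in .frame_base_options) {
        primer <- paste0(.BSMBI_FWD, fb, anneal)
        if (.count_sites(primer) != 1L) next
        excl <- if (role == "backbone_fwd")
          data.frame(template = p$name, strand = "+", start = jR,
                     end = jR + La, stringsAsFactors = FALSE)
        else
          data.frame(template = p$name, strand = "-", start = xL - La - 1L,
                     end = xL - La, stringsAsFactors = FALSE)
        ot <- max_offtarget_annealing(primer, p, exclude = excl)
        if (ot$max_tm <= offtarget_max)
          return(.primer_row(sprintf("%s|sp%02d|%s", p$name, fragment, role),
                             fragment, role, primer, La, tm, ot$max_tm))
        break  # off-target failure: extend rather than change the spacer
      }
    }
    stop("no ", role, " primer for fragment ", fragment,
         " satisfies the Tm window and specificity; adjust the fragment boundary")
  }
  rbind(mk("backbone_fwd"), mk("backbone_rev"))
}

#' Design the subpool amplification primer pair
#'
#' Primers anneal across the barcode, BsmBI recognition and cut region of a
#' subpool's oligos. The 3' end is fixed at the cut site, so melting
#' temperature is tuned by trimming the 5' end; specificity is enforced
#' against the entire oligo pool (and the plasmid).
#'
#' @param oligos data.frame of this subpool's oligos (from
#'   [design_subpool_oligos()]).
#' @param pool Named character vector of all oligos in the library.
#' @param p The `plasmid` (scanned as an additional template).
#' @param tm_window,offtarget_max As in [design_backbone_primers()].
#' @param min_len Minimum primer length when trimming.
#' @return data.frame of two primer rows (`subpool_fwd`, `subpool_rev`), or
#'   an error asking for a barcode swap when no trim length works.
#' @export
design_subpool_primers <- function(oligos, pool, p, tm_window = c(55, 61),
                                   offtarget_max = 35, min_len = 12L) {
  stopifnot(nrow(oligos) >= 1L)
  fragment <- oligos$subpool[1]
  gene <- oligos$gene[1]
  full_f <- substr(oligos$sequence[1], 1L, 23L)
  L_o <- nchar(oligos$sequence[1])      # constant within a subpool
  full_r <- revcomp(substr(oligos$sequence[1], L_o - 22L, L_o))
  own_prefix <- sprintf("%s|sp%02d|", gene, fragment)
  mk <- function(role) {
    full <- if (role == "subpool_fwd") full_f else full_r
    excl <- if (role == "subpool_fwd")
      data.frame(template = own_prefix, strand = "+", start = 0L, end = 23L,
                 stringsAsFactors = FALSE)
    else
      data.frame(template = own_prefix, strand = "-", start = L_o - 24L,
                 end = L_o - 22L, stringsAsFactors = FALSE)
    last_err <- "melting temperature window unreachable"
    for (len in seq(nchar(full), min_len)) {
      primer <- substr(full, nchar(full) - len + 1L, nchar(full))
      tm <- melting_temperature(primer)
      if (tm$tm_mean < tm_window[1] || tm$tm_mean > tm_window[2]) next
      ot_pool <- max_offtarget_annealing(primer, pool, exclude = excl)
      ot_pl <- max_offtarget_annealing(primer, p)
      worst <- max(ot_pool$max_tm, ot_pl$max_tm)
      if (worst <= offtarget_max)
        return(.primer_row(sprintf("%s|sp%02d|%s", gene, fragment, role),
                           fragment, role, primer, len, tm, worst))
      last_err <- "no specific primer at any trim length"
    }
    stop(errorCondition(
      paste0(last_err, " for ", role, " of subpool ", fragment,
             "; swap the barcode"),
      class = c("dominsert_barcode_swap", "error"),
      fragment = fragment, role = role))
  }
  rbind(mk("subpool_fwd"), mk("subpool_rev"))
}

# ---- full design driver -----------------------------------------------------

#' Design a complete programmed domain-insertion oligo library
#'
#' End-to-end driver: domesticates the plasmid (removes BsaI/BsmBI sites),
#' plans codon-aligned fragments with unique Golden Gate overhangs, builds
#' the genetic handle, assigns subpool barcodes, emits one oligo per
#' insertion position, designs backbone and subpool primers, and runs final
#' in silico quality control. The design is a pure function of (plasmid,
#' configuration, seed).
#'
#' @param p A `plasmid`.
#' @param oligo_max Synthesis length limit (default 230 nt).
#' @param tm_window Combined-Tm acceptance window (default 55-61 C).
#' @param offtarget_max Off-target annealing ceiling (default 35 C).
#' @param handle A `genetic_handle` (default [build_handle()]).
#' @param barcodes Optional user-supplied barcode list (character vector);
#'   generated when `NULL`.
#' @param n_spare_barcodes Spare barcodes kept for QC replacements.
#' @param seed Seed for barcode generation.
#' @param domesticate Remove BsaI/BsmBI sites from the plasmid first.
#' @param extra_templates Additional templates (e.g. other genes' oligos)
#'   subpool primers must be specific against.
#' @param reserved_overhangs Overhangs committed to other genes of a shared
#'   pool; this design's overhangs will avoid them.
#' @param run_qc Run [final_qc()] on the assembled design.
#' @return An `insertion_design` object.
#' @export
design_insertion_library <- function(p, oligo_max = 230L, tm_window = c(55, 61),
                                     offtarget_max = 35,
                                     handle = build_handle(),
                                     barcodes = NULL, n_spare_barcodes = 6L,
                                     seed = 1L, domesticate = TRUE,
                                     extra_templates = NULL,
                                     reserved_overhangs = character(),
                                     run_qc = TRUE) {
  original <- p
  dom_changes <- NULL
  if (domesticate) {
    dom <- domesticate_plasmid(p)
    p <- dom$plasmid
    dom_changes <- dom$changes
  }
  p <- prepare_junctions(p, reserved = reserved_overhangs)
  plan <- plan_fragments(p, oligo_max = oligo_max,
                         reserved = reserved_overhangs)
  F <- nrow(plan)
  if (is.null(barcodes))
    barcodes <- generate_barcodes(2L * F + n_spare_barcodes, seed = seed)
  if (length(barcodes) < 2L * F)
    stop("need at least ", 2L * F, " barcodes for ", F, " subpools")
  assign_bc <- data.frame(fragment = rep(seq_len(F), each = 2L),
                          role = rep(c("fwd", "rev"), F),
                          barcode = barcodes[seq_len(2L * F)],
                          stringsAsFactors = FALSE)
  # subpool orthogonality requires pairwise-distinct barcodes; duplicates in
  # a user-supplied list are replaced from the remaining pool
  dup <- duplicated(assign_bc$barcode)
  if (any(dup)) {
    spare <- setdiff(barcodes, assign_bc$barcode)
    if (length(spare) < sum(dup))
      stop("duplicate barcodes assigned and not enough spares to replace them")
    assign_bc$barcode[dup] <- spare[seq_len(sum(dup))]
  }
  frame_bases <- matrix("A", nrow = F, ncol = 2L)
  oligos <- do.call(rbind, lapply(seq_len(F), function(f)
    design_subpool_oligos(p, plan, f, handle,
                          bc_fwd = assign_bc$barcode[assign_bc$fragment == f &
                                                     assign_bc$role == "fwd"],
                          bc_rev = assign_bc$barcode[assign_bc$fragment == f &
                                                     assign_bc$role == "rev"],
                          frame_bases = frame_bases[f, ])))
  backbone <- do.call(rbind, lapply(seq_len(F), function(f)
    design_backbone_primers(p, plan, f, tm_window, offtarget_max)))
  # subpool primers; a failure is remedied by swapping the subpool's barcode
  # for a spare and rebuilding its oligos (bounded retries)
  subpool <- NULL
  for (f in seq_len(F)) {
    for (attempt in 1:8) {
      pool <- stats::setNames(oligos$sequence, oligos$oligo_id)
      if (!is.null(extra_templates)) pool <- c(pool, extra_templates)
      pr <- tryCatch(
        design_subpool_primers(oligos[oligos$subpool == f, ], pool, p,
                               tm_window, offtarget_max),
        dominsert_barcode_swap = function(e) e)
      if (!inherits(pr, "condition")) break
      role <- if (identical(pr$role, "subpool_rev")) "rev" else "fwd"
      spare <- setdiff(barcodes, assign_bc$barcode)
      if (!length(spare)) stop(conditionMessage(pr),
                               " (barcode pool exhausted)")
      sel <- assign_bc$fragment == f & assign_bc$role == role
      assign_bc$barcode[sel] <- spare[1]
      oligos[oligos$subpool == f, ] <- design_subpool_oligos(
        p, plan, f, handle,
        bc_fwd = assign_bc$barcode[assign_bc$fragment == f &
                                   assign_bc$role == "fwd"],
        bc_rev = assign_bc$barcode[assign_bc$fragment == f &
                                   assign_bc$role == "rev"],
        frame_bases = frame_bases[f, ])
      if (attempt == 8L) stop(conditionMessage(pr))
    }
    subpool <- rbind(subpool, pr)
  }
  design <- structure(list(
    plasmid = p, original_plasmid = original, domestication = dom_changes,
    plan = plan, handle = handle,
    barcode_pool = barcodes, barcode_assignment = assign_bc,
    frame_bases = frame_bases,
    oligos = oligos, backbone_primers = backbone, subpool_primers = subpool,
    extra_templates = extra_templates,
    config = list(oligo_max = oligo_max, tm_window = tm_window,
                  offtarget_max = offtarget_max, seed = seed),
    qc = NULL), class = "insertion_design")
  if (run_qc) design <- final_qc(design)
  design
}

#' @export
print.insertion_design <- function(x, ...) {
  cat(sprintf("<insertion_design '%s'>\n", x$plasmid$name))
  cat(sprintf("  gene: %d codons, %d fragments, %d oligos (positions %d..%d)\n",
              n_codons(x$plasmid), nrow(x$plan), nrow(x$oligos),
              min(x$oligos$position), max(x$oligos$position)))
  cat(sprintf("  oligo length max %d nt (budget %d)\n",
              max(nchar(x$oligos$sequence)), x$config$oligo_max))
  pr <- rbind(x$backbone_primers, x$subpool_primers)
  cat(sprintf("  primers: %d; combined Tm %.1f-%.1f C; max off-target %.1f C\n",
              nrow(pr), min(pr$tm_mean), max(pr$tm_mean),
              max(pr$max_offtarget)))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d action(s), %d unresolved\n",
                nrow(x$qc$actions), x$qc$unresolved))
  invisible(x)
}

#' @export
summary.insertion_design <- function(object, ...) {
  x <- object
  print(x)
  cat("\nFragments:\n")
  print.data.frame(as.data.frame(x$plan), row.names = FALSE)
  cat("\nPrimers:\n")
  pr <- rbind(x$backbone_primers, x$subpool_primers)
  print.data.frame(pr[, c("name", "sequence", "tm_mean", "max_offtarget")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

# ---- final QC ---------------------------------------------------------------

# expected site positions (0-based recognition starts) for an oligo
.expected_sites <- function(oligo_seq, handle_offset, handle) {
  L <- nchar(oligo_seq)
  h <- handle_offset
  n5 <- nchar(handle$linker5_codons)
  list(
    BsmBI = data.frame(position = c(12L, L - 18L), strand = c("+", "-")),
    BsaI = data.frame(position = c(h + n5, h + n5 + 6L), strand = c("-", "+")))
}

# classify an unintended site span within an oligo
.classify_span <- function(st, en, L, handle_offset, handle_len) {
  if (st < 12L) return("barcode_fwd")
  if (en > L - 12L) return("barcode_rev")
  if (st <= 18L && en > 18L) return("frame_fwd")
  if (st < L - 18L && en >= L - 18L) return("frame_rev")
  if (en > handle_offset && st < handle_offset + handle_len) return("handle")
  "payload"
}

#' Final in silico quality control of a designed pool
#'
#' Checks every oligo for creation of unintended BsaI/BsmBI recognition
#' sites and every subpool primer for specificity across all oligos.
#' Unintended sites are removed by, in order of preference: flipping the
#' frame base, replacing the offending barcode (from the spare pool), or a
#' silent codon swap inside the gene payload. Non-specific subpool primers
#' trigger a barcode replacement. QC is repeated until clean (bounded), and
#' every change is reported.
#'
#' @param design An `insertion_design`.
#' @param max_iter Iteration bound.
#' @return The corrected `insertion_design`, with `$qc` holding `actions`
#'   (data.frame of changes) and `unresolved` (count; 0 for a clean pool).
#' @export
final_qc <- function(design, max_iter = 10L) {
  actions <- list()
  note <- function(...) actions[[length(actions) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  used_bc <- function() design$barcode_assignment$barcode
  next_spare <- function() {
    spare <- setdiff(design$barcode_pool, used_bc())
    if (!length(spare)) stop("barcode pool exhausted during QC")
    spare[1]
  }
  rebuild_subpool <- function(f) {
    ab <- design$barcode_assignment
    o <- design_subpool_oligos(design$plasmid, design$plan, f, design$handle,
      bc_fwd = ab$barcode[ab$fragment == f & ab$role == "fwd"],
      bc_rev = ab$barcode[ab$fragment == f & ab$role == "rev"],
      frame_bases = design$frame_bases[f, ])
    design$oligos[design$oligos$subpool == f, ] <<- o
  }
  redo_primers <- function(f) {
    pool <- stats::setNames(design$oligos$sequence, design$oligos$oligo_id)
    if (!is.null(design$extra_templates)) pool <- c(pool, design$extra_templates)
    pr <- design_subpool_primers(design$oligos[design$oligos$subpool == f, ],
                                 pool, design$plasmid,
                                 design$config$tm_window,
                                 design$config$offtarget_max)
    design$subpool_primers[design$subpool_primers$fragment == f, ] <<- pr
  }
  unresolved <- 0L
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE       # a structural change (barcode/frame) restarts the audit
    unresolved <- 0L
    redo <- integer(0)
    # 1) unintended recognition sites in oligos; payload codon swaps are
    #    applied in place (independent per oligo), structural fixes rebuild
    #    the subpool and restart the audit
    for (i in seq_len(nrow(design$oligos))) {
      guard <- 0L
      repeat {
        guard <- guard + 1L
        if (guard > 20L) stop("oligo ", design$oligos$oligo_id[i],
                              " cannot be cleaned of recognition sites")
        o <- design$oligos[i, ]
        exp <- .expected_sites(o$sequence, o$handle_offset, design$handle)
        extra <- NULL
        for (ez in c("BsmBI", "BsaI")) {
          found <- find_restriction_sites(o$sequence, ez)
          bad <- found[!(paste(found$position, found$strand) %in%
                         paste(exp[[ez]]$position, exp[[ez]]$strand)), ,
                       drop = FALSE]
          if (nrow(bad)) { extra <- bad[1L, ]; extra_ez <- ez; break }
        }
        if (is.null(extra)) break
        st <- extra$position; en <- st + 6L
        cls <- .classify_span(st, en, nchar(o$sequence), o$handle_offset,
                              design$handle$length)
        f <- o$subpool
        if (cls %in% c("barcode_fwd", "barcode_rev")) {
          role <- if (cls == "barcode_fwd") "fwd" else "rev"
          new_bc <- next_spare()
          sel <- design$barcode_assignment$fragment == f &
                 design$barcode_assignment$role == role
          note(action = "barcode_swap", target = o$oligo_id,
               detail = paste0(design$barcode_assignment$barcode[sel],
                               "->", new_bc), enzyme = extra_ez)
          design$barcode_assignment$barcode[sel] <- new_bc
          rebuild_subpool(f)
          redo <- union(redo, f)
          dirty <- TRUE
          break
        } else if (cls %in% c("frame_fwd", "frame_rev")) {
          col <- if (cls == "frame_fwd") 1L else 2L
          cur <- design$frame_bases[f, col]
          alt <- setdiff(.frame_base_options, cur)[1]
          note(action = "frame_base_flip", target = o$oligo_id,
               detail = paste0(cur, "->", alt), enzyme = extra_ez)
          design$frame_bases[f, col] <- alt
          rebuild_subpool(f)
          redo <- union(redo, f)
          dirty <- TRUE
          break
        } else if (cls == "payload") {
          fix <- .swap_site_in_oligo(design, i, st, en)
          if (is.null(fix)) {
            unresolved <- unresolved + 1L
            note(action = "unresolved_site", target = o$oligo_id,
                 detail = paste0("position ", st), enzyme = extra_ez)
            break
          }
          design$oligos$sequence[i] <- fix$sequence
          note(action = "codon_swap", target = o$oligo_id,
               detail = fix$detail, enzyme = extra_ez)
          redo <- union(redo, f)
          # re-scan the same oligo for further unintended sites
        } else {
          unresolved <- unresolved + 1L
          note(action = "unresolved_site", target = o$oligo_id,
               detail = paste0("position ", st, " (", cls, ")"),
               enzyme = extra_ez)
          break
        }
      }
      if (dirty) break
    }
    # 2) subpool primer specificity across all oligos
    if (!dirty) {
      pool <- stats::setNames(design$oligos$sequence, design$oligos$oligo_id)
      if (!is.null(design$extra_templates))
        pool <- c(pool, design$extra_templates)
      for (r in seq_len(nrow(design$subpool_primers))) {
        pr <- design$subpool_primers[r, ]
        f <- pr$fragment
        gene <- design$oligos$gene[1]
        L_o <- nchar(design$oligos$sequence[design$oligos$subpool == f][1])
        excl <- if (pr$role == "subpool_fwd")
          data.frame(template = sprintf("%s|sp%02d|", gene, f), strand = "+",
                     start = 0L, end = 23L, stringsAsFactors = FALSE)
        else
          data.frame(template = sprintf("%s|sp%02d|", gene, f), strand = "-",
                     start = L_o - 24L, end = L_o - 22L,
                     stringsAsFactors = FALSE)
        ot <- max_offtarget_annealing(pr$sequence, pool, exclude = excl)
        if (ot$max_tm > design$config$offtarget_max) {
          role <- if (pr$role == "subpool_fwd") "fwd" else "rev"
          new_bc <- next_spare()
          sel <- design$barcode_assignment$fragment == f &
                 design$barcode_assignment$role == role
          note(action = "barcode_swap", target = pr$name,
               detail = paste0(design$barcode_assignment$barcode[sel],
                               "->", new_bc), enzyme = NA_character_)
          design$barcode_assignment$barcode[sel] <- new_bc
          rebuild_subpool(f)
          redo <- union(redo, f)
          dirty <- TRUE
          break
        }
      }
    }
    for (f in redo) redo_primers(f)
    if (!dirty) break
    if (iter == max_iter)
      stop("quality control did not converge within ", max_iter, " iterations")
  }
  design$qc <- list(
    actions = if (length(actions)) do.call(rbind, actions)
              else data.frame(action = character(), target = character(),
                              detail = character(), enzyme = character(),
                              stringsAsFactors = FALSE),
    unresolved = unresolved)
  if (unresolved > 0L)
    stop("unresolvable recognition site(s) in: ",
         paste(design$qc$actions$target[
           design$qc$actions$action == "unresolved_site"], collapse = ", "))
  design
}

# attempt a silent codon swap removing a site at oligo span [st, en);
# returns list(sequence, detail) on success, NULL when no swap works
.swap_site_in_oligo <- function(design, i, st, en) {
  o <- design$oligos[i, ]
  p <- design$plasmid
  plan <- design$plan
  row <- plan[plan$fragment == o$subpool, ]
  s <- row$start_codon; e <- row$end_codon; j <- o$position
  hlen <- design$handle$length
  # oligo offsets of gene codons (exclude boundary codons s and e, whose bases
  # sit inside assembly overhangs)
  cods <- setdiff(seq(s, e), c(s, e))
  offs <- as.integer(ifelse(cods <= j, 20L + 3L * (cods - s),
                            20L + 3L * (cods - s) + hlen))
  touched <- cods[offs < en & offs + 3L > st]
  motifs <- .banned_motifs()
  seq0 <- o$sequence
  for (idx in seq_along(touched)) {
    ci <- touched[idx]
    off <- offs[match(ci, cods)]
    cod <- substr(seq0, off + 1L, off + 3L)
    res <- .codon_table()[cod]
    up <- substr(seq0, max(1L, off - 9L), off)
    dn <- substr(seq0, off + 4L, min(nchar(seq0), off + 13L))
    new <- tryCatch(silent_codon_swap(cod, res, motifs, up, dn),
                    error = function(e) NULL)
    if (!is.null(new) && new != cod) {
      seq2 <- seq0
      substr(seq2, off + 1L, off + 3L) <- new
      return(list(sequence = seq2,
                  detail = paste0(cod, "->", new, " @codon ", ci)))
    }
  }
  NULL
}

# ---- multi-gene pools -------------------------------------------------------

#' Design a multi-gene oligo pool with shared, orthogonal barcodes
#'
#' Designs each gene in turn against a shared barcode supply; subpool primers
#' of every gene are required to be specific against the accumulated pool of
#' all genes' oligos.
#'
#' @param plasmids List of `plasmid` objects.
#' @param seed Seed for the shared barcode pool.
#' @param ... Passed to [design_insertion_library()].
#' @return List of `insertion_design` objects (one per gene).
#' @export
design_insertion_pool <- function(plasmids, seed = 1L, ...) {
  need <- sum(vapply(plasmids, function(p)
    2L * nrow(plan_fragments(domesticate_plasmid(p)$plasmid,
                             unique_overhangs = FALSE)), integer(1)))
  bcs <- generate_barcodes(need + 8L, seed = seed)
  designs <- list()
  used <- 0L
  acc <- NULL
  taken <- character()
  for (p in plasmids) {
    d <- design_insertion_library(p, barcodes = bcs[(used + 1L):length(bcs)],
                                  seed = seed, extra_templates = acc,
                                  reserved_overhangs = taken, ...)
    used <- used + nrow(d$plan) * 2L
    acc <- c(acc, stats::setNames(d$oligos$sequence, d$oligos$oligo_id))
    taken <- c(taken, d$plan$left_overhang, d$plan$right_overhang)
    designs[[p$name]] <- d
  }
  designs
}

# ---- export -----------------------------------------------------------------

#' Write a design to disk (oligo FASTA, primer TSV, QC JSON, plan TSV)
#'
#' @param design An `insertion_design`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_design <- function(design, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(stats::setNames(design$oligos$sequence, design$oligos$oligo_id),
              file.path(dir, "oligo_pool.fasta"))
  pr <- rbind(design$backbone_primers, design$subpool_primers)
  utils::write.table(pr, file.path(dir, "primers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fragment_plan(design$plan, file.path(dir, "fragment_plan.tsv"))
  jsonlite::write_json(
    list(actions = design$qc$actions, unresolved = design$qc$unresolved),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
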