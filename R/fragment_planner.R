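# Division of the target ORF into codon-aligned fragments that fit the oligo
# length budget and carry mutually unique Golden Gate overhangs.
#
# Geometry: a fragment spans codons [s, e] (1-based inclusive). Its two 4-nt
# assembly overhangs are read from the wildtype plasmid:
#   left  = the base preceding codon s, then codon s          [g(s)-1, g(s)+3)
#   right = codon e, then the base following it               [g(e),  g(e)+4)
# with g(c) = orf_start + 3*(c-1). Insertions are then possible after codons
# s..e-1 without touching either overhang, so consecutive fragments sharing
# exactly one codon (s[f+1] = e[f]) tile every interior inter-codon junction
# of the ORF exactly once.

# nt budget available for gene sequence per oligo:
# oligo_max - handle(24) - 2 barcodes(2*12) - 2 sites(2*(6+1))
.payload_budget <- function(oligo_max, fixed_costs = c(barcode = 12L, site = 7L, handle = 24L)) {
  as.integer(oligo_max - fixed_costs[["handle"]] -
             2L * fixed_costs[["barcode"]] - 2L * fixed_costs[["site"]])
}

# max codons per fragment: gene payload of a c-codon fragment is 3c + 2
# (two junction extension bases)
.max_fragment_codons <- function(max_payload) (max_payload - 2L) %/% 3L

.overhang_left <- function(p, s) .plasmid_sub(p, p$orf_start + 3L * (s - 1L) - 1L,
                                              p$orf_start + 3L * (s - 1L) + 3L)
.overhang_right <- function(p, e) .plasmid_sub(p, p$orf_start + 3L * (e - 1L),
                                               p$orf_start + 3L * e + 1L)

.is_palindrome <- function(x) x == revcomp(x)

# all 2F overhangs of a span table; returns character vector
.plan_overhangs <- function(p, spans) {
  c(vapply(spans$start_codon, function(s) .overhang_left(p, s), character(1)),
    vapply(spans$end_codon, function(e) .overhang_right(p, e), character(1)))
}

# overhang set validity: pairwise distinct, no revcomp collisions, no palindromes
.overhangs_ok <- function(oh) {
  !any(duplicated(oh)) &&
    !any(vapply(oh, .is_palindrome, logical(1))) &&
    !any(vapply(oh, revcomp, character(1)) %in% oh)
}

#' Prepare the ORF edge junctions for Golden Gate assembly
#'
#' The outermost assembly overhangs are pinned to the gene edges: the left
#' one is [base before the ORF + start codon], the right one [last codon +
#' following base]. When such an edge overhang is palindromic it would
#' self-ligate and no boundary move can fix it; instead the junction is
#' repaired in sequence space: on the left by substituting the (non-coding)
#' backbone base preceding the ORF, on the right by a synonymous swap of the
#' last codon. Either change is checked not to create a BsaI/BsmBI site.
#'
#' @param p A `plasmid` (domesticated).
#' @param reserved Overhangs already committed elsewhere (e.g. other genes of
#'   a shared pool) that the edges must also avoid.
#' @return The (possibly edited) `plasmid`.
#' @export
prepare_junctions <- function(p, reserved = character()) {
  motifs <- .banned_motifs()
  N <- n_codons(p)
  clashes <- function(x) x %in% reserved | revcomp(x) %in% reserved
  window_clean <- function(pp, center) {
    w <- .plasmid_sub(pp, max(0L, center - 6L), min(pp$length, center + 7L))
    all(vapply(motifs, function(m) length(.fixed_matches(m, w)) == 0L,
               logical(1)))
  }
  # left edge: always [x]ATG, whose shared-suffix annealing stays below the
  # specificity ceiling, so only palindromes must be repaired here
  lo <- .overhang_left(p, 1L)
  if (.is_palindrome(lo)) {
    pos <- if (p$circular) (p$orf_start - 1L) %% p$length else p$orf_start - 1L
    done <- FALSE
    for (b in setdiff(c("A", "C", "G", "T"), .plasmid_base(p, pos))) {
      cand <- paste0(b, substr(lo, 2L, 4L))
      if (.is_palindrome(cand)) next
      s2 <- p$sequence
      substr(s2, pos + 1L, pos + 1L) <- b
      p2 <- plasmid(s2, p$orf_start, p$orf_end, p$circular, p$name)
      if (window_clean(p2, pos)) { p <- p2; done <- TRUE; break }
    }
    if (!done) stop("cannot repair palindromic left edge overhang ", lo)
  }
  lo <- .overhang_left(p, 1L)
  ro <- .overhang_right(p, N)
  bad_right <- function(x) .is_palindrome(x) || x == lo || x == revcomp(lo) ||
    clashes(x)
  if (bad_right(ro)) {
    nt0 <- p$orf_start + 3L * (N - 1L)
    cod <- substr(p$sequence, nt0 + 1L, nt0 + 3L)
    res <- .codon_table()[cod]
    ext <- substr(ro, 4L, 4L)
    done <- FALSE
    for (cand in setdiff(ranked_synonymous_codons(res), cod)) {
      if (bad_right(paste0(cand, ext))) next
      s2 <- p$sequence
      substr(s2, nt0 + 1L, nt0 + 3L) <- cand
      p2 <- plasmid(s2, p$orf_start, p$orf_end, p$circular, p$name)
      if (window_clean(p2, nt0 + 1L)) { p <- p2; done <- TRUE; break }
    }
    if (!done) stop("cannot repair clashing right edge overhang ", ro)
  }
  p
}

#' Plan codon-aligned gene fragments
#'
#' Divides the ORF into evenly sized fragments (to the nearest codon) such
#' that each fragment's gene payload fits the synthesis length budget, with
#' consecutive fragments overlapping by exactly one codon. Overhangs are then
#' made unique with [ensure_unique_overhangs()].
#'
#' @param p A `plasmid` (domesticated: free of BsaI/BsmBI sites).
#' @param oligo_max Maximum synthesizable oligo length (default 230 nt).
#' @param fixed_costs Named vector of per-oligo fixed costs (nt):
#'   `barcode` (each of two), `site` (each of two; recognition + 1 spacer),
#'   `handle`.
#' @param unique_overhangs Run [ensure_unique_overhangs()] on the result.
#' @param reserved Overhangs committed elsewhere (multi-gene pools) that this
#'   plan must avoid.
#' @return A `fragment_plan`: data.frame with columns `fragment`,
#'   `start_codon`, `end_codon`, `n_codons`, `nt_span`, `left_overhang`,
#'   `right_overhang`; attributes `max_payload`, `oligo_max`.
#' @export
plan_fragments <- function(p, oligo_max = 230L,
                           fixed_costs = c(barcode = 12L, site = 7L, handle = 24L),
                           unique_overhangs = TRUE, reserved = character()) {
  stopifnot(inherits(p, "plasmid"))
  N <- n_codons(p)
  if (N < 2L) stop("gene shorter than 2 codons")
  max_payload <- .payload_budget(oligo_max, fixed_costs)
  cap <- .max_fragment_codons(max_payload)
  if (cap < 2L) stop("oligo length budget infeasible")
  # F fragments, one-codon overlaps: sum of sizes = N + F - 1, each <= cap.
  # When fragments sit at the cap no boundary can move, so if the overhang
  # search fails the split is re-balanced over one more fragment (bounded).
  F0 <- ceiling((N - 1L) / (cap - 1L))
  last_err <- NULL
  for (F in F0:min(F0 + 3L, N - 1L)) {
    spans <- .split_spans(N, F)
    plan <- .finish_plan(p, spans, max_payload, oligo_max)
    if (!unique_overhangs) return(plan)
    plan <- tryCatch(ensure_unique_overhangs(plan, p, reserved),
                     error = function(e) e)
    if (!inherits(plan, "error")) return(plan)
    last_err <- plan
  }
  stop(conditionMessage(last_err))
}

# even split of codons 1..N into F fragments with one-codon overlaps
.split_spans <- function(N, F) {
  total <- N + F - 1L
  base <- total %/% F
  sizes <- rep(base, F)
  extra <- total - base * F
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  start <- integer(F); end <- integer(F)
  s <- 1L
  for (f in seq_len(F)) {
    start[f] <- s
    end[f] <- s + sizes[f] - 1L
    s <- end[f]                      # one-codon overlap
  }
  stopifnot(end[F] == N)
  data.frame(fragment = seq_len(F), start_codon = start, end_codon = end)
}

.finish_plan <- function(p, spans, max_payload, oligo_max) {
  spans$n_codons <- spans$end_codon - spans$start_codon + 1L
  spans$nt_span <- 3L * spans$n_codons
  spans$left_overhang <- vapply(spans$start_codon, function(s)
    .overhang_left(p, s), character(1))
  spans$right_overhang <- vapply(spans$end_codon, function(e)
    .overhang_right(p, e), character(1))
  structure(spans, class = c("fragment_plan", "data.frame"),
            max_payload = max_payload, oligo_max = oligo_max)
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat(sprintf("<fragment_plan>  %d fragments, payload budget %d nt\n",
              nrow(x), attr(x, "max_payload")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Adjust fragment boundaries to make all overhangs unique
#'
#' The 2F overhangs of a plan must be pairwise distinct, distinct from each
#' other's reverse complements, and non-palindromic (a palindromic overhang
#' would self-ligate). Clashing internal boundaries are moved by whole codons
#' using an outward greedy search (+/-1, +/-2, ... codons, leftmost boundary
#' first, bounded at +/-10); any move that would push a fragment over the
#' payload budget is rejected.
#'
#' @param plan A `fragment_plan`.
#' @param p The `plasmid` the plan was made from.
#' @param reserved Overhangs committed elsewhere that must also be avoided.
#' @return A valid `fragment_plan` (possibly the input unchanged).
#' @export
ensure_unique_overhangs <- function(plan, p, reserved = character()) {
  stopifnot(inherits(plan, "fragment_plan"))
  max_payload <- attr(plan, "max_payload")
  cap <- .max_fragment_codons(max_payload)
  spans <- data.frame(fragment = plan$fragment,
                      start_codon = plan$start_codon,
                      end_codon = plan$end_codon)
  F <- nrow(spans)
  N <- plan$end_codon[F]
  ok_with_reserved <- function(oh) {
    # oh[1] is the gene's left-edge overhang (always [x]ATG; annealing-safe
    # across genes), exempt from the cross-pool reservation
    if (!.overhangs_ok(oh)) return(FALSE)
    if (!length(reserved)) return(TRUE)
    chk <- oh[-1L]
    !any(chk %in% reserved) &&
      !any(vapply(chk, revcomp, character(1)) %in% reserved)
  }
  sizes_ok <- function(sp)
    all(sp$end_codon - sp$start_codon + 1L <= cap) &&
    all(sp$end_codon - sp$start_codon >= 1L)
  if (ok_with_reserved(.plan_overhangs(p, spans)) && sizes_ok(spans))
    return(.finish_plan(p, spans, max_payload, attr(plan, "oligo_max")))
  if (F == 1L)
    stop("overhang clash within a single fragment cannot be adjusted; ",
         "clashing overhangs: ",
         paste(.plan_overhangs(p, spans), collapse = ", "))
  # greedy leftmost-first: fix the gene edges, then move each internal
  # boundary outward (0, +/-1, ..., +/-10 codons) until its two overhangs are
  # compatible with everything accepted so far
  edge_l <- .overhang_left(p, 1L)
  edge_r <- .overhang_right(p, N)
  taken <- c(edge_l, edge_r)
  if (!ok_with_reserved(taken))
    stop("gene edge overhangs clash (", edge_l, ", ", edge_r,
         "); repair the junctions first")
  for (b in seq_len(F - 1L)) {
    placed <- FALSE
    for (d in c(0L, as.vector(rbind(1:10, -(1:10))))) {
      sp2 <- spans
      sp2$end_codon[b] <- sp2$end_codon[b] + d
      sp2$start_codon[b + 1L] <- sp2$start_codon[b + 1L] + d
      if (!sizes_ok(sp2)) next
      oh_b <- c(.overhang_right(p, sp2$end_codon[b]),
                .overhang_left(p, sp2$start_codon[b + 1L]))
      if (!ok_with_reserved(c(edge_l, taken[-1L], oh_b))) next
      spans <- sp2
      taken <- c(taken, oh_b)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("no boundary assignment with unique overhangs found within the ",
           "search budget at fragment boundary ", b)
  }
  stopifnot(ok_with_reserved(.plan_overhangs(p, spans)), sizes_ok(spans))
  .finish_plan(p, spans, max_payload, attr(plan, "oligo_max"))
}

#' Export a fragment plan as TSV
#' @param plan A `fragment_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragment_plan <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
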