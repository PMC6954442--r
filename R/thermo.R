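# Nearest-neighbor melting temperature under two published parameter sets,
# and the 3'-anchored off-target annealing scan used for primer specificity.
#
# Tm = 1000*dH / (dS + 0.368*(N-1)*ln[Na+] + R*ln(C_T/4)) - 273.15
# with dH in kcal/mol, dS in cal/(mol K), R = 1.987 cal/(mol K); the C_T/4
# factor is the non-self-complementary two-strand convention. The entropic
# salt correction is applied to both parameter sets.

.nn_cache <- new.env(parent = emptyenv())

#' Nearest-neighbor parameter table
#'
#' Loads one of the two shipped parameter sets (TSV under `extdata`). The ten
#' unique dinucleotide stacks are expanded to all sixteen via reverse
#' complement symmetry.
#'
#' @param model `"sugimoto1996"` or `"santalucia2004"`.
#' @return List with `dH`/`dS` named vectors over all 16 dinucleotides and
#'   `init`, `init_AT`, `init_GC` two-element vectors (dH, dS).
#' @export
nn_parameters <- function(model = c("santalucia2004", "sugimoto1996")) {
  model <- match.arg(model)
  if (!is.null(.nn_cache[[model]])) return(.nn_cache[[model]])
  path <- system.file("extdata", paste0("nn_", model, ".tsv"),
                      package = "dominsert", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rownames(tab) <- tab$pair
  pairs <- tab$pair[!startsWith(tab$pair, "init")]
  dH <- dS <- stats::setNames(numeric(16),
    as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)))
  for (p in names(dH)) {
    src <- if (p %in% pairs) p else revcomp(p)
    dH[p] <- tab[src, "dH"]; dS[p] <- tab[src, "dS"]
  }
  out <- list(dH = dH, dS = dS,
              init = unlist(tab["init", c("dH", "dS")], use.names = FALSE),
              init_AT = unlist(tab["init_AT", c("dH", "dS")], use.names = FALSE),
              init_GC = unlist(tab["init_GC", c("dH", "dS")], use.names = FALSE))
  .nn_cache[[model]] <- out
  out
}

# core NN Tm without length guard (used for scoring short annealing stretches)
.tm_nn <- function(seq, model, conc = 5e-7, na = 0.05) {
  n <- nchar(seq)
  if (n < 2L) return(-Inf)
  par <- nn_parameters(model)
  di <- substring(seq, 1:(n - 1L), 2:n)
  dH <- par$init[1] + sum(par$dH[di])
  dS <- par$init[2] + sum(par$dS[di])
  for (end in c(substr(seq, 1L, 1L), substr(seq, n, n))) {
    term <- if (end %in% c("A", "T")) par$init_AT else par$init_GC
    dH <- dH + term[1]; dS <- dS + term[2]
  }
  dS <- dS + 0.368 * (n - 1L) * log(na)
  1000 * dH / (dS + 1.987 * log(conc / 4)) - 273.15
}

#' Nearest-neighbor melting temperature under both parameter sets
#'
#' @param seq DNA string, length >= 8, ACGT only.
#' @param conc Total strand concentration (molar; default 500 nM).
#' @param na Monovalent salt concentration (molar; default 50 mM).
#' @return A `tm_estimate`: list with `tm_sugimoto`, `tm_santalucia`,
#'   `tm_mean` (degrees C) and the model parameters.
#' @export
melting_temperature <- function(seq, conc = 5e-7, na = 0.05) {
  .check_dna(seq, "primer")
  if (nchar(seq) < 8L) stop("sequence shorter than 8 nt")
  t1 <- .tm_nn(seq, "sugimoto1996", conc, na)
  t2 <- .tm_nn(seq, "santalucia2004", conc, na)
  structure(list(tm_sugimoto = t1, tm_santalucia = t2,
                 tm_mean = (t1 + t2) / 2,
                 model_params = list(conc = conc, na = na)),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("Tm  Sugimoto %.2f C | SantaLucia %.2f C | mean %.2f C\n",
              x$tm_sugimoto, x$tm_santalucia, x$tm_mean))
  invisible(x)
}

# Templates for off-target scanning: a named character vector of sequences.
.as_templates <- function(template) {
  if (inherits(template, "plasmid"))
    return(stats::setNames(template$sequence, template$name))
  if (is.character(template)) {
    if (length(template) == 0L) stop("empty template")
    if (is.null(names(template)))
      names(template) <- paste0("template", seq_along(template))
    return(toupper(template))
  }
  stop("template must be a plasmid or character vector")
}

# 3'-anchored match positions of `primer` in `subject`: for each occurrence of
# the primer's 3'-terminal anchor k-mer, extend the match 5'-ward and return
# (end position 0-based exclusive, matched length).
.anchored_hits <- function(primer, subject, min_anchor = 6L) {
  m <- nchar(primer)
  if (m < min_anchor) return(NULL)
  anchor <- substr(primer, m - min_anchor + 1L, m)
  starts <- .fixed_matches(anchor, subject)
  if (!length(starts)) return(NULL)
  pch <- strsplit(primer, "", fixed = TRUE)[[1]]
  sch <- strsplit(subject, "", fixed = TRUE)[[1]]
  ends <- starts + min_anchor          # 0-based exclusive end of the match
  lens <- integer(length(starts))
  for (i in seq_along(starts)) {
    len <- min_anchor
    sp <- starts[i]                    # 0-based subject index before the match
    pp <- m - min_anchor               # primer chars remaining 5' of anchor
    while (pp > 0L && sp > 0L && sch[sp] == pch[pp]) {
      len <- len + 1L; sp <- sp - 1L; pp <- pp - 1L
    }
    lens[i] <- len
  }
  list(end = ends, len = lens)
}

#' Maximum off-target annealing temperature of a primer
#'
#' Scans every register of the primer against both strands of each template
#' (circularly for circular plasmids). At each register the best-annealing
#' duplex is the longest contiguous exact match anchored at the primer's 3'
#' end (minimum `min_anchor` nt); it is scored as the combined
#' nearest-neighbor melting temperature of that matched stretch. The maximum
#' over all positions outside the intended footprint is returned.
#'
#' @param primer Primer sequence (5'->3').
#' @param template A `plasmid` or (named) character vector (e.g. oligo pool).
#' @param exclude Optional data.frame describing intended footprints with
#'   columns `template`, `strand`, `start`, `end` (interval of allowed 3'-end
#'   positions in 0-based plus-strand coordinates, `(start, end]`).
#'   `template` is matched as a name prefix.
#' @param min_anchor Minimum 3'-anchored exact match length scored.
#' @return List with `max_tm` (degrees C; `-Inf` when nothing anneals) and
#'   `hits`, a data.frame of scored positions.
#' @export
max_offtarget_annealing <- function(primer, template, exclude = NULL,
                                    min_anchor = 6L) {
  primer <- toupper(primer)
  .check_dna(primer, "primer")
  if (nchar(primer) < 8L) stop("primer shorter than 8 nt")
  tpl <- .as_templates(template)
  if (length(tpl) == 0L || all(nchar(tpl) == 0L)) stop("empty template")
  circular <- inherits(template, "plasmid") && template$circular
  hits <- list()
  for (nm in names(tpl)) {
    s <- tpl[[nm]]
    L <- nchar(s)
    subj_plus <- if (circular) paste0(s, substr(s, 1L, min(L, 60L))) else s
    subj_minus <- revcomp(subj_plus)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") subj_plus else subj_minus
      h <- .anchored_hits(primer, subject, min_anchor)
      if (is.null(h)) next
      # 3'-end position in plus-strand coordinates of the template
      end_plus <- if (strand == "+") h$end else nchar(subject) - h$end
      if (circular) end_plus <- end_plus %% L
      keep <- !duplicated(paste(end_plus, strand))
      hits[[length(hits) + 1L]] <- data.frame(
        template = nm, strand = strand, end = end_plus[keep],
        match_len = h$len[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(list(max_tm = -Inf,
                hits = data.frame(template = character(), strand = character(),
                                  end = integer(), match_len = integer(),
                                  tm = numeric())))
  hits <- do.call(rbind, hits)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    drop <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(exclude))) {
      e <- exclude[i, ]
      drop <- drop | (startsWith(hits$template, e$template) &
                      hits$strand == e$strand &
                      hits$end > e$start & hits$end <= e$end)
    }
    hits <- hits[!drop, , drop = FALSE]
  }
  if (nrow(hits) == 0L)
    return(list(max_tm = -Inf, hits = hits))
  m <- nchar(primer)
  stretch <- substring(primer, m - hits$match_len + 1L, m)
  hits$tm <- vapply(stretch, function(x)
    (.tm_nn(x, "sugimoto1996") + .tm_nn(x, "santalucia2004")) / 2, numeric(1),
    USE.NAMES = FALSE)
  hits <- hits[order(-hits$tm), , drop = FALSE]
  rownames(hits) <- NULL
  list(max_tm = hits$tm[1], hits = hits)
}

#' Is a primer specific against a template?
#'
#' A primer is specific when its maximum off-target annealing temperature
#' does not exceed `threshold` (strictly greater than `threshold` flags it
#' as non-specific).
#'
#' @inheritParams max_offtarget_annealing
#' @param threshold Degrees C (default 35).
#' @return Logical flag.
#' @export
is_specific <- function(primer, template, exclude = NULL, threshold = 35) {
  max_offtarget_annealing(primer, template, exclude)$max_tm <= threshold
}
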