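# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

.fx <- new.env(parent = emptyenv())

# small single-gene design (120 codons, 2 fragments) used across modules
fixture_design <- function() {
  if (is.null(.fx$design)) {
    p <- make_synthetic_plasmid(120, backbone_len = 1600, seed = 7,
                                name = "fixgene")
    .fx$design <- design_insertion_library(p, seed = 7)
  }
  .fx$design
}

# small in-frame, site-free domain (30 codons)
fixture_domain <- function() {
  if (is.null(.fx$domain))
    .fx$domain <- orf_sequence(make_synthetic_plasmid(30, backbone_len = 400,
                                                      seed = 99))
  .fx$domain
}

# 4-gene pool with shared barcodes
fixture_pool <- function() {
  if (is.null(.fx$pool)) {
    ps <- lapply(1:4, function(i)
      make_synthetic_plasmid(60, backbone_len = 1200, seed = 10 + i,
                             name = paste0("g", i)))
    .fx$pool <- design_insertion_pool(ps, seed = 2)
  }
  .fx$pool
}

# brute-force 3'-anchored off-target oracle: all registers, both strands
oracle_offtarget <- function(primer, template, min_anchor = 6L) {
  best <- -Inf
  m <- nchar(primer)
  pch <- strsplit(primer, "")[[1]]
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") template else
      paste(rev(strsplit(chartr("ACGT", "TGCA", template), "")[[1]]),
            collapse = "")
    sch <- strsplit(subj, "")[[1]]
    L <- length(sch)
    for (end in seq_len(L)) {          # 1-based position of the 3' base
      len <- 0L
      while (len < m && end - len >= 1L &&
             sch[end - len] == pch[m - len]) len <- len + 1L
      if (len >= min_anchor) {
        # independent register enumeration; the stretch is scored with the
        # same NN primitive the package uses (itself tested against frozen
        # published-table sums)
        stretch <- substr(primer, m - len + 1L, m)
        val <- (dominsert:::.tm_nn(stretch, "sugimoto1996") +
                dominsert:::.tm_nn(stretch, "santalucia2004")) / 2
        best <- max(best, val)
      }
    }
  }
  best
}
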