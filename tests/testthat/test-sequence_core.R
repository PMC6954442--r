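test_that("translation follows the standard code, renders stops as *", {
  expect_identical(translate_cds("ATGGGA"), "MG")
  expect_identical(translate_cds(""), "")
  expect_identical(translate_cds("ATGTAA"), "M*")
  expect_error(translate_cds("ATGG"), "divisible")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("plasmid construction validates ORF and sequence", {
  seq <- paste0(strrep("ACGGT", 40), "ATGGGATGCTAA", strrep("CT", 50))
  p <- plasmid(seq, 200, 209, circular = TRUE, name = "t")
  expect_identical(orf_protein(p), "MGC")
  expect_equal(n_codons(p), 3L)
  expect_error(plasmid(seq, 200, 210), "divisible")
  expect_error(plasmid(chartr("A", "N", seq), 200, 209), "non-ACGT")
  # internal stop
  seq2 <- paste0(strrep("C", 60), "ATGTAAGGG", strrep("C", 60))
  expect_error(plasmid(seq2, 60, 69), "internal stop")
})

test_that("restriction-site scan finds both strands and origin-spanning sites", {
  expect_equal(find_restriction_sites("AAGGTCTCAA", "BsaI"),
               data.frame(enzyme = "BsaI", position = 2L, strand = "+"),
               ignore_attr = TRUE)
  expect_equal(find_restriction_sites("AAGAGACCAA", "BsaI"),
               data.frame(enzyme = "BsaI", position = 2L, strand = "-"),
               ignore_attr = TRUE)
  # site split across the origin of a 10-mer circle
  circ <- "TCAAAAGGTC"
  expect_equal(nrow(find_restriction_sites(circ, "BsaI", circular = FALSE)), 0L)
  hit <- find_restriction_sites(circ, "BsaI", circular = TRUE)
  expect_equal(hit$position, 6L)
  expect_error(find_restriction_sites("ACGT", "EcoRI"), "unknown enzyme")
})

test_that("site scan matches brute-force doubled-sequence search (property)", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(60:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    for (ez in c("BsaI", "BsmBI")) {
      rec <- enzyme_registry(ez)$recognition
      dd <- paste0(s, substr(s, 1, 5))
      brute <- function(pat) {
        m <- gregexpr(pat, dd, fixed = TRUE)[[1]]
        if (m[1] == -1) integer(0) else sort(unique((as.integer(m) - 1L) %% L))
      }
      got <- find_restriction_sites(s, ez, circular = TRUE)
      expect_equal(sort(got$position[got$strand == "+"]), brute(rec))
      expect_equal(sort(got$position[got$strand == "-"]), brute(revcomp(rec)))
    }
  }
})

test_that("scan on reverse complement mirrors positions with strands exchanged", {
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  s <- paste0(s, "GGTCTC", s, "GAGACC")  # guarantee sites on both strands
  a <- find_restriction_sites(s, "BsaI")
  b <- find_restriction_sites(revcomp(s), "BsaI")
  L <- nchar(s)
  mirrored <- sort(L - 6L - b$position[b$strand == "-"])
  expect_equal(sort(a$position[a$strand == "+"]), mirrored)
})

test_that("silent codon swap preserves residue and destroys the motif", {
  # GGT inside a GGTCTC match: any synonymous Gly codon except GGT breaks it
  swapped <- silent_codon_swap("GGT", "G", .banned <- c("GGTCTC", "GAGACC"),
                               upstream = "AA", downstream = "CTCAA")
  expect_true(swapped %in% c("GGA", "GGC", "GGG"))
  expect_identical(translate_cds(swapped), "G")
  # Met is a single-codon amino acid: unresolvable when fully overlapped
  expect_error(
    silent_codon_swap("ATG", "M", c("CATGC"), upstream = "C", downstream = "C"),
    "no synonymous codon")
})

test_that("domestication removes all planted sites without changing the protein", {
  p <- make_synthetic_plasmid(300, seed = 21, forbid_sites = FALSE,
                              salt_bsmbi = 5)
  expect_equal(nrow(find_restriction_sites(p, "BsmBI")), 5L)
  # plant one site inside the ORF too (codons CGT CTC at codon 50)
  s2 <- p$sequence
  at <- p$orf_start + 3L * 49L
  substr(s2, at + 1L, at + 6L) <- "CGTCTC"
  p2 <- plasmid(s2, p$orf_start, p$orf_end, TRUE, p$name)
  dom <- domesticate_plasmid(p2)
  expect_equal(nrow(find_restriction_sites(dom$plasmid, "BsmBI")), 0L)
  expect_equal(nrow(find_restriction_sites(dom$plasmid, "BsaI")), 0L)
  expect_identical(orf_protein(dom$plasmid), orf_protein(p2))
  expect_true(any(dom$changes$type == "codon_swap"))
})

test_that("FASTA round trip and ORF autodetection work", {
  p <- make_synthetic_plasmid(80, backbone_len = 800, seed = 31)
  tmp <- tempfile(fileext = ".fasta")
  write_fasta(stats::setNames(p$sequence, p$name), tmp)
  # explicit coordinates survive the round trip byte-exactly
  q <- read_plasmid_fasta(tmp, orf_start = p$orf_start, orf_end = p$orf_end)
  expect_identical(q$sequence, p$sequence)
  expect_identical(orf_protein(q), orf_protein(p))
  unlink(tmp)
  # autodetection on an unambiguous molecule finds the embedded ORF
  orf <- paste0("ATG", strrep("GCTGAA", 30), "TAA")
  seq <- paste0(strrep("CT", 40), orf, strrep("GA", 40))
  tmp2 <- tempfile(fileext = ".fasta")
  write_fasta(c(mini = seq), tmp2)
  q2 <- read_plasmid_fasta(tmp2)
  expect_equal(q2$orf_start, 80L)
  expect_equal(n_codons(q2), 61L)
  unlink(tmp2)
})

test_that("codon usage ranking is a total order over synonymous codons", {
  expect_identical(ranked_synonymous_codons("M"), "ATG")
  g <- ranked_synonymous_codons("G")
  expect_setequal(g, c("GGT", "GGC", "GGA", "GGG"))
  expect_identical(g[1], "GGC")  # most used human Gly codon first
})
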