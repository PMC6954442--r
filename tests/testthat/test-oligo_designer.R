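test_that("the genetic handle satisfies all of its structural invariants", {
  h <- build_handle()
  expect_equal(h$length, 24L)
  expect_equal(nchar(h$sequence), 24L)
  expect_equal(nrow(find_restriction_sites(h$sequence, "BsaI")), 2L)
  expect_equal(nrow(find_restriction_sites(h$sequence, "BsmBI")), 0L)
  # in-frame translation contributes the linkers at both ends
  aa <- translate_cds(h$sequence)
  expect_identical(substr(aa, 1, 2), "SG")
  expect_identical(substr(aa, 7, 8), "GS")
  # cut overhangs fall wholly inside linker codons
  expect_identical(h$left_overhang, substr(h$linker5_codons, 2, 5))
  expect_identical(h$right_overhang, substr(h$linker3_codons, 2, 5))
  expect_error(build_handle(linker5 = "S"), "at least 2 residues")
})

test_that("simulated BsaI digestion of the handle releases linker-internal overhangs", {
  h <- build_handle()
  ctx <- paste0("ATGCATCCT", h$sequence, "GAATTGCAT")
  frags <- digest_type_iis(ctx, "BsaI")
  expect_length(frags, 3L)
  expect_identical(frags[[1]]$right_overhang, h$left_overhang)
  expect_identical(frags[[3]]$left_overhang, h$right_overhang)
})

test_that("each subpool carries one oligo per insertion position", {
  d <- fixture_design()
  plan <- d$plan
  for (f in plan$fragment) {
    o <- d$oligos[d$oligos$subpool == f, ]
    expect_equal(nrow(o), plan$n_codons[f] - 1L)
    expect_equal(o$position, seq(plan$start_codon[f], plan$end_codon[f] - 1L))
  }
  # union over subpools: every interior junction exactly once
  expect_equal(sort(d$oligos$position), seq_len(n_codons(d$plasmid) - 1L))
  expect_false(any(duplicated(d$oligos$position)))
  expect_true(all(nchar(d$oligos$sequence) <= 230L))
})

test_that("every oligo payload translates to the fragment with the handle spliced in", {
  d <- fixture_design()
  p <- d$plasmid
  h <- d$handle
  prot <- orf_protein(p)
  handle_aa <- translate_cds(h$sequence)
  for (i in seq(1, nrow(d$oligos), by = 17)) {   # sample across subpools
    o <- d$oligos[i, ]
    f <- o$subpool
    s <- d$plan$start_codon[f]; e <- d$plan$end_codon[f]
    # codon-aligned part of the payload: drop 1-nt extensions at both ends
    core <- substr(o$sequence, 21L, nchar(o$sequence) - 20L)
    expect_equal(nchar(core) %% 3L, 0L)
    want <- paste0(substr(prot, s, o$position), handle_aa,
                   substr(prot, o$position + 1L, e))
    expect_identical(translate_cds(core), want)
  }
})

test_that("generated barcodes satisfy distance, composition and motif rules", {
  bcs <- generate_barcodes(20, seed = 3)
  expect_length(bcs, 20L)
  expect_true(all(nchar(bcs) == 12L))
  for (i in 1:19) for (j in (i + 1):20)
    expect_gte(dominsert:::.hamming(bcs[i], bcs[j]), 4L)
  for (bc in bcs) {
    for (m in c("GGTCTC", "GAGACC", "CGTCTC", "GAGACG")) {
      expect_false(grepl(m, paste0(bc, "CGTCTC"), fixed = TRUE) && m != "CGTCTC")
      expect_false(grepl(m, bc, fixed = TRUE))
    }
  }
  expect_length(generate_barcodes(1, seed = 4), 1L)
  expect_error(generate_barcodes(100, length = 2, min_distance = 3),
               "infeasible")
  # determinism
  expect_identical(generate_barcodes(5, seed = 11),
                   generate_barcodes(5, seed = 11))
})

test_that("accepted primers meet the Tm window and specificity when re-checked", {
  d <- fixture_design()
  pr <- rbind(d$backbone_primers, d$subpool_primers)
  for (i in seq_len(nrow(pr))) {
    anneal <- if (startsWith(pr$role[i], "backbone"))
      substr(pr$sequence[i], 8L, nchar(pr$sequence[i]))
    else pr$sequence[i]
    tm <- melting_temperature(anneal)
    expect_gte(tm$tm_mean, 55)
    expect_lte(tm$tm_mean, 61)
    expect_equal(tm$tm_mean, pr$tm_mean[i], tolerance = 1e-9)
  }
  expect_true(all(pr$max_offtarget <= 35))
})

test_that("backbone primer tails cut to the fragment's plan overhangs", {
  d <- fixture_design()
  p <- d$plasmid
  for (f in d$plan$fragment) {
    amp <- dominsert:::.backbone_amplicon(p, d$plan$start_codon[f],
                                          d$plan$end_codon[f])
    frags <- digest_type_iis(amp, "BsmBI")
    expect_length(frags, 3L)
    center <- frags[[2]]
    expect_identical(center$left_overhang, d$plan$right_overhang[f])
    expect_identical(center$right_overhang, d$plan$left_overhang[f])
  }
})

test_that("subpool primers bind only their own subpool in the pool", {
  pool <- fixture_pool()
  allo <- do.call(c, unname(lapply(pool, function(d)
    stats::setNames(d$oligos$sequence, d$oligos$oligo_id))))
  for (d in pool) {
    gene <- d$oligos$gene[1]
    for (r in seq_len(nrow(d$subpool_primers))) {
      pr <- d$subpool_primers[r, ]
      f <- pr$fragment
      own <- startsWith(names(allo), sprintf("%s|sp%02d|", gene, f))
      # exact full-length match only within the subpool
      if (pr$role == "subpool_fwd") {
        hit <- vapply(allo, function(o)
          grepl(pr$sequence, o, fixed = TRUE), logical(1))
      } else {
        hit <- vapply(allo, function(o)
          grepl(revcomp(pr$sequence), o, fixed = TRUE), logical(1))
      }
      expect_true(all(hit[own]))
      expect_false(any(hit[!own]))
      # and no above-threshold annealing anywhere else
      L_o <- nchar(d$oligos$sequence[d$oligos$subpool == f][1])
      excl <- if (pr$role == "subpool_fwd")
        data.frame(template = sprintf("%s|sp%02d|", gene, f), strand = "+",
                   start = 0L, end = 23L)
      else
        data.frame(template = sprintf("%s|sp%02d|", gene, f), strand = "-",
                   start = L_o - 24L, end = L_o - 22L)
      expect_lte(max_offtarget_annealing(pr$sequence, allo,
                                         exclude = excl)$max_tm, 35)
    }
  }
})

test_that("a planted barcode collision is detected and remedied", {
  p <- make_synthetic_plasmid(60, backbone_len = 1200, seed = 17)
  good <- generate_barcodes(10, seed = 6)
  # same barcode supplied for two subpools: the designer must end up with
  # distinct assignments (collision fixed from the spare pool)
  bcs <- c(good[1], good[2], good[1], good[3], good[4:10])
  d <- design_insertion_library(p, barcodes = bcs, seed = 1)
  expect_false(any(duplicated(d$barcode_assignment$barcode)))
})

test_that("final QC swaps a barcode that creates a recognition site", {
  p <- make_synthetic_plasmid(60, backbone_len = 1200, seed = 2)
  good <- generate_barcodes(12, seed = 5)
  bad_bc <- "ATCATAAGAGAC"   # joined to CGTCTC -> GAGACC (BsaI)
  d <- design_insertion_library(p, barcodes = c(bad_bc, good), seed = 1)
  expect_true(any(d$qc$actions$action == "barcode_swap"))
  for (i in seq_len(nrow(d$oligos))) {
    o <- d$oligos[i, ]
    expect_equal(nrow(find_restriction_sites(o$sequence, "BsaI")), 2L)
    expect_equal(nrow(find_restriction_sites(o$sequence, "BsmBI")), 2L)
  }
})

test_that("final QC on a clean design is a fixed point", {
  d <- fixture_design()
  expect_equal(nrow(d$qc$actions), 0L)
  d2 <- final_qc(d)
  expect_identical(d2$oligos$sequence, d$oligos$sequence)
  expect_equal(nrow(d2$qc$actions), 0L)
})

test_that("final QC silently swaps a codon when the payload carries a site", {
  # un-domesticated gene with a BsmBI site planted mid-fragment
  p <- make_synthetic_plasmid(120, backbone_len = 1600, seed = 23)
  s2 <- p$sequence
  at <- p$orf_start + 3L * 29L           # codon 30, far from boundaries
  substr(s2, at + 1L, at + 6L) <- "CGTCTC"
  p2 <- plasmid(s2, p$orf_start, p$orf_end, TRUE, p$name)
  d <- design_insertion_library(p2, seed = 1, domesticate = FALSE)
  expect_true(any(d$qc$actions$action == "codon_swap"))
  for (i in seq_len(nrow(d$oligos))) {
    o <- d$oligos[i, ]
    expect_equal(nrow(find_restriction_sites(o$sequence, "BsmBI")), 2L)
  }
})

test_that("the full design is deterministic given plasmid, config and seed", {
  p <- make_synthetic_plasmid(60, backbone_len = 1200, seed = 27)
  d1 <- design_insertion_library(p, seed = 3)
  d2 <- design_insertion_library(p, seed = 3)
  expect_identical(d1$oligos$sequence, d2$oligos$sequence)
  expect_identical(d1$backbone_primers$sequence, d2$backbone_primers$sequence)
  expect_identical(d1$subpool_primers$sequence, d2$subpool_primers$sequence)
  # and written artifacts are byte-identical
  t1 <- tempfile(); t2 <- tempfile()
  write_design(d1, t1); write_design(d2, t2)
  for (fn in list.files(t1)) {
    expect_identical(readLines(file.path(t1, fn)),
                     readLines(file.path(t2, fn)))
  }
  unlink(c(t1, t2), recursive = TRUE)
})
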