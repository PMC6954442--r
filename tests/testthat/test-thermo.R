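# Frozen reference values for the fixed 20-mer were computed with an
# independent nearest-neighbor summation over the two published parameter
# sets (500 nM total strand, 50 mM Na+, entropic salt correction) before the
# module was written.

test_that("nearest-neighbor Tm reproduces frozen reference values", {
  tm <- melting_temperature("AGCGTAGCTGAAACGTTGCA")
  expect_equal(tm$tm_sugimoto, 63.1936, tolerance = 0.1 / 63)
  expect_equal(tm$tm_santalucia, 58.2892, tolerance = 0.1 / 58)
  tm2 <- melting_temperature("ACGTACGTACGT")
  expect_equal(tm2$tm_sugimoto, 43.6841, tolerance = 0.01)
  expect_equal(tm2$tm_santalucia, 39.6581, tolerance = 0.01)
})

test_that("Tm equals an in-test spreadsheet NN sum for the unified table", {
  # independent summation with the published unified parameters
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  full_dH <- c(dH, stats::setNames(dH, vapply(names(dH), revcomp, "")))
  full_dS <- c(dS, stats::setNames(dS, vapply(names(dS), revcomp, "")))
  s <- "AGCGTAGCTGAAACGTTGCA"
  n <- nchar(s)
  di <- substring(s, 1:(n - 1), 2:n)
  H <- sum(full_dH[di]); S <- sum(full_dS[di])
  for (end in c(substr(s, 1, 1), substr(s, n, n))) {
    if (end %in% c("A", "T")) { H <- H + 2.3; S <- S + 4.1 }
    else { H <- H + 0.1; S <- S - 2.8 }
  }
  S <- S + 0.368 * (n - 1) * log(0.05)
  tm_hand <- 1000 * H / (S + 1.987 * log(5e-7 / 4)) - 273.15
  expect_equal(melting_temperature(s)$tm_santalucia, tm_hand, tolerance = 1e-9)
})

test_that("Tm rises with GC content and is reverse-complement invariant", {
  at <- melting_temperature(strrep("AT", 10))
  gc <- melting_temperature(strrep("GC", 10))
  expect_lt(at$tm_sugimoto, gc$tm_sugimoto)
  expect_lt(at$tm_santalucia, gc$tm_santalucia)
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    expect_equal(melting_temperature(s)$tm_mean,
                 melting_temperature(revcomp(s))$tm_mean, tolerance = 1e-10)
  }
  expect_error(melting_temperature("ACGTACG"), "shorter than 8")
  expect_error(melting_temperature("ACGTNACGT"), "non-ACGT")
})

test_that("Tm increases with length under homogeneous extension", {
  base <- "GATCGATC"
  prev <- -Inf
  for (k in 1:6) {
    tm <- melting_temperature(strrep(base, k))$tm_mean
    expect_gt(tm, prev)
    prev <- tm
  }
})

test_that("off-target scan agrees with the all-registers brute-force oracle", {
  set.seed(6)
  for (rep in 1:8) {
    template <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                      collapse = "")
    primer <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                    collapse = "")
    got <- max_offtarget_annealing(primer, c(t1 = template))$max_tm
    want <- oracle_offtarget(primer, template)
    if (is.infinite(want)) expect_true(is.infinite(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("planted decoys are found and scored as the matched stretch's Tm", {
  set.seed(7)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  primer <- "TGCAACGTTTCAGCTACGCT"
  decoy <- substr(primer, nchar(primer) - 11L, nchar(primer))  # 3' 12-mer
  template <- paste0(substr(bg, 1, 1500), decoy, substr(bg, 1501, 3000))
  res <- max_offtarget_annealing(primer, c(t1 = template))
  hit <- res$hits[1, ]
  expect_gte(hit$match_len, 12L)
  if (hit$match_len == 12L)
    expect_equal(hit$tm, melting_temperature(decoy)$tm_mean, tolerance = 1e-9)
  # verbatim duplicate scores the full-length Tm and is non-specific
  template2 <- paste0(bg, primer, bg)
  res2 <- max_offtarget_annealing(primer, c(t1 = template2))
  expect_equal(res2$max_tm, melting_temperature(primer)$tm_mean,
               tolerance = 1e-9)
  expect_false(is_specific(primer, c(t1 = template2)))
})

test_that("specificity rule is strict: at the threshold a primer is specific", {
  set.seed(8)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
              collapse = "")
  primer <- "TGCAACGTTTCAGCTACGCT"
  template <- paste0(bg, substr(primer, 13, 20), bg)  # 8-nt 3' decoy
  res <- max_offtarget_annealing(primer, c(t1 = template))
  expect_lt(res$max_tm, 35)          # an 8-mer anneals far below the ceiling
  expect_true(is_specific(primer, c(t1 = template)))
  # boundary semantics: a hit exactly at the threshold is still specific
  expect_true(is_specific(primer, c(t1 = template),
                          threshold = res$max_tm))
  expect_false(is_specific(primer, c(t1 = template),
                           threshold = res$max_tm - 1e-6))
  expect_error(max_offtarget_annealing(primer, character(0)), "empty template")
})

test_that("intended-footprint exclusion removes only the designed site", {
  p <- make_synthetic_plasmid(100, backbone_len = 1000, seed = 41)
  primer <- substr(p$sequence, 101, 124)  # anneals at [100, 124) 0-based
  excl <- data.frame(template = p$name, strand = "+", start = 100L,
                     end = 124L, stringsAsFactors = FALSE)
  with_own <- max_offtarget_annealing(primer, p)
  without <- max_offtarget_annealing(primer, p, exclude = excl)
  expect_equal(with_own$max_tm, melting_temperature(primer)$tm_mean,
               tolerance = 1e-9)
  expect_lt(without$max_tm, with_own$max_tm)
})
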