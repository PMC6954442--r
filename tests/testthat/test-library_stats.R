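test_that("normalized insertions per residue average to one", {
  tb <- insertion_counts(1:10, rep(30L, 10))
  expect_equal(normalized_insertions_per_residue(tb), rep(1, 10))
  # all mass on one position
  tb2 <- insertion_counts(1:8, c(0, 0, 0, 80, 0, 0, 0, 0))
  v <- normalized_insertions_per_residue(tb2)
  expect_equal(v[4], 8)
  expect_equal(sum(v != 0), 1L)
  set.seed(3)
  tb3 <- insertion_counts(1:50, rpois(50, 20) + 1L)
  expect_equal(mean(normalized_insertions_per_residue(tb3)), 1)
  expect_error(normalized_insertions_per_residue(insertion_counts(1:3, c(0, 0, 0))),
               "zero total")
})

test_that("KS statistic matches brute-force ECDF enumeration", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  # n=5 vs n=5: D = sup over all breakpoints of |ECDF_a - ECDF_b|
  a <- c(0.1, 0.4, 0.45, 0.8, 0.9)
  b <- c(0.2, 0.3, 0.5, 0.6, 0.7)
  brk <- sort(c(a, b))
  d_brute <- max(abs(vapply(brk, function(x)
    mean(a <= x) - mean(b <= x), numeric(1))))
  expect_equal(ks_two_sample(a, b)$D, d_brute)
  expect_error(ks_two_sample(numeric(0), 1:3), "empty")
})

test_that("coverage curves resample to target depth and are monotone", {
  tb <- insertion_counts(1:20, rep(300L, 20))
  cc <- coverage_curve(tb, thresholds = c(1, 100, 300, 301))
  expect_equal(cc$fraction_covered, c(1, 1, 1, 0))
  # half the positions empty: fraction <= 0.5 at any threshold >= 1
  tb2 <- insertion_counts(1:20, rep(c(0L, 100L), 10))
  cc2 <- coverage_curve(tb2, thresholds = c(1, 50))
  expect_true(all(cc2$fraction_covered <= 0.5))
  # seeded resampling equals an independent multinomial draw with same seed
  tb3 <- insertion_counts(1:10, c(5L, 10L, 0L, 40L, 5L, 10L, 10L, 10L, 5L, 5L))
  cc3 <- coverage_curve(tb3, thresholds = c(1, 200, 400), normalize_to = 300,
                        seed = 77)
  want <- dominsert:::.with_seed(77,
    as.integer(stats::rmultinom(1L, 300L * 10L, tb3$count / sum(tb3$count))))
  expect_equal(cc3$fraction_covered,
               vapply(c(1, 200, 400), function(th) mean(want >= th),
                      numeric(1)))
  # monotone non-increasing over a random table
  set.seed(4)
  tb4 <- insertion_counts(1:100, rpois(100, 50))
  cc4 <- coverage_curve(tb4, thresholds = c(1, 5, 10, 50, 100, 200))
  expect_true(all(diff(cc4$fraction_covered) <= 0))
})

test_that("six-class frequencies sum to one and enrichment is ratio of frequencies", {
  calls <- data.frame(position = rep(c(3, 9), each = 6),
                      frame = rep(c(0, 0, 1, 1, 2, 2), 2),
                      direction = rep(c("+", "-"), 6),
                      count = c(10, 10, 10, 10, 10, 10,
                                30, 10, 10, 10, 10, 10))
  ff <- frame_direction_frequencies(calls)
  expect_equal(sum(ff$frequency), 1)
  expect_equal(nrow(ff), 6L)
  # identical tables: all enrichments one
  en <- frame_direction_enrichment(calls, calls)
  expect_equal(en$enrichment, rep(1, 6))
  # planted 2x excess of class (0, +)
  sorted <- calls
  control <- calls
  control$count <- rep(10, 12)
  # sorted has 40 of (0,+) over 100 -> 4/12... compute explicitly
  fs <- frame_direction_frequencies(sorted)
  fc <- frame_direction_frequencies(control)
  en2 <- frame_direction_enrichment(sorted, control)
  expect_equal(en2$enrichment,
               fs$frequency / fc$frequency)
  # zero-frequency control class reported as missing, not infinity
  control0 <- control[!(control$frame == 2 & control$direction == "-"), ]
  en3 <- frame_direction_enrichment(sorted, control0)
  expect_true(is.na(en3$enrichment[en3$frame == 2 & en3$direction == "-"]))
  # duplicated calls collapse before normalization
  dup <- rbind(calls, calls[1, ])
  expect_equal(frame_direction_frequencies(dup)$frequency, ff$frequency)
})

test_that("1-bp deletion counting from CIGARs matches constructed truth", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:ref\tLN:500",
           sprintf("r%d\t0\tref\t%d\t60\t%s\t*\t0\t0\t*\t*", 1:6,
                   c(1, 5, 9, 13, 17, 21),
                   c("50M", "20M1D30M", "10M1D10M1D30M", "20M2D30M",
                     "50M", "25M1D25M")))
  df <- deletion_frequency(sam)
  expect_equal(df$n_reads, 6L)
  expect_equal(df$n_deletion_reads, 3L)  # multi-1D read counts once; 2D ignored
  expect_equal(df$frequency, 0.5)
  # depletion: sorted 0.05 vs control 0.10 -> enrichment 0.5
  mk <- function(n, k) c("@SQ\tSN:ref\tLN:500",
    sprintf("r%d\t0\tref\t1\t60\t%s\t*\t0\t0\t*\t*", 1:n,
            c(rep("10M1D40M", k), rep("50M", n - k))))
  en <- deletion_enrichment(mk(100, 5), mk(100, 10))
  expect_equal(en$enrichment, 0.5)
})

test_that("deletion generator parameters are recovered from its SAM output", {
  ref <- orf_sequence(make_synthetic_plasmid(120, seed = 55))
  sam <- simulate_deletion_alignments(ref, n_reads = 10000, deletion_rate = 0.12,
                                      seed = 8)
  df <- deletion_frequency(sam)
  ci <- 3 * sqrt(0.12 * 0.88 / 10000)
  expect_lt(abs(df$frequency - 0.12), ci)
  # rate zero -> frequency zero; determinism
  sam0 <- simulate_deletion_alignments(ref, n_reads = 200, deletion_rate = 0,
                                       seed = 9)
  expect_equal(deletion_frequency(sam0)$frequency, 0)
  expect_identical(simulate_deletion_alignments(ref, 100, 0.3, seed = 10),
                   simulate_deletion_alignments(ref, 100, 0.3, seed = 10))
  # file round trip
  tmp <- tempfile(fileext = ".sam")
  simulate_deletion_alignments(ref, 500, 0.2, seed = 11, path = tmp)
  expect_equal(deletion_frequency(tmp)$n_reads, 500L)
  unlink(tmp)
})

test_that("insertion-context matrices expose a planted trinucleotide preference", {
  p <- make_synthetic_plasmid(400, seed = 61)
  gene <- orf_sequence(p)
  codons <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
  cgg <- which(codons == "CGG")
  skip_if(length(cgg) < 3)   # astronomically unlikely under this seed
  centers <- 3L * (cgg - 1L) + 1L   # nt position of the C
  mats <- insertion_context_matrices(rep(centers, 20), gene, k = 5)
  d <- mats$difference
  expect_gt(d["C", "0"], 0.5)
  expect_gt(d["G", "1"], 0.5)
  expect_gt(d["G", "2"], 0.5)
  # uniform sites: difference matrix ~ 0
  mats0 <- insertion_context_matrices(seq(6, nchar(gene) - 6), gene, k = 5)
  expect_lt(max(abs(mats0$difference)), 0.05)
  # single site: one-hot columns away from the edges
  m1 <- insertion_context_matrices(60L, gene, k = 2)
  expect_true(all(colSums(m1$foreground) == 1))
  expect_true(all(m1$foreground %in% c(0L, 1L)))
  expect_error(insertion_context_matrices(integer(0), gene), "empty")
})

test_that("replicate agreement follows the textbook rank formula", {
  t1 <- insertion_counts(1:6, c(10L, 20L, 30L, 40L, 50L, 60L))
  expect_equal(replicate_spearman(list(t1, t1)), 1)
  t2 <- insertion_counts(1:6, rev(t1$count))
  expect_equal(replicate_spearman(list(t1, t2)), -1)
  # hand computation: ranks b = (3,1,2,6,4,5) -> rho = 1 - 6*12/210
  t3 <- insertion_counts(1:6, c(30L, 10L, 20L, 60L, 40L, 50L))
  expect_equal(replicate_spearman(list(t1, t3)), 1 - 6 * 12 / 210)
  # three replicates: mean of pairwise coefficients
  expect_equal(replicate_spearman(list(t1, t1, t2)), mean(c(1, -1, -1)))
})
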