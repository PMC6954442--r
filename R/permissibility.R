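# Domain-insertion permissibility scoring from sorted populations:
# per-position enrichment between surface-expressed (SE) and non-surface
# expressed (NSE) cells, z-scoring, replicate aggregation, and the
# two-proportion z-test used for false-call comparisons.

#' Per-position permissibility enrichment between sorted populations
#'
#' For each residue i, F(i) = r_SE(i)/t_SE - r_NSE(i)/t_NSE, where r are the
#' position's read counts and t the sample totals. Only positions with reads
#' in *both* populations get a value; all others are NA and excluded from
#' downstream statistics. When no position is NA the profile sums to zero.
#'
#' @param counts_se,counts_nse `insertion_counts` tables over the same gene
#'   (surface-expressed and non-surface-expressed populations).
#' @return A `permissibility_profile` data.frame: `position`, `F`, `z`
#'   (NA until [zscore_profile()]), `na` mask.
#' @export
enrichment_profile <- function(counts_se, counts_nse) {
  if (nrow(counts_se) != nrow(counts_nse))
    stop("SE and NSE tables differ in length")
  t_se <- sum(counts_se$count)
  t_nse <- sum(counts_nse$count)
  if (t_se <= 0 || t_nse <= 0) stop("zero total reads")
  covered <- counts_se$count > 0 & counts_nse$count > 0
  F <- ifelse(covered,
              counts_se$count / t_se - counts_nse$count / t_nse, NA_real_)
  out <- data.frame(position = counts_se$position, F = F, z = NA_real_,
                    na = !covered)
  class(out) <- c("permissibility_profile", "data.frame")
  out
}

#' Z-score a permissibility profile
#'
#' Standardizes the non-NA F values by their sample mean and sample (n-1)
#' standard deviation; NA positions are propagated.
#'
#' @param profile A `permissibility_profile`.
#' @return The profile with its `z` column filled.
#' @export
zscore_profile <- function(profile) {
  x <- profile$F[!profile$na]
  if (length(x) < 2L) stop("fewer than 2 covered positions")
  s <- stats::sd(x)
  if (s == 0) stop("constant profile (sigma = 0)")
  profile$z <- ifelse(profile$na, NA_real_, (profile$F - mean(x)) / s)
  profile
}

#' Aggregate replicate permissibility profiles
#'
#' Per-position mean of z-scores across replicates, ignoring NA; a position
#' is NA in the aggregate only when it is NA in every replicate. (Each
#' replicate is z-scored on its own before averaging.)
#'
#' @param profiles List of >= 2 `permissibility_profile`s (same gene).
#' @return A `permissibility_profile` with the aggregated `z`.
#' @export
aggregate_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ns <- vapply(profiles, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("profiles differ in length")
  profiles <- lapply(profiles, function(pr)
    if (all(is.na(pr$z))) zscore_profile(pr) else pr)
  zmat <- vapply(profiles, function(pr) pr$z, numeric(ns[1]))
  zbar <- rowMeans(zmat, na.rm = TRUE)
  allna <- apply(is.na(zmat), 1L, all)
  zbar[allna] <- NA_real_
  out <- data.frame(position = profiles[[1]]$position,
                    F = NA_real_, z = zbar, na = allna,
                    n_replicates = rowSums(!is.na(zmat)))
  class(out) <- c("permissibility_profile", "data.frame")
  out
}

#' @export
print.permissibility_profile <- function(x, ...) {
  cat(sprintf("<permissibility_profile>  %d positions, %d NA\n",
              nrow(x), sum(x$na)))
  zz <- x$z[!x$na]
  if (length(zz) && !all(is.na(zz)))
    cat(sprintf("  z: mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
                mean(zz), stats::sd(zz), min(zz), max(zz)))
  invisible(x)
}

#' Export a permissibility profile as TSV
#' @param profile A `permissibility_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two-proportion z-test (pooled)
#'
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with the pooled proportion
#' p = (x1 + x2)/(n1 + n2); the p-value is two-sided normal.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    stop("degenerate pooled proportion (all successes or all failures)")
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}
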