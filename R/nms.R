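#' Archaic match statistic for one haplotype-window
#'
#' The match statistic is `S / (N + H)`: the number of derived variants
#' shared between the focal haplotype and the (possibly unphased) archaic
#' genome, normalized by the number of archaic mutations (`N`, sites where
#' the archaic genome carries at least one derived allele, homozygous or
#' heterozygous) plus the number of human mutations (`H`, sites
#' segregating in the target sample at which the archaic genome is not
#' variant). Higher values indicate closer similarity to the archaic
#' genome; archaic calls validated against a real archaic sequence should
#' show elevated values.
#'
#' @param S,N,H Window counts as defined above.
#' @return `S / (N + H)`, or `NA` (with a warning) when `N + H = 0` and
#'   the window should be skipped.
#' @export
nms <- function(S, N, H) {
  stopifnot(S >= 0, N >= 0, H >= 0, S <= N + H || N + H == 0)
  if (N + H == 0) {
    warning("window has no archaic or human mutations; NMS undefined")
    return(NA_real_)
  }
  S / (N + H)
}

#' Match-statistic counts from haplotype data
#'
#' Computes `S`, `N` and `H` for every target haplotype in a window given
#' the archaic genotype at each site (0, 1 or 2 derived copies; a single
#' simulated archaic haplotype is treated as a haploid genotype). A focal
#' derived allele counts as shared when the archaic genotype carries at
#' least one derived copy.
#'
#' @param target `n` x `S` 0/1 target haplotype matrix for the window.
#' @param arch_geno Derived-allele dosage of the archaic genome at each of
#'   the window's sites.
#' @return A list: `S` (per-haplotype shared counts), `N`, `H` (window
#'   scalars) and `nms` (per-haplotype statistic).
#' @export
match_counts <- function(target, arch_geno) {
  target <- as.matrix(target)
  stopifnot(ncol(target) == length(arch_geno))
  arch_carries <- arch_geno > 0
  seg <- colSums(target) > 0L
  N <- sum(arch_carries)
  H <- sum(seg & !arch_carries)
  S <- as.vector(target[, arch_carries, drop = FALSE] %*%
                   rep(1, sum(arch_carries)))
  list(S = S, N = N, H = H,
       nms = if (N + H > 0) S / (N + H) else rep(NA_real_, nrow(target)))
}

#' Per-window match statistics for a simulated region
#'
#' Uses the region's simulated archaic haplotype(s) as the archaic genome
#' (summed into a derived-allele dosage), so the diagnostics are testable
#' without an external archaic reference.
#'
#' @param region An `"archtrace_region"` with at least one archaic
#'   haplotype.
#' @param windows Window-interval matrix from [tile_windows()].
#' @return `n_windows` x `n_target` matrix of match statistics (`NA` where
#'   undefined).
#' @export
nms_windows <- function(region, windows) {
  ai <- region$panels$archaic
  if (!length(ai)) stop("region has no archaic haplotype")
  ti <- region$panels$target
  out <- matrix(NA_real_, nrow = nrow(windows), ncol = length(ti))
  for (k in seq_len(nrow(windows))) {
    idx <- which(region$positions >= windows[k, 1] &
                   region$positions < windows[k, 2])
    mc <- match_counts(region$haps[ti, idx, drop = FALSE],
                       colSums(region$haps[ai, idx, drop = FALSE]))
    out[k, ] <- mc$nms
  }
  out
}

#' Archaic vs non-archaic match contrast
#'
#' For each window with both call classes present, the contrast
#' `(mean NMS of archaic-called haplotypes - mean NMS of the rest) /
#' (mean NMS of all haplotypes)`; the division controls for mutation-rate
#' heterogeneity between windows. The genome-wide mean over windows is
#' tested against zero with a delete-one-block jackknife z-test over
#' 100 kb blocks. Windows with less than 90% callable bases are excluded.
#'
#' @param nms_mat `n_windows` x `n_haplotypes` match statistics.
#' @param calls Logical matrix of the same shape: archaic call per
#'   (window, haplotype).
#' @param windows Window-interval matrix (used to assign jackknife
#'   blocks).
#' @param callable_fraction Per-window accessible-base fraction.
#' @param min_callable Minimum callable fraction for a window to
#'   contribute.
#' @param block_bp Jackknife block size in bp.
#' @return A list: `mean_delta`, `se`, `p` (two-sided), `n_windows`
#'   (contributing count), `delta` (per-window values, `NA` where not
#'   contributing).
#' @export
delta_nms <- function(nms_mat, calls, windows,
                      callable_fraction = rep(1, nrow(nms_mat)),
                      min_callable = 0.9, block_bp = 1e5) {
  stopifnot(all(dim(nms_mat) == dim(calls)),
            nrow(windows) == nrow(nms_mat))
  delta <- rep(NA_real_, nrow(nms_mat))
  for (k in seq_len(nrow(nms_mat))) {
    if (is.na(callable_fraction[k]) || callable_fraction[k] < min_callable)
      next
    v <- nms_mat[k, ]
    cl <- calls[k, ]
    if (anyNA(v) || !any(cl) || all(cl)) next
    denom <- mean(v)
    if (denom == 0) next
    delta[k] <- (mean(v[cl]) - mean(v[!cl])) / denom
  }
  use <- which(!is.na(delta))
  if (!length(use)) stop("no qualifying windows for the NMS contrast")
  block_id <- floor(windows[use, 1] / block_bp)
  blocks <- split(delta[use], block_id)
  if (length(blocks) < 2L)
    stop("the NMS contrast jackknife needs windows in at least 2 blocks")
  jk <- block_jackknife(function(bl) mean(unlist(bl)), blocks)
  z <- jk$estimate / jk$se
  list(mean_delta = jk$estimate, se = jk$se,
       p = 2 * stats::pnorm(-abs(z)), n_windows = length(use),
       delta = delta)
}

#' Archaic call frequency binned by background-selection strength
#'
#' Bins positions by their B-value (a published measure of selective
#' constraint; lower = more constrained) into `[0, 250]`, `(250, 500]`,
#' `(500, 750]`, `(750, 1000]`, reports the mean confident-archaic call
#' frequency per bin, and tests the lowest-vs-highest bin difference with
#' a 50 kb block jackknife. Purging of archaic ancestry by selection shows
#' up as lower frequencies in low-B bins.
#'
#' @param positions Genomic positions (bp) of the scored sites.
#' @param freq Archaic call frequency at each position.
#' @param bvalues B-value at each position (0-1000).
#' @param block_bp Jackknife block size in bp.
#' @return A list: `bins` (data frame of bin, n, mean frequency; empty
#'   bins reported with `NA`), `diff` (highest minus lowest bin mean),
#'   `se`, `p`.
#' @export
bvalue_bins <- function(positions, freq, bvalues, block_bp = 5e4) {
  stopifnot(length(positions) == length(freq),
            length(freq) == length(bvalues))
  breaks <- c(-Inf, 250, 500, 750, 1000)
  labels <- c("[0-250]", "(250-500]", "(500-750]", "(750-1000]")
  bin <- cut(bvalues, breaks = breaks, labels = labels)
  means <- tapply(freq, bin, mean)
  bins <- data.frame(bin = labels,
                     n = as.integer(table(bin)[labels]),
                     mean_freq = as.numeric(means[labels]))
  lo <- bin == labels[1]
  hi <- bin == labels[4]
  if (!any(lo, na.rm = TRUE) || !any(hi, na.rm = TRUE))
    return(list(bins = bins, diff = NA_real_, se = NA_real_, p = NA_real_))
  block_id <- floor(positions / block_bp)
  df <- data.frame(freq = freq, lo = lo, hi = hi, block = block_id)
  blocks <- split(df, df$block)
  stat <- function(bl) {
    d <- do.call(rbind, bl)
    mean(d$freq[d$hi]) - mean(d$freq[d$lo])
  }
  jk <- tryCatch(block_jackknife(stat, blocks), error = function(e) NULL)
  if (is.null(jk) || !is.finite(jk$se) || jk$se == 0) {
    est <- stat(blocks)
    return(list(bins = bins, diff = est, se = if (is.null(jk)) NA else jk$se,
                p = if (!is.null(jk) && jk$se == 0 && est == 0) 1 else NA))
  }
  z <- jk$estimate / jk$se
  list(bins = bins, diff = jk$estimate, se = jk$se,
       p = 2 * stats::pnorm(-abs(z)))
}
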