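#' Haplotype analysis window
#'
#' Bundles the inputs to feature extraction for one focal haplotype: the
#' target-panel and reference-panel haplotypes restricted to the variants
#' inside one window, with positions in bp. Features never see the archaic
#' haplotype.
#'
#' @param target `n` x `S` 0/1 matrix of target haplotypes (1 = derived).
#' @param ref `n_ref` x `S` 0/1 matrix of reference haplotypes.
#' @param positions Sorted bp positions of the `S` variants.
#' @param focal Row index of the focal haplotype in `target`.
#' @param start,end Window interval in bp (half-open).
#' @return An object of class `"archtrace_window"`.
#' @export
haplotype_window <- function(target, ref, positions, focal = 1L,
                             start = 0, end = max(positions, 0) + 1) {
  target <- as.matrix(target); ref <- as.matrix(ref)
  stopifnot(ncol(target) == length(positions), ncol(ref) == length(positions),
            focal >= 1, focal <= nrow(target))
  structure(list(target = target, ref = ref, positions = as.numeric(positions),
                 focal = as.integer(focal), start = start, end = end),
            class = "archtrace_window")
}

#' Extract a window from a simulated region
#'
#' @param region An `"archtrace_region"`.
#' @param start,end Half-open window interval in bp.
#' @param focal Target-panel haplotype index.
#' @return An `"archtrace_window"` restricted to variants in the interval.
#' @export
region_window <- function(region, start, end, focal = 1L) {
  idx <- which(region$positions >= start & region$positions < end)
  haplotype_window(
    target = region$haps[region$panels$target, idx, drop = FALSE],
    ref = region$haps[region$panels$ref, idx, drop = FALSE],
    positions = region$positions[idx], focal = focal,
    start = start, end = end)
}

#' Individual frequency spectrum of the focal haplotype
#'
#' Entry `i` (for `i = 1..n`, the target-panel size) counts the derived
#' alleles carried by the focal haplotype whose derived-allele count in the
#' target panel equals `i`: entry 1 counts target singletons on the focal
#' haplotype, entry 2 doubletons, and entry `n` sites fixed derived in the
#' target panel. Archaic admixture leaves an excess of alleles at
#' frequencies near the admixture fraction, which this spectrum captures.
#'
#' @param window An `"archtrace_window"`.
#' @return Integer vector of length `n`.
#' @export
compute_ifs <- function(window) {
  n <- nrow(window$target)
  carried <- window$target[window$focal, ] == 1L
  counts <- colSums(window$target)[carried]
  tabulate(counts, nbins = n)
}

#' Euclidean distance vector and its moments
#'
#' Distances from the focal haplotype to every target haplotype (self
#' included, distance 0) over all window variants, sorted ascending so the
#' feature is invariant to haplotype ordering, together with the mean,
#' variance, skew and kurtosis of the unsorted distance distribution.
#'
#' @param window An `"archtrace_window"`.
#' @return A list with `dist` (sorted length-`n` vector) and `moments`
#'   (named vector `mean`, `var`, `skew`, `kurt`).
#' @export
compute_distance_features <- function(window) {
  f <- window$target[window$focal, ]
  d <- sqrt(colSums((t(window$target) - f)^2))
  list(dist = sort(d), moments = dist_moments(d))
}

#' Minimum distance to the reference panel
#'
#' Minimum Euclidean distance from the focal haplotype to any reference
#' haplotype over the window's variants. Large values suggest ancestry
#' from a population that diverged before the target-reference split.
#'
#' @param window An `"archtrace_window"`.
#' @return A non-negative number.
#' @export
compute_min_ref_distance <- function(window) {
  if (nrow(window$ref) == 0L)
    stop("reference panel is empty: the minimum-reference-distance ",
         "feature is undefined (use the no-reference feature set)")
  f <- window$target[window$focal, ]
  min(sqrt(colSums((t(window$ref) - f)^2)))
}

#' Number of SNPs private to the focal haplotype
#'
#' Counts sites at which the focal haplotype carries the derived allele and
#' the derived allele is entirely absent from the reference panel (the
#' derived count in the target panel is unconstrained).
#'
#' @param window An `"archtrace_window"`.
#' @return A non-negative integer.
#' @export
count_private_snps <- function(window) {
  carried <- window$target[window$focal, ] == 1L
  sum(carried & colSums(window$ref) == 0L)
}

#' S* hyperparameters
#'
#' Scoring constants for the S* dynamic program, following the
#' Vernot-Akey-style dialect: linking two candidate sites `bp` base pairs
#' apart scores `bp + bonus` when `bp >= min_bp` and `penalty` otherwise;
#' chains may skip sites and negative prefixes are reset to zero.
#'
#' @param bonus Reward added to the bp distance of an admissible link.
#' @param min_bp Minimum spacing for an admissible link.
#' @param penalty Score of a link closer than `min_bp`.
#' @export
sstar_params <- function(bonus = 5000, min_bp = 10, penalty = -10000) {
  list(bonus = bonus, min_bp = min_bp, penalty = penalty)
}

# Core S* dynamic program over sorted candidate positions.
sstar_dp <- function(pos, params = sstar_params()) {
  k <- length(pos)
  if (k < 2L) return(0)
  S <- numeric(k)
  for (j in 2:k) {
    d <- pos[j] - pos[seq_len(j - 1L)]
    s <- ifelse(d >= params$min_bp, d + params$bonus, params$penalty)
    S[j] <- max(0, S[seq_len(j - 1L)] + s)
  }
  max(S, 0)
}

#' S* statistic of the focal haplotype
#'
#' Scores long, high-LD chains of derived alleles absent from the
#' reference panel, a classic signal of introgressed haplotypes. Candidate
#' sites are those where the focal haplotype carries the derived allele and
#' the reference derived count is zero; a dynamic program then maximizes
#' the chain score `S(j) = max(0, max_{i<j} S(i) + s(i, j))` with the
#' pairwise scores of [sstar_params()]. Zero when fewer than two candidate
#' sites exist.
#'
#' @param window An `"archtrace_window"`.
#' @param params Scoring constants, see [sstar_params()].
#' @return A non-negative number.
#' @export
compute_s_star <- function(window, params = sstar_params()) {
  cand <- window$target[window$focal, ] == 1L & colSums(window$ref) == 0L
  sstar_dp(window$positions[cand], params)
}

#' Feature names in canonical order
#'
#' @param n Target-panel haploid sample size.
#' @param extra_count Include the trailing total focal derived-allele count
#'   feature (the default 208-feature layout at `n = 100`).
#' @return Character vector of feature names.
#' @export
feature_names <- function(n, extra_count = TRUE) {
  c(paste0("ifs", seq_len(n)), paste0("dist", seq_len(n)),
    "dist_mean", "dist_var", "dist_skew", "dist_kurt",
    "min_ref_dist", "n_private", "s_star",
    if (extra_count) "focal_derived")
}

# Which feature columns depend on the reference panel (dropped by the
# no-reference model). S* is reference-dependent because its candidate
# sites are conditioned on absence from the reference.
reference_feature_names <- function() c("min_ref_dist", "n_private", "s_star")

#' Full feature vector for one focal haplotype
#'
#' Assembles the per-window feature representation in a fixed, documented
#' order: the individual frequency spectrum (`n` entries), the sorted
#' distance vector (`n` entries), its four moments, the minimum reference
#' distance, the private-SNP count, S*, and (optionally) the total number
#' of derived alleles on the focal haplotype. At `n = 100` this yields 208
#' features (207 with `extra_count = FALSE`).
#'
#' @param window An `"archtrace_window"`.
#' @param extra_count Include the trailing derived-allele-count feature.
#' @param sstar Scoring constants for S*.
#' @return Named numeric vector.
#' @export
featurize <- function(window, extra_count = TRUE, sstar = sstar_params()) {
  df <- compute_distance_features(window)
  v <- c(compute_ifs(window), df$dist, df$moments,
         compute_min_ref_distance(window), count_private_snps(window),
         compute_s_star(window, sstar),
         if (extra_count) sum(window$target[window$focal, ]))
  names(v) <- feature_names(nrow(window$target), extra_count)
  v
}

# Vectorized feature computation for every target haplotype of one window.
# Tm/Rm are the target and reference 0/1 matrices restricted to the window,
# pos the matching bp positions. Returns an n x n_features matrix whose
# row j equals featurize() with focal = j.
window_feature_matrix <- function(Tm, Rm, pos, extra_count = TRUE,
                                  sstar = sstar_params()) {
  n <- nrow(Tm)
  if (nrow(Rm) == 0L)
    stop("reference panel is empty: reference-dependent features are undefined")
  nf <- 2L * n + 7L + as.integer(extra_count)
  out <- matrix(0, nrow = n, ncol = nf,
                dimnames = list(NULL, feature_names(n, extra_count)))
  S <- ncol(Tm)
  if (S > 0L) {
    ct <- colSums(Tm)
    cr <- colSums(Rm)
    # IFS for all focals at once: index (focal - 1) * n + target count
    w <- which(Tm == 1L, arr.ind = TRUE)
    out[, 1:n] <- matrix(
      tabulate((w[, 1] - 1L) * n + ct[w[, 2]], nbins = n * n),
      nrow = n, byrow = TRUE)
    # pairwise distances among targets
    rs <- rowSums(Tm)
    D2 <- outer(rs, rs, "+") - 2 * tcrossprod(Tm)
    D <- sqrt(pmax(D2, 0))
    out[, (n + 1):(2 * n)] <- t(apply(D, 1, sort))
    mom <- t(apply(D, 1, dist_moments))
    out[, 2 * n + 1:4] <- mom
    # minimum distance to the reference panel
    rr <- rowSums(Rm)
    DR2 <- outer(rs, rr, "+") - 2 * tcrossprod(Tm, Rm)
    out[, "min_ref_dist"] <- sqrt(pmax(apply(DR2, 1, min), 0))
    # private SNPs and S*
    priv <- which(cr == 0L)
    if (length(priv)) {
      Tp <- Tm[, priv, drop = FALSE]
      out[, "n_private"] <- rowSums(Tp)
      pp <- pos[priv]
      out[, "s_star"] <- vapply(
        seq_len(n), function(j) sstar_dp(pp[Tp[j, ] == 1L], sstar), 0)
    }
    if (extra_count) out[, "focal_derived"] <- rs
  }
  out
}

#' Featurize every target haplotype in every window of a region
#'
#' Tiles the region with sliding windows and computes the full feature
#' matrix for all (window, focal haplotype) pairs, along with the true
#' archaic ancestry fraction of each pair when tracts are available.
#'
#' @param region An `"archtrace_region"`.
#' @param window,step Window length and stride in bp.
#' @param extra_count,sstar Passed to the feature computation.
#' @return A list: `features` (one matrix per window, `n` x `n_features`),
#'   `windows` (two-column matrix of window intervals), `fractions`
#'   (`n_windows` x `n` true archaic fractions).
#' @export
featurize_region <- function(region, window = 50000, step = 10000,
                             extra_count = TRUE, sstar = sstar_params()) {
  wins <- tile_windows(region$length_bp, window, step)
  ti <- region$panels$target
  ri <- region$panels$ref
  feats <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    idx <- which(region$positions >= wins[k, 1] & region$positions < wins[k, 2])
    feats[[k]] <- window_feature_matrix(
      region$haps[ti, idx, drop = FALSE],
      region$haps[ri, idx, drop = FALSE],
      region$positions[idx], extra_count, sstar)
  }
  list(features = feats, windows = wins,
       fractions = ancestry_fraction_matrix(region, wins))
}
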