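#' Precision-recall and ROC confusion curves
#'
#' Enumerates every distinct score as a threshold `t` (ties grouped) and
#' tabulates `TP(t)`, `FP(t)`, `TN(t)`, `FN(t)` for the rule
#' "call positive iff score >= t", with the derived
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)` and
#' `FPR = FP / (FP + TN)`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary truth (0/1 or logical), aligned with `scores`.
#' @return A data frame of class `"archtrace_curve"` with columns
#'   `threshold`, `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `fpr`,
#'   ordered by decreasing threshold.
#' @export
confusion_curve <- function(scores, labels) {
  rc <- rank_counts(scores, labels)
  out <- data.frame(threshold = rc$threshold, tp = rc$tp, fp = rc$fp,
                    tn = rc$N - rc$fp, fn = rc$P - rc$tp)
  out$precision <- out$tp / (out$tp + out$fp)
  out$recall <- out$tp / rc$P
  out$fpr <- out$fp / rc$N
  class(out) <- c("archtrace_curve", "data.frame")
  attr(out, "P") <- rc$P
  attr(out, "N") <- rc$N
  out
}

# Shared curve core: cumulative TP/FP at each distinct score threshold
# (ties grouped), ordered by decreasing threshold.
rank_counts <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1L)
  N <- length(labels) - P
  if (P == 0L || N == 0L)
    stop("both classes must be present to build a curve")
  o <- order(scores, decreasing = TRUE)
  ss <- scores[o]
  tp <- cumsum(labels[o])
  last <- which(ss != c(ss[-1], NA)) # last index of each tied block
  if (!length(last) || last[length(last)] != length(ss))
    last <- c(last, length(ss))
  list(threshold = ss[last], tp = tp[last], fp = last - tp[last],
       P = P, N = N)
}

# Vectorized Davis-Goadrich area from rank counts: one interpolated point
# per unit of TP with FP linear in TP, trapezoid over recall.
aupr_from_counts <- function(rc) {
  P <- rc$P
  tp <- c(0, rc$tp)
  fp <- c(0, rc$fp)
  d <- diff(tp)
  seg <- which(d > 0)
  if (!length(seg)) return(0)
  reps <- d[seg]
  idx <- rep(seg, reps)
  x <- sequence(reps)
  tpa <- tp[idx]
  fpa <- fp[idx]
  slope <- (fp[idx + 1L] - fpa) / (tp[idx + 1L] - tpa)
  itp <- tpa + x
  p <- itp / (itp + fpa + slope * x)
  prev <- c(0, p[-length(p)])
  first <- x == 1L
  # precision at the segment start (after any vertical drop); a segment
  # starting at TP = 0 is anchored flat at its own interpolated precision
  prev[first] <- ifelse(tpa[first] == 0, p[first],
                        tpa[first] / (tpa[first] + fpa[first]))
  sum((p + prev) / 2) / P
}

auroc_from_counts <- function(rc) {
  x <- c(0, rc$fp / rc$N, 1)
  y <- c(0, rc$tp / rc$P, 1)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Area under the precision-recall curve (Davis-Goadrich)
#'
#' Interpolates between achievable PR points in true-positive space (one
#' interpolated point per unit of TP, with FP linear in TP, the
#' Davis-Goadrich scheme that avoids the incorrect linear interpolation of
#' precision) and integrates by trapezoid over recall. The curve is
#' anchored at recall 0 with the precision of its highest-threshold
#' achievable point.
#'
#' @param scores,labels As in [confusion_curve()], or pass a prebuilt
#'   curve via `curve`.
#' @param curve Optional `"archtrace_curve"`.
#' @return The area, in `[0, 1]`.
#' @export
aupr <- function(scores, labels, curve = NULL) {
  rc <- if (is.null(curve)) rank_counts(scores, labels) else
    list(threshold = curve$threshold, tp = curve$tp, fp = curve$fp,
         P = attr(curve, "P"), N = attr(curve, "N"))
  aupr_from_counts(rc)
}

#' Area under the ROC curve
#'
#' Trapezoidal area over the (FPR, TPR) step curve with (0,0) and (1,1)
#' endpoints; equals the Mann-Whitney probability of correct ranking with
#' ties counted half.
#'
#' @inheritParams aupr
#' @return The area, in `[0, 1]`.
#' @export
auroc <- function(scores, labels, curve = NULL) {
  rc <- if (is.null(curve)) rank_counts(scores, labels) else
    list(tp = curve$tp, fp = curve$fp,
         P = attr(curve, "P"), N = attr(curve, "N"))
  auroc_from_counts(rc)
}

#' Block jackknife standard error
#'
#' Delete-one-block jackknife for a statistic computed on blocked genomic
#' data (e.g. AUPR pooled over 1 Mb replicate regions):
#' `SE = sqrt((B - 1) / B * sum((theta_(b) - mean(theta_(b)))^2))`.
#'
#' @param statistic Function taking a list of blocks and returning a
#'   scalar (it sees the pooled data of the blocks it is given).
#' @param blocks List of at least two data blocks.
#' @return A list: `estimate` (all blocks), `se`, `loo` (the
#'   leave-one-out values).
#' @export
block_jackknife <- function(statistic, blocks) {
  B <- length(blocks)
  if (B < 2L) stop("block jackknife needs at least 2 blocks")
  est <- statistic(blocks)
  loo <- vapply(seq_len(B), function(b) statistic(blocks[-b]), 0)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, loo = loo)
}

#' Operating point at a target precision
#'
#' Smallest threshold whose precision reaches the target, with its recall;
#' the classifier's calling threshold for a chosen false discovery rate
#' (precision 0.8 corresponds to a 20% FDR).
#'
#' @param curve An `"archtrace_curve"`.
#' @param precision_target Required precision.
#' @return A list: `threshold`, `precision`, `recall`.
#' @export
operating_point <- function(curve, precision_target = 0.8) {
  ok <- which(curve$precision >= precision_target)
  if (!length(ok))
    stop(sprintf("precision %.3f unattainable (maximum %.3f)",
                 precision_target, max(curve$precision)))
  i <- ok[which.min(curve$threshold[ok])]
  list(threshold = curve$threshold[i], precision = curve$precision[i],
       recall = curve$recall[i])
}

#' Precision and recall at a fixed threshold
#'
#' @param scores,labels As in [confusion_curve()].
#' @param threshold Calling threshold (call iff `score >= threshold`).
#' @return A list: `precision`, `recall`, `called` (count),
#'   `called_fraction`.
#' @export
precision_recall_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  call <- scores >= threshold
  tp <- sum(call & labels == 1L)
  list(precision = if (any(call)) tp / sum(call) else NA_real_,
       recall = tp / sum(labels == 1L),
       called = sum(call), called_fraction = mean(call))
}

# Pool per-SNP scores and truths across scans into aligned vectors.
pool_scans <- function(scans) {
  list(scores = unlist(lapply(scans, function(s) as.vector(s$prob))),
       labels = unlist(lapply(scans, function(s) as.vector(s$truth))))
}

#' Per-SNP evaluation of a set of scans
#'
#' Pools the per-SNP probabilities and true archaic states of a list of
#' scans (one per replicate region), builds PR and ROC curves, and
#' attaches block-jackknife standard errors treating each region as one
#' block.
#'
#' @param scans List of `"archtrace_scan"` objects carrying `truth`.
#' @param se Compute delete-one-replicate jackknife standard errors (the
#'   expensive part for large scan sets; disable when only the point
#'   estimates are needed).
#' @return A list: `curve`, `aupr`, `auroc`, `aupr_se`, `auroc_se`,
#'   `n` (number of pooled (SNP, haplotype) pairs).
#' @export
evaluate_scans <- function(scans, se = TRUE) {
  pooled <- pool_scans(scans)
  curve <- confusion_curve(pooled$scores, pooled$labels)
  blocks <- lapply(scans, function(s)
    list(scores = as.vector(s$prob), labels = as.vector(s$truth)))
  # one sort per leave-one-out evaluation serves both areas
  areas <- function(bl) {
    rc <- rank_counts(unlist(lapply(bl, `[[`, "scores")),
                      unlist(lapply(bl, `[[`, "labels")))
    c(aupr_from_counts(rc), auroc_from_counts(rc))
  }
  B <- length(blocks)
  est <- areas(blocks)
  if (se && B >= 2L) {
    loo <- vapply(seq_len(B), function(b) areas(blocks[-b]), c(0, 0))
    se <- sqrt((B - 1) / B * rowSums((loo - rowMeans(loo))^2))
  } else se <- c(NA_real_, NA_real_)
  list(curve = curve, aupr = est[1], aupr_se = se[1],
       auroc = est[2], auroc_se = se[2],
       n = length(pooled$scores))
}

#' Haplotype-level evaluation
#'
#' Evaluates window-level scores against the 70/30 haplotype labeling:
#' haplotype-windows with true archaic fraction >= 0.7 are positives,
#' <= 0.3 negatives, and intermediate haplotypes are excluded.
#'
#' @param scores Per-haplotype-window scores.
#' @param fractions True archaic fractions, aligned with `scores`.
#' @param lower,upper Labeling thresholds.
#' @return A list: `curve`, `aupr`, `auroc`, `n_excluded`.
#' @export
haplotype_level_eval <- function(scores, fractions, lower = 0.3,
                                 upper = 0.7) {
  stopifnot(length(scores) == length(fractions))
  keep <- fractions >= upper | fractions <= lower
  if (!any(keep)) stop("no haplotypes outside the intermediate band")
  labels <- as.integer(fractions[keep] >= upper)
  curve <- confusion_curve(scores[keep], labels)
  list(curve = curve, aupr = aupr(curve = curve),
       auroc = auroc(curve = curve), n_excluded = sum(!keep))
}

#' Sliding-window S* baseline scan
#'
#' The reference-free S* comparison: within each 50 kb window, S* is
#' computed for every focal haplotype in its 100-haplotype target cohort,
#' and the window scores are averaged per SNP across overlapping windows,
#' mirroring the classifier's aggregation so both methods are evaluated
#' identically. By default the averaged raw scores are used directly as
#' the ranking statistic; `normalize` optionally converts window scores to
#' `[0, 1]` empirical-CDF ranks first, either within each window cohort
#' (`"window"`) or against the pooled window-score distribution of the
#' region (`"region"`). Rank conversion before averaging compresses the
#' informative upper tail and measurably weakens the baseline's
#' precision-recall behavior, so the raw variant — which reproduces the
#' published baseline operating characteristics — is the default.
#'
#' @param region An `"archtrace_region"`.
#' @param window,step Tiling in bp.
#' @param sstar S* scoring constants.
#' @param normalize Score conversion before per-SNP averaging: `"none"`
#'   (raw, default), `"window"` or `"region"`.
#' @return An `"archtrace_scan"` whose `prob` holds the per-SNP averaged
#'   S* ranking statistic and `window_probs` the per-window scores.
#' @export
sstar_scan <- function(region, window = 50000, step = 10000,
                       sstar = sstar_params(),
                       normalize = c("none", "window", "region")) {
  normalize <- match.arg(normalize)
  wins <- tile_windows(region$length_bp, window, step)
  ti <- region$panels$target
  ri <- region$panels$ref
  n <- length(ti)
  scores <- matrix(0, nrow = nrow(wins), ncol = n)
  for (k in seq_len(nrow(wins))) {
    idx <- which(region$positions >= wins[k, 1] & region$positions < wins[k, 2])
    Tm <- region$haps[ti, idx, drop = FALSE]
    Rm <- region$haps[ri, idx, drop = FALSE]
    pos <- region$positions[idx]
    priv <- colSums(Rm) == 0L
    s <- vapply(seq_len(n), function(j)
      sstar_dp(pos[priv & Tm[j, ] == 1L], sstar), 0)
    scores[k, ] <- if (normalize == "window") stats::ecdf(s)(s) else s
  }
  if (normalize == "region")
    scores <- matrix(stats::ecdf(scores)(scores), nrow(scores), ncol(scores))
  sp <- snp_probabilities(region$positions, wins, scores)
  structure(list(positions = region$positions, prob = sp$prob,
                 n_windows = sp$n_windows, window_probs = scores,
                 windows = wins,
                 fractions = ancestry_fraction_matrix(region, wins),
                 truth = snp_truth_matrix(region)),
            class = "archtrace_scan")
}

#' Demographic-perturbation experiment
#'
#' Simulates test data under a scenario with one parameter multiplied by
#' `factor`, applies the model trained on the unperturbed scenario, and
#' reports precision and recall at a fixed threshold as log10 fold changes
#' relative to the unperturbed baseline. Perturbations that produce an
#' invalid demography (e.g. an admixture time beyond the split time) raise
#' an error and should be recorded as skipped by the caller (see
#' [perturbation_grid()]).
#'
#' @param model An `"archtrace"` fit with a stored scenario.
#' @param param,factor Parameter name and multiplier for
#'   [perturb_demography()]; `factor = 1` reproduces the baseline.
#' @param baseline A list with `precision` and `recall` of the model on
#'   unperturbed test data at `threshold` (from [precision_recall_at()]).
#' @param threshold Fixed calling threshold (the precision-0.8 operating
#'   point by default).
#' @param n_rep,region_length,seed Test-set simulation settings.
#' @param rates Optional per-replicate `(mu, r)` matrix for the
#'   rate-heterogeneity experiment (used with `factor = 1`).
#' @return A list: `param`, `factor`, `precision`, `recall`,
#'   `log10_fold_precision`, `log10_fold_recall`.
#' @export
perturbation_experiment <- function(model, param, factor, baseline,
                                    threshold = 0.62, n_rep = 20,
                                    region_length = 1e6, n_target = 100,
                                    n_ref = 100, seed, rates = NULL) {
  if (missing(seed)) stop("a seed is required")
  scenario <- if (is.null(param)) model$scenario else
    perturb_demography(model$scenario, param, factor)
  scenario$length_bp <- as.integer(region_length)
  regions <- simulate_regions(scenario, n_rep = n_rep, n_target = n_target,
                              n_ref = n_ref, seed = seed, rates = rates)
  scans <- predict(model, regions)
  pooled <- pool_scans(scans)
  pr <- precision_recall_at(pooled$scores, pooled$labels, threshold)
  list(param = param, factor = factor,
       precision = pr$precision, recall = pr$recall,
       log10_fold_precision = log10(pr$precision / baseline$precision),
       log10_fold_recall = log10(pr$recall / baseline$recall))
}

#' Run the full perturbation grid
#'
#' Halves and doubles each demographic parameter in turn, skipping (and
#' recording) combinations that do not yield a sensible demography.
#'
#' @param model An `"archtrace"` fit.
#' @param baseline Baseline precision/recall list.
#' @param params Parameters to perturb.
#' @param factors Multipliers applied to each.
#' @inheritParams perturbation_experiment
#' @return A data frame with one row per (param, factor), including a
#'   `skipped` flag.
#' @export
perturbation_grid <- function(model, baseline, threshold = 0.62,
                              params = c("m", "N0", "N1", "N2", "Na",
                                         "T0", "Ts", "Ta"),
                              factors = c(0.5, 2), n_rep = 20,
                              region_length = 1e6, seed) {
  if (missing(seed)) stop("a seed is required")
  rows <- list()
  i <- 0L
  for (p in params) for (f in factors) {
    i <- i + 1L
    res <- tryCatch(
      perturbation_experiment(model, p, f, baseline, threshold = threshold,
                              n_rep = n_rep, region_length = region_length,
                              seed = child_seed(seed, i)),
      error = function(e) NULL)
    rows[[i]] <- if (is.null(res)) {
      data.frame(param = p, factor = f, precision = NA, recall = NA,
                 log10_fold_precision = NA, log10_fold_recall = NA,
                 skipped = TRUE)
    } else {
      data.frame(param = p, factor = f, precision = res$precision,
                 recall = res$recall,
                 log10_fold_precision = res$log10_fold_precision,
                 log10_fold_recall = res$log10_fold_recall,
                 skipped = FALSE)
    }
  }
  do.call(rbind, rows)
}
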