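test_that("confusion curves tabulate thresholds correctly", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.2)
  labels <- c(1, 1, 0, 0, 1)
  cv <- confusion_curve(scores, labels)
  expect_equal(cv$threshold, c(0.9, 0.8, 0.4, 0.2))
  expect_equal(cv$tp, c(1, 2, 2, 3))
  expect_equal(cv$fp, c(0, 1, 2, 2))
  expect_equal(cv$tp + cv$fp + cv$tn + cv$fn, rep(5, 4))
  expect_equal(cv$precision, cv$tp / (cv$tp + cv$fp))
  expect_equal(cv$recall, cv$tp / 3)
  expect_equal(cv$fpr, cv$fp / 2)
  # recall non-decreasing as the threshold drops, fpr too
  expect_true(all(diff(cv$recall) >= 0))
  expect_true(all(diff(cv$fpr) >= 0))
  expect_error(confusion_curve(scores, rep(1, 5)), "both classes")
})

test_that("perfect and random scores give the expected areas", {
  y <- rep(c(1, 0), each = 50)
  s <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(aupr(s, y), 1)
  expect_equal(auroc(s, y), 1)
  set.seed(31)
  y2 <- rep(0:1, 2000)
  s2 <- runif(4000)
  expect_lt(abs(auroc(s2, y2) - 0.5), 0.05)
})

test_that("AUPR equals the independent Davis-Goadrich oracle on toys", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2) # coarse scores force ties
    expect_equal(aupr(s, y), oracle_aupr_dg(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC equals the exhaustive Mann-Whitney count on toys", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 1)
    expect_equal(auroc(s, y), oracle_auroc_mw(s, y), tolerance = 1e-12)
  }
})

test_that("block jackknife matches closed forms", {
  # identical blocks: zero variance
  blocks <- rep(list(c(1, 2, 3)), 6)
  jk <- block_jackknife(function(bl) mean(unlist(bl)), blocks)
  expect_equal(jk$estimate, 2)
  expect_equal(jk$se, 0)
  # for the mean with equal-size blocks, SE = sd(block means) / sqrt(B)
  set.seed(34)
  blocks <- lapply(1:12, function(i) rnorm(10, mean = i %% 3))
  jk <- block_jackknife(function(bl) mean(unlist(bl)), blocks)
  bm <- vapply(blocks, mean, 0)
  expect_equal(jk$se, sd(bm) / sqrt(12), tolerance = 1e-12)
  # a sum statistic with one outlier block: hand-computed leave-one-out
  blocks <- list(1, 1, 1, 100)
  jk <- block_jackknife(function(bl) sum(unlist(bl)), blocks)
  expect_equal(jk$loo, c(102, 102, 102, 3))
  expect_equal(jk$se, sqrt(3 / 4 * sum((jk$loo - mean(jk$loo))^2)))
  expect_error(block_jackknife(mean, list(1)), "at least 2")
})

test_that("the operating point is the smallest threshold reaching the precision", {
  s <- c(0.95, 0.9, 0.7, 0.62, 0.5, 0.3, 0.1)
  y <- c(1, 1, 0, 1, 0, 0, 1)
  cv <- confusion_curve(s, y)
  op <- operating_point(cv, 0.75)
  # exhaustive scan oracle
  best <- Inf
  for (t in s) {
    prec <- sum(s >= t & y == 1) / sum(s >= t)
    if (prec >= 0.75 && t < best) best <- t
  }
  expect_equal(op$threshold, best)
  expect_equal(op$recall, sum(s >= best & y == 1) / sum(y))
  # unattainable target: the top-ranked example is a false positive
  cv_bad <- confusion_curve(c(0.9, 0.8), c(0, 1))
  expect_error(operating_point(cv_bad, 0.999), "unattainable")
  # perfect classifier: threshold at the top score block, full recall
  cv2 <- confusion_curve(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(operating_point(cv2, 1)$recall, 1)
})

test_that("precision and recall at a threshold match hand counts", {
  s <- c(0.9, 0.7, 0.6, 0.3)
  y <- c(1, 0, 1, 1)
  pr <- precision_recall_at(s, y, 0.6)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 2 / 3)
  expect_equal(pr$called_fraction, 3 / 4)
  expect_true(is.na(precision_recall_at(s, y, 2)$precision))
})

test_that("haplotype-level evaluation applies the 70/30 exclusion", {
  scores <- c(0.9, 0.8, 0.2, 0.1, 0.5)
  fractions <- c(0.95, 0.5, 0.1, 0.0, 0.72)
  ev <- haplotype_level_eval(scores, fractions)
  expect_equal(ev$n_excluded, 1L)
  expect_equal(ev$aupr, 1) # retained scores separate perfectly
  expect_equal(ev$auroc, 1)
  expect_error(haplotype_level_eval(c(0.5, 0.6), c(0.4, 0.5)),
               "intermediate")
})

test_that("S* scan scores and ranks match per-focal recomputation", {
  regs <- small_regions()
  reg <- regs[[2]]
  # raw window scores are the per-focal S* values
  w <- region_window(reg, 0, 50000, focal = 1)
  n <- length(reg$panels$target)
  s <- vapply(seq_len(n), function(j) {
    wj <- w
    wj$focal <- j
    compute_s_star(wj)
  }, 0)
  sc <- sstar_scan(reg, window = 50000, step = 50000)
  expect_equal(sc$window_probs[1, ], s)
  # within-cohort rank conversion is the empirical CDF, rank/n
  scr <- sstar_scan(reg, window = 50000, step = 50000,
                    normalize = "window")
  expect_true(all(scr$prob >= 0 & scr$prob <= 1))
  expect_equal(scr$window_probs[1, ], vapply(s, function(x) mean(s <= x), 0))
})

test_that("an unperturbed perturbation run has zero fold change", {
  sc <- demography(m = 0.2, length_bp = 50000L)
  fit0 <- structure(list(intercept = -2,
                         weights = c(n_private = 0.5, min_ref_dist = 0.3),
                         features_used = c("n_private", "min_ref_dist"),
                         n = 10, window = 50000, scenario = sc),
                    class = "archtrace")
  base_regions <- simulate_regions(sc, n_rep = 3, n_target = 10, n_ref = 10,
                                   seed = 5151)
  scans <- predict(fit0, base_regions, step = 50000)
  pooled <- archtrace:::pool_scans(scans)
  base <- precision_recall_at(pooled$scores, pooled$labels, 0.1)
  res <- perturbation_experiment(fit0, NULL, 1, base, threshold = 0.1,
                                 n_rep = 3, region_length = 50000,
                                 n_target = 10, n_ref = 10, seed = 5151)
  expect_equal(res$log10_fold_precision, 0)
  expect_equal(res$log10_fold_recall, 0)
})
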