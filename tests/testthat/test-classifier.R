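fake_features <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- c("dist_skew", "n_private", "min_ref_dist", "s_star",
                   "dist_kurt")[seq_len(p)]
  X
}

test_that("the 70/30 labeling rule is applied with inclusive bounds", {
  X <- fake_features(6, 2)
  ts <- build_training_set(X, c(0.71, 0.30, 0.50, 0.70, 0.0, 0.699))
  expect_equal(ts$labels, c(1L, 0L, 1L, 0L))
  expect_equal(ts$n_discarded, 2L)
  expect_error(build_training_set(X, rep(0.5, 6)), "no examples")
})

test_that("uninformative features recover the null model", {
  set.seed(10)
  n <- 4000
  X <- matrix(rnorm(2 * n), n, 2,
              dimnames = list(NULL, c("dist_skew", "n_private")))
  y <- rep(c(1, 0), c(n / 4, 3 * n / 4))
  ts <- build_training_set(X, y) # fractions 1 and 0 map to labels 1/0
  fit <- archtrace_fit(ts)
  expect_lt(abs(fit$intercept - log(1 / 3)), 0.15)
  expect_true(all(abs(fit$weights) < 0.1))
})

test_that("the logistic fit matches an independent IRLS oracle", {
  set.seed(11)
  n <- 200
  X <- fake_features(n, 5, seed = 11)
  eta <- -1 + X %*% c(1, -0.5, 0.25, 0, 0.75)
  y <- rbinom(n, 1, plogis(eta))
  ts <- build_training_set(X, y)
  fit <- archtrace_fit(ts)
  oracle <- oracle_irls_logit(X, y)
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
  # bit-identical across repeat fits on the same data
  expect_identical(coef(archtrace_fit(ts)), coef(fit))
})

test_that("probabilities follow the logistic closed form", {
  X <- fake_features(4, 3, seed = 12)
  model <- structure(list(intercept = 0,
                          weights = setNames(rep(0, 3), colnames(X)),
                          features_used = colnames(X)),
                     class = "archtrace")
  expect_equal(unname(predict(model, X)), rep(0.5, 4))
  model$intercept <- log(3)
  expect_equal(unname(predict(model, X)), rep(0.75, 4))
  model$weights[] <- c(0.5, -1, 2)
  expect_equal(unname(predict(model, X)),
               unname(plogis(log(3) + X %*% c(0.5, -1, 2))[, 1]))
  expect_error(predict(model, X[, 1:2]), "lacks model features")
})

test_that("standardized weights scale by the feature standard deviation", {
  model <- structure(list(weights = c(a = 2, b = 3, c = -4),
                          feature_sds = c(a = 0.5, b = 0, c = 2)),
                     class = "archtrace")
  expect_equal(standardized_weights(model), c(a = 1, b = 0, c = -8))
})

test_that("feature groups select the documented columns", {
  all <- feature_names(100)
  expect_equal(feature_group("full", all), all)
  expect_setdiff <- setdiff(all, feature_group("no_reference", all))
  expect_equal(sort(expect_setdiff),
               sort(c("min_ref_dist", "n_private", "s_star")))
  expect_equal(feature_group("skew_only", all), "dist_skew")
  expect_equal(feature_group("three_feat", all),
               c("dist_skew", "n_private", "min_ref_dist"))
  expect_error(feature_group("everything", all), "unknown feature group")
})

test_that("the full subset equals the plain fit and subsets drop columns", {
  set.seed(13)
  X <- fake_features(300, 5, seed = 13)
  y <- rbinom(300, 1, plogis(X[, 1] - X[, 2]))
  ts <- build_training_set(X, y)
  expect_identical(coef(archtrace_fit(ts, feature_set = "full")),
                   coef(archtrace_fit(ts)))
  sub <- archtrace_fit(ts, feature_set = "three_feat")
  expect_setequal(names(sub$weights),
                  c("dist_skew", "n_private", "min_ref_dist"))
})

test_that("predictions are invariant to affine feature rescaling", {
  set.seed(14)
  X <- fake_features(400, 3, seed = 14)
  y <- rbinom(400, 1, plogis(0.5 * X[, 1] - X[, 3]))
  ts <- build_training_set(X, y)
  f1 <- archtrace_fit(ts)
  X2 <- X
  X2[, 1] <- 10 * X[, 1] + 3
  X2[, 2] <- -0.2 * X[, 2]
  ts2 <- build_training_set(X2, y)
  f2 <- archtrace_fit(ts2)
  expect_equal(predict(f1, X), predict(f2, X2), tolerance = 1e-4)
})

test_that("constant features are dropped and degenerate fits are flagged", {
  set.seed(15)
  X <- fake_features(100, 3, seed = 15)
  X[, 2] <- 7 # constant
  y <- rbinom(100, 1, 0.3)
  ts <- build_training_set(X, y)
  expect_message(fit <- archtrace_fit(ts), "constant feature")
  expect_false("n_private" %in% names(fit$weights))
  # perfectly separable data still yields a finite, usable fit
  Xs <- matrix(c(seq(-1, -0.01, length.out = 50),
                 seq(0.01, 1, length.out = 50)), ncol = 1,
               dimnames = list(NULL, "dist_skew"))
  ys <- rep(0:1, each = 50)
  fs <- archtrace_fit(build_training_set(Xs, ys))
  p <- predict(fs, Xs)
  expect_true(all(is.finite(p)))
  expect_gt(mean(p[ys == 1]), mean(p[ys == 0]))
})

test_that("model text serialization round-trips", {
  set.seed(16)
  X <- fake_features(150, 4, seed = 16)
  y <- rbinom(150, 1, plogis(X[, 1]))
  fit <- archtrace_fit(build_training_set(X, y), scenario = demography(),
                       window = 50000, seed = 9)
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back$feature_sds, fit$feature_sds)
  expect_equal(back$scenario$m, 0.02)
  expect_equal(predict(back, X), predict(fit, X))
})
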