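#' Build a labeled training set from featurized windows
#'
#' Applies the 70/30 labeling rule: a haplotype-window is labeled archaic
#' (1) when at least 70% of its bases are truly archaic, non-archaic (0)
#' when at most 30% are, and discarded otherwise.
#'
#' @param features Numeric matrix, one row per (window, focal haplotype)
#'   example, columns named as in [feature_names()].
#' @param fractions True archaic ancestry fraction of each example.
#' @param lower,upper Labeling thresholds (inclusive bounds).
#' @return An `"archtrace_training"` object: `features`, `labels` (0/1),
#'   `fractions`, `n_discarded`.
#' @export
build_training_set <- function(features, fractions, lower = 0.3, upper = 0.7) {
  stopifnot(nrow(features) == length(fractions))
  lab <- ifelse(fractions >= upper, 1L, ifelse(fractions <= lower, 0L, NA))
  keep <- !is.na(lab)
  if (!any(keep)) stop("no examples retained by the labeling rule")
  structure(list(features = features[keep, , drop = FALSE],
                 labels = lab[keep], fractions = fractions[keep],
                 n_discarded = sum(!keep)),
            class = "archtrace_training")
}

#' @export
print.archtrace_training <- function(x, ...) {
  cat(sprintf(
    "Training set: %d examples (%d archaic, %d non-archaic), %d discarded, %d features\n",
    length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
    x$n_discarded, ncol(x$features)))
  invisible(x)
}

#' Named feature subsets
#'
#' Groups used in the ablation experiments. `"no_reference"` removes every
#' feature that depends on the reference panel (minimum reference distance,
#' private-SNP count and S*, whose candidate sites are conditioned on
#' absence from the reference).
#'
#' @param group One of `"full"`, `"no_reference"`, `"skew_only"`,
#'   `"private_only"`, `"min_dist_only"`, `"three_feat"`.
#' @param all_names Full canonical feature-name vector.
#' @return Character vector of retained feature names.
#' @export
feature_group <- function(group, all_names) {
  switch(group,
    full = all_names,
    no_reference = setdiff(all_names, reference_feature_names()),
    skew_only = "dist_skew",
    private_only = "n_private",
    min_dist_only = "min_ref_dist",
    three_feat = c("dist_skew", "n_private", "min_ref_dist"),
    stop("unknown feature group '", group, "'"))
}

# Maximum-likelihood binomial logit by iteratively reweighted least
# squares on the normal equations. Equivalent to glm.fit's MLE but an
# order of magnitude faster on tall design matrices (one BLAS crossprod
# per iteration instead of a LINPACK QR). Exactly collinear (aliased)
# columns are detected once via pivoted Cholesky of the Gram matrix and
# excluded from the solve; their coefficients are returned as NA, matching
# glm's convention.
irls_logit <- function(X1, y, maxit = 50, eps = 1e-10) {
  # weighted Gram matrix accumulated over row chunks, so peak memory stays
  # a small multiple of one chunk rather than a full weighted copy of X
  chunked_gram <- function(X, w, z) {
    p <- ncol(X)
    XtWX <- matrix(0, p, p)
    XtWz <- numeric(p)
    n <- nrow(X)
    step <- 65536L
    for (lo in seq(1L, n, by = step)) {
      hi <- min(lo + step - 1L, n)
      Xi <- X[lo:hi, , drop = FALSE]
      wi <- w[lo:hi]
      XtWX <- XtWX + crossprod(Xi * sqrt(wi))
      XtWz <- XtWz + drop(crossprod(Xi, wi * z[lo:hi]))
    }
    list(XtWX = XtWX, XtWz = XtWz)
  }
  G <- chunked_gram(X1, rep(1, nrow(X1)), numeric(nrow(X1)))$XtWX
  ch <- suppressWarnings(chol(G, pivot = TRUE))
  rank <- attr(ch, "rank")
  keep <- sort(attr(ch, "pivot")[seq_len(rank)])
  Xk <- if (rank < ncol(X1)) X1[, keep, drop = FALSE] else X1
  beta <- numeric(rank)
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xk %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    g <- chunked_gram(Xk, w, z)
    beta <- drop(solve(g$XtWX, g$XtWz))
    dev_new <- -2 * sum(stats::dbinom(y, 1, stats::plogis(drop(Xk %*% beta)),
                                      log = TRUE))
    if (is.finite(dev_new) && abs(dev_new - dev) / (abs(dev_new) + 0.1) < eps) {
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  out <- rep(NA_real_, ncol(X1))
  names(out) <- colnames(X1)
  out[keep] <- beta
  list(coefficients = out, converged = converged)
}

# Ridge-stabilized IRLS, used only as a flagged fallback when the
# unpenalized likelihood does not converge (e.g. complete separation).
# The penalty is scaled per column so it is invariant to feature units.
irls_ridge <- function(X1, y, lambda = 1e-8, maxit = 100, tol = 1e-10) {
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(lambda * pmax(colSums(X1^2), 1), p)
  pen[1, 1] <- 0 # never penalize the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X1, X1 * w) + pen, crossprod(X1, w * z))
    if (max(abs(new - beta)) < tol) {
      beta <- drop(new); break
    }
    beta <- drop(new)
  }
  beta
}

#' Fit the archaic-ancestry logistic regression
#'
#' Maximum-likelihood binomial logit fit of the label on the (raw,
#' unstandardized) features — the same MLE a
#' `glm(family = binomial("logit"))` call computes, obtained by an IRLS
#' solver that scales to millions of training rows. Constant
#' (zero-variance) features are dropped with a message and exactly
#' collinear ones are aliased to weight zero; if the likelihood fails to
#' converge (e.g. complete separation) a tiny-ridge fallback is used and
#' flagged. Feature means and standard deviations are stored for weight
#' standardization, which is a reporting device only.
#'
#' @param training An `"archtrace_training"` object.
#' @param feature_set Named subset from [feature_group()].
#' @param scenario Optional scenario the training data came from (stored
#'   as metadata and used as the default test scenario).
#' @param window Window length in bp the features were computed on.
#' @param seed Optional seed recorded in the metadata.
#' @return An object of class `"archtrace"`: `intercept`, `weights` (named,
#'   aligned to `features_used`), `feature_means`, `feature_sds`,
#'   `feature_set`, `n` (target panel size), `window`, `scenario`,
#'   `n_train`, `n_pos`, `n_discarded`, `separation`.
#' @seealso [archtrace()] for the one-call simulate-and-fit interface.
#' @export
archtrace_fit <- function(training, feature_set = "full", scenario = NULL,
                          window = 50000, seed = NULL) {
  stopifnot(inherits(training, "archtrace_training"))
  y <- training$labels
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot fit")
  keep <- feature_group(feature_set, colnames(training$features))
  X <- training$features[, keep, drop = FALSE]

  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    message("dropping ", sum(sds == 0), " constant feature(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  X1 <- cbind("(Intercept)" = 1, X)

  fit <- irls_logit(X1, y)
  beta <- fit$coefficients
  dropped <- is.na(beta)
  if (any(dropped)) {
    message("dropping ", sum(dropped), " collinear feature(s): ",
            paste(names(beta)[dropped], collapse = ", "))
    beta[dropped] <- 0
  }
  if (!fit$converged) {
    b <- irls_ridge(X1[, !dropped, drop = FALSE], y)
    beta[!dropped] <- b
  }

  structure(list(
    intercept = unname(beta[1]),
    weights = beta[-1],
    feature_means = colMeans(X),
    feature_sds = apply(X, 2, stats::sd),
    feature_set = feature_set,
    features_used = colnames(X),
    n = sum(startsWith(colnames(training$features), "ifs")),
    window = window,
    scenario = scenario,
    n_train = length(y), n_pos = sum(y == 1L),
    n_discarded = training$n_discarded,
    separation = !fit$converged,
    seed = seed), class = "archtrace")
}

#' Train an archaic local ancestry classifier by simulation
#'
#' The one-call interface: simulates `n_loci` replicate training regions
#' under `scenario`, featurizes every target haplotype over the full
#' region window, labels haplotypes by the 70/30 archaic-fraction rule,
#' and fits the logistic regression. The fitted object predicts archaic
#' ancestry probabilities for new windows or whole regions via
#' [predict.archtrace()].
#'
#' @param scenario An [demography()] scenario; its `length_bp` is the
#'   training window size.
#' @param n_loci Number of replicate training regions.
#' @param n_target,n_ref Haploid sample sizes (the feature layout is tied
#'   to `n_target`).
#' @param seed Integer seed (required).
#' @param feature_set Feature subset to train on, see [feature_group()].
#' @param extra_count Include the trailing derived-allele-count feature.
#' @param sstar S* scoring constants.
#' @return An object of class `"archtrace"`.
#' @examples
#' \donttest{
#' fit <- archtrace(demography(), n_loci = 50, seed = 7)
#' summary(fit)
#' }
#' @export
archtrace <- function(scenario = demography(), n_loci = 1000,
                      n_target = 100, n_ref = 100, seed,
                      feature_set = "full", extra_count = TRUE,
                      sstar = sstar_params()) {
  if (missing(seed)) stop("a seed is required: training must be reproducible")
  regions <- simulate_regions(scenario, n_rep = n_loci, n_target = n_target,
                              n_ref = n_ref, n_archaic = 1, seed = seed)
  training <- training_from_regions(regions, extra_count = extra_count,
                                    sstar = sstar)
  archtrace_fit(training, feature_set = feature_set, scenario = scenario,
                window = scenario$length_bp, seed = seed)
}

#' Featurize and label whole simulated regions
#'
#' Each region contributes one example per target haplotype, featurized
#' over the full region as a single window.
#'
#' @param regions List of `"archtrace_region"` objects.
#' @param extra_count,sstar Passed to the feature computation.
#' @return An `"archtrace_training"` object.
#' @export
training_from_regions <- function(regions, extra_count = TRUE,
                                  sstar = sstar_params()) {
  L <- regions[[1]]$length_bp
  parts <- lapply(regions, function(reg) {
    fr <- featurize_region(reg, window = L, step = L,
                           extra_count = extra_count, sstar = sstar)
    list(X = fr$features[[1]], f = fr$fractions[1, ])
  })
  build_training_set(do.call(rbind, lapply(parts, `[[`, "X")),
                     unlist(lapply(parts, `[[`, "f")))
}

#' @export
print.archtrace <- function(x, ...) {
  cat("Archaic local ancestry classifier (binomial logit)\n")
  cat(sprintf("  features: %s (%d used, target panel n = %d)\n",
              x$feature_set, length(x$weights), x$n))
  cat(sprintf("  training: %d examples (%.2f%% archaic), %d discarded\n",
              x$n_train, 100 * x$n_pos / x$n_train, x$n_discarded))
  if (x$separation) cat("  note: ridge fallback used (non-convergence)\n")
  invisible(x)
}

#' @export
coef.archtrace <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Standardized feature weights
#'
#' Each raw weight multiplied by its feature's training standard
#' deviation, putting weights on a comparable scale for interpretation
#' (constant features get weight 0). `summary()` and `plot()` report
#' `log10` of the absolute standardized weights.
#'
#' @param model An `"archtrace"` fit.
#' @return Named numeric vector.
#' @export
standardized_weights <- function(model) {
  model$weights * model$feature_sds
}

#' @export
summary.archtrace <- function(object, ...) {
  sw <- standardized_weights(object)
  ord <- order(abs(sw), decreasing = TRUE)
  out <- list(model = object,
              standardized = data.frame(
                feature = names(sw)[ord], weight = object$weights[ord],
                standardized_weight = sw[ord],
                log10_abs = log10(abs(sw[ord])), row.names = NULL))
  class(out) <- "summary.archtrace"
  out
}

#' @export
print.summary.archtrace <- function(x, ...) {
  print(x$model)
  cat("\nLargest standardized weights:\n")
  print(utils::head(x$standardized, 10), digits = 3)
  invisible(x)
}

#' @export
plot.archtrace <- function(x, ...) {
  sw <- standardized_weights(x)
  graphics::barplot(log10(pmax(abs(sw), 1e-12)),
                    names.arg = names(sw), las = 2, cex.names = 0.5,
                    ylab = "log10 |standardized weight|", ...)
  invisible(x)
}

#' Simulate fresh regions from a fitted model's scenario
#'
#' @param object An `"archtrace"` fit with a stored scenario.
#' @param nsim Number of regions.
#' @param seed Integer seed (required).
#' @param ... Passed to [simulate_regions()].
#' @export
simulate.archtrace <- function(object, nsim = 1, seed, ...) {
  if (is.null(object$scenario)) stop("model carries no scenario")
  simulate_regions(object$scenario, n_rep = nsim, seed = seed, ...)
}

#' Predict archaic ancestry probabilities
#'
#' For a feature matrix (rows = examples), returns the logistic
#' probabilities `plogis(intercept + X w)`. For a simulated region (or
#' list of regions), runs the sliding-window scan: featurizes every
#' (window, haplotype) pair, converts window scores to probabilities, and
#' averages them into per-SNP probabilities (see [snp_probabilities()]).
#'
#' @param object An `"archtrace"` fit.
#' @param newdata Feature matrix with named columns, an
#'   `"archtrace_region"`, or a list of regions.
#' @param window,step Scan tiling in bp (region input only).
#' @param ... Unused.
#' @return Probabilities for matrix input; an `"archtrace_scan"` (or list
#'   of scans) for region input, each holding `positions`, `prob`
#'   (SNP x haplotype means), `n_windows`, `window_probs`, `windows`,
#'   `fractions` (true per-window archaic fractions) and `truth` (true
#'   per-SNP archaic states).
#' @export
predict.archtrace <- function(object, newdata, window = NULL,
                              step = 10000, ...) {
  if (is.matrix(newdata) || is.data.frame(newdata)) {
    X <- as.matrix(newdata)
    miss <- setdiff(object$features_used, colnames(X))
    if (length(miss))
      stop("feature matrix lacks model features: ",
           paste(utils::head(miss, 5), collapse = ", "))
    X <- X[, object$features_used, drop = FALSE]
    return(stats::plogis(object$intercept + drop(X %*% object$weights)))
  }
  if (inherits(newdata, "archtrace_region"))
    return(scan_region(object, newdata, window = window, step = step))
  if (is.list(newdata))
    return(lapply(newdata, function(r)
      scan_region(object, r, window = window, step = step)))
  stop("newdata must be a feature matrix, a region, or a list of regions")
}

scan_region <- function(model, region, window = NULL, step = 10000,
                        features = NULL) {
  if (is.null(window)) window <- model$window
  fr <- if (is.null(features)) featurize_region(region, window = window,
                                                step = step) else features
  wp <- do.call(rbind, lapply(fr$features, function(X)
    predict.archtrace(model, X)))
  sp <- snp_probabilities(region$positions, fr$windows, wp)
  structure(list(positions = region$positions, prob = sp$prob,
                 n_windows = sp$n_windows, window_probs = wp,
                 windows = fr$windows, fractions = fr$fractions,
                 truth = snp_truth_matrix(region)),
            class = "archtrace_scan")
}

#' Score regions against precomputed window features
#'
#' Sliding-window featurization dominates scan cost; when several models
#' (e.g. ablations) are evaluated on the same test regions, featurize each
#' region once with [featurize_region()] and rescore with this function.
#'
#' @param model An `"archtrace"` fit.
#' @param regions List of `"archtrace_region"` objects.
#' @param features List of matching [featurize_region()] results.
#' @return A list of `"archtrace_scan"` objects.
#' @export
scan_with_features <- function(model, regions, features) {
  stopifnot(length(regions) == length(features))
  Map(function(r, f) scan_region(model, r, features = f), regions, features)
}

#' @export
print.archtrace_scan <- function(x, ...) {
  cat(sprintf(
    "Archaic ancestry scan: %d SNPs x %d haplotypes over %d windows; mean P(archaic) = %.3f\n",
    nrow(x$prob), ncol(x$prob), nrow(x$windows), mean(x$prob)))
  invisible(x)
}

#' Serialize a fitted model as versioned plain text
#'
#' @param model An `"archtrace"` fit.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  obj <- model
  obj$scenario <- if (is.null(model$scenario)) NULL else
    unclass(model$scenario)
  jsonlite::write_json(
    c(list(format = "archtrace-model", version = 1L), unclass(obj)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "archtrace-model"))
    stop("not an archtrace model file")
  obj$format <- NULL
  obj$version <- NULL
  for (f in c("weights", "feature_means", "feature_sds")) {
    v <- unlist(obj[[f]])
    names(v) <- obj$features_used
    obj[[f]] <- v
  }
  if (!is.null(obj$scenario)) {
    sc <- obj$scenario
    obj$scenario <- do.call(demography, sc[setdiff(names(sc), "structure")])
    if (length(sc$structure)) {
      st <- sc$structure
      if (is.data.frame(st))
        st <- lapply(seq_len(nrow(st)), function(i) as.list(st[i, ]))
      obj$scenario$structure <- st
    }
  }
  class(obj) <- "archtrace"
  obj
}
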