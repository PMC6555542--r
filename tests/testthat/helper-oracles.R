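# Independent brute-force oracles used to check the package's
# implementations on small inputs. These are deliberately naive and slow.

# Per-base archaic fraction: literally count archaic bases one by one.
oracle_ancestry_fraction <- function(tracts, start, end) {
  if (nrow(tracts) == 0L) return(0)
  bases <- start:(end - 1)
  hit <- rep(FALSE, length(bases))
  for (k in seq_len(nrow(tracts)))
    hit <- hit | (bases >= tracts[k, 1] & bases < tracts[k, 2])
  mean(hit)
}

# Raw moments computed straight from their definitions.
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  if (m2 == 0) c(m, 0, 0, 0) else c(m, m2, m3 / m2^1.5, m4 / m2^2)
}

# S* by exhaustive maximization over all subsets of candidate sites,
# scoring each ordered subset as the sum of its consecutive-pair scores.
oracle_sstar <- function(pos, bonus = 5000, min_bp = 10, penalty = -10000) {
  k <- length(pos)
  if (k < 2L) return(0)
  best <- 0
  for (mask in 1:(2^k - 1)) {
    sel <- pos[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    if (length(sel) < 2L) next
    d <- diff(sel)
    best <- max(best, sum(ifelse(d >= min_bp, d + bonus, penalty)))
  }
  best
}

# Plain Newton/IRLS logistic regression, coded independently of the
# package's fitting path.
oracle_irls_logit <- function(X, y, maxit = 200, tol = 1e-12) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(t(X1) %*% (X1 * W), t(X1) %*% (y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Davis-Goadrich AUPR by explicit point-list construction: PR points at
# every threshold, unit-TP interpolation loops, then trapezoid.
oracle_aupr_dg <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- list(c(tp = 0, fp = 0))
  for (t in th) {
    call <- scores >= t
    pts[[length(pts) + 1]] <- c(tp = sum(call & labels == 1),
                                fp = sum(call & labels == 0))
  }
  area <- 0
  prev_rec <- 0
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[[i]]
    b <- pts[[i + 1]]
    dtp <- unname(b["tp"] - a["tp"])
    if (dtp == 0) next # vertical precision drop: no recall gained
    s <- unname(b["fp"] - a["fp"]) / dtp
    # left edge of the segment: achievable precision at its start point
    # (a curve starting at tp = 0 is anchored flat at its first point)
    prev_prec <- if (a["tp"] > 0) unname(a["tp"] / (a["tp"] + a["fp"])) else NA
    for (x in 1:dtp) {
      tp <- unname(a["tp"]) + x
      fp <- unname(a["fp"]) + s * x
      rec <- tp / P
      prec <- tp / (tp + fp)
      if (is.na(prev_prec)) prev_prec <- prec
      area <- area + (rec - prev_rec) * (prec + prev_prec) / 2
      prev_rec <- rec
      prev_prec <- prec
    }
  }
  area
}

# AUROC as the exhaustive Mann-Whitney pair count (ties count half).
oracle_auroc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Hand-rolled region object for deterministic feature tests.
make_toy_region <- function(target, ref, archaic = NULL, positions,
                            length_bp, tracts = NULL) {
  n_t <- nrow(target)
  haps <- rbind(target, ref)
  panels <- list(target = seq_len(n_t),
                 ref = n_t + seq_len(nrow(ref)), archaic = integer(0))
  if (!is.null(archaic)) {
    panels$archaic <- nrow(haps) + seq_len(nrow(archaic))
    haps <- rbind(haps, archaic)
  }
  if (is.null(tracts))
    tracts <- rep(list(matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("start", "end")))), n_t)
  structure(list(positions = positions, haps = haps, panels = panels,
                 tracts = tracts, length_bp = as.integer(length_bp),
                 seed = 0L),
            class = "archtrace_region")
}

# Random 0/1 haplotype window for property-style tests.
random_window <- function(n = 8, n_ref = 6, S = 20, L = 10000, focal = 1,
                          p = 0.3) {
  pos <- sort(sample.int(L, S))
  haplotype_window(
    target = matrix(rbinom(n * S, 1, p), nrow = n),
    ref = matrix(rbinom(n_ref * S, 1, p), nrow = n_ref),
    positions = pos, focal = focal, start = 0, end = L)
}
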