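toy_window <- function() {
  # 4 target haplotypes x 5 sites; focal = h1 carries sites 1-4 with
  # target derived counts 1, 1, 2, 4; site 5 is not on the focal
  target <- rbind(
    h1 = c(1, 1, 1, 1, 0),
    h2 = c(0, 0, 1, 1, 1),
    h3 = c(0, 0, 0, 1, 0),
    h4 = c(0, 0, 0, 1, 0))
  ref <- rbind(
    r1 = c(0, 0, 1, 1, 0),
    r2 = c(0, 0, 0, 1, 0))
  haplotype_window(target, ref, positions = c(100, 5000, 9000, 12000, 20000),
                   focal = 1, start = 0, end = 50000)
}

test_that("the individual frequency spectrum counts focal alleles by target frequency", {
  expect_equal(compute_ifs(toy_window()), c(2, 1, 0, 1))
  # focal with no derived alleles
  w <- toy_window()
  w$target[1, ] <- 0
  expect_equal(compute_ifs(w), c(0, 0, 0, 0))
  # all focal sites singletons
  w2 <- haplotype_window(rbind(c(1, 1, 1), c(0, 0, 0)),
                         matrix(0, 1, 3), c(10, 20, 30), focal = 1)
  expect_equal(compute_ifs(w2), c(3, 0))
})

test_that("distance features match their definitions", {
  # identical haplotypes: all distances zero, degenerate moments
  w <- haplotype_window(matrix(1, 4, 3), matrix(0, 2, 3), c(1, 2, 3))
  df <- compute_distance_features(w)
  expect_equal(df$dist, rep(0, 4))
  expect_equal(unname(df$moments), c(0, 0, 0, 0))
  # 101 vs 110 differ at two sites
  w2 <- haplotype_window(rbind(c(1, 0, 1), c(1, 1, 0)),
                         matrix(0, 1, 3), c(1, 2, 3))
  expect_equal(compute_distance_features(w2)$dist, c(0, sqrt(2)))
  # random toys against per-definition recomputation
  set.seed(42)
  for (i in 1:15) {
    w <- random_window(n = 8, S = 20)
    df <- compute_distance_features(w)
    direct <- apply(w$target, 1, function(h)
      sqrt(sum((w$target[w$focal, ] - h)^2)))
    expect_equal(df$dist, sort(direct))
    expect_equal(unname(df$moments), oracle_moments(direct))
    expect_equal(df$dist[1], 0) # self-distance included
  }
})

test_that("minimum reference distance is an exhaustive minimum", {
  w <- toy_window()
  w$ref[1, ] <- w$target[1, ] # focal present verbatim in the reference
  expect_equal(compute_min_ref_distance(w), 0)
  # differing at exactly k sites
  w$ref[1, ] <- c(0, 1, 1, 1, 0) # one mismatch with focal
  w$ref[2, ] <- c(0, 0, 0, 0, 0)
  expect_equal(compute_min_ref_distance(w), 1)
  set.seed(43)
  for (i in 1:15) {
    w <- random_window()
    direct <- min(apply(w$ref, 1, function(h)
      sqrt(sum((w$target[w$focal, ] - h)^2))))
    expect_equal(compute_min_ref_distance(w), direct)
  }
  w$ref <- w$ref[0, , drop = FALSE]
  expect_error(compute_min_ref_distance(w), "empty")
})

test_that("private SNPs are focal derived alleles absent from the reference", {
  expect_equal(count_private_snps(toy_window()), 2) # sites 1 and 2
  w <- toy_window()
  w$ref[1, ] <- 1 # reference now shares everything
  expect_equal(count_private_snps(w), 0)
  set.seed(44)
  for (i in 1:15) {
    w <- random_window()
    direct <- sum(vapply(seq_along(w$positions), function(s)
      w$target[w$focal, s] == 1 && sum(w$ref[, s]) == 0, TRUE))
    expect_equal(count_private_snps(w), direct)
  }
})

test_that("S* follows the chain dynamic program", {
  # no candidates
  w <- toy_window()
  w$target[1, ] <- 0
  expect_equal(compute_s_star(w), 0)
  # two candidates 20 kb apart: bp + 5000 bonus
  w2 <- haplotype_window(rbind(c(1, 1), c(0, 0)), matrix(0, 1, 2),
                         positions = c(10000, 30000))
  expect_equal(compute_s_star(w2), 25000)
  # single candidate scores zero
  w3 <- haplotype_window(matrix(1, 1, 1), matrix(0, 1, 1), positions = 500)
  expect_equal(compute_s_star(w3), 0)
  # close spacing is penalized, not rewarded
  w4 <- haplotype_window(rbind(c(1, 1)), matrix(0, 1, 2),
                         positions = c(100, 105))
  expect_equal(compute_s_star(w4), 0) # max(0, -10000)
})

test_that("the S* dynamic program equals the exhaustive subset oracle", {
  set.seed(45)
  for (i in 1:25) {
    k <- sample(2:12, 1)
    pos <- sort(sample.int(60000, k))
    expect_equal(compute_s_star(
      haplotype_window(matrix(1, 1, k), matrix(0, 1, k), pos)),
      oracle_sstar(pos))
  }
  # dense clusters exercise the penalty branch
  for (i in 1:10) {
    k <- sample(2:10, 1)
    pos <- sort(sample.int(100, k))
    expect_equal(compute_s_star(
      haplotype_window(matrix(1, 1, k), matrix(0, 1, k), pos)),
      oracle_sstar(pos))
  }
})

test_that("featurize assembles the documented layout", {
  w <- toy_window()
  v <- featurize(w)
  expect_length(v, 2 * 4 + 8)
  expect_named(v, feature_names(4, extra_count = TRUE))
  expect_length(featurize(w, extra_count = FALSE), 2 * 4 + 7)
  expect_equal(unname(v["n_private"]), 2)
  expect_equal(unname(v["focal_derived"]), 4)
  expect_equal(sum(v[1:4]), sum(w$target[1, ])) # IFS sums to focal count
  expect_identical(featurize(w), featurize(w)) # deterministic
  # empty window: all-zero features
  we <- haplotype_window(matrix(0, 3, 0), matrix(0, 2, 0), numeric(0))
  expect_true(all(featurize(we) == 0))
})

test_that("the batch feature matrix agrees with per-focal featurize", {
  set.seed(46)
  w <- random_window(n = 6, n_ref = 5, S = 25)
  batch <- archtrace:::window_feature_matrix(w$target, w$ref, w$positions)
  for (j in 1:6) {
    wj <- w
    wj$focal <- j
    expect_equal(unname(batch[j, ]), unname(featurize(wj)))
  }
})

test_that("features are invariant to non-focal haplotype order", {
  set.seed(47)
  w <- random_window(n = 8, S = 30, focal = 3)
  v <- featurize(w)
  perm <- c(3, sample(setdiff(1:8, 3)))
  w2 <- w
  w2$target <- w$target[perm, ]
  w2$focal <- 1L
  expect_equal(unname(featurize(w2)), unname(v))
  # reference order never matters either
  w3 <- w
  w3$ref <- w$ref[sample(nrow(w$ref)), ]
  expect_equal(featurize(w3), v)
})

test_that("removing the archaic haplotype changes no feature", {
  regs <- small_regions()
  reg <- regs[[1]]
  with_arch <- featurize_region(reg, window = 50000, step = 50000)
  no_arch <- reg
  keep <- c(reg$panels$target, reg$panels$ref)
  # drop archaic rows and any site segregating only on them
  seg <- colSums(reg$haps[keep, , drop = FALSE]) > 0
  no_arch$haps <- reg$haps[keep, seg, drop = FALSE]
  no_arch$positions <- reg$positions[seg]
  no_arch$panels$archaic <- integer(0)
  without <- featurize_region(no_arch, window = 50000, step = 50000)
  expect_equal(with_arch$features, without$features)
})

test_that("a new focal-only derived allele increments ifs[1] and the private count", {
  set.seed(48)
  w <- random_window(n = 6, n_ref = 5, S = 20)
  v0 <- featurize(w)
  # insert a site carried only by the focal haplotype
  newpos <- 4321.5
  at <- findInterval(newpos, w$positions)
  ins <- function(M, col) cbind(M[, seq_len(at), drop = FALSE], col,
                                M[, -seq_len(at), drop = FALSE])
  w$target <- ins(w$target, as.integer(seq_len(nrow(w$target)) == w$focal))
  w$ref <- ins(w$ref, 0L)
  w$positions <- c(w$positions[seq_len(at)], newpos, w$positions[-seq_len(at)])
  v1 <- featurize(w)
  expect_equal(unname(v1["ifs1"] - v0["ifs1"]), 1)
  expect_equal(unname(v1["n_private"] - v0["n_private"]), 1)
})
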