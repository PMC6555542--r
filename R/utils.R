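# Internal helpers shared across modules.

# Evaluate an expression under a local RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed below 2^31 from (seed, index), so independent
# simulation batches inside one pipeline never share streams.
child_seed <- function(seed, index) {
  (as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629 + 1
}

# First four raw-population moments of a numeric vector: mean, variance
# (m2), skew m3/m2^1.5 and (non-excess) kurtosis m4/m2^2. Degenerate
# zero-variance input yields skew = kurtosis = 0.
dist_moments <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    c(mean = m, var = m2, skew = mean(d^3) / m2^1.5, kurt = mean(d^4) / m2^2)
  } else {
    c(mean = m, var = 0, skew = 0, kurt = 0)
  }
}

python_binary <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("no 'python' interpreter on PATH; the simulation engine needs ",
         "Python with msprime and numpy")
  p
}

driver_path <- function() {
  p <- system.file("python", "msprime_driver.py", package = "archtrace")
  if (!nzchar(p)) stop("msprime driver script not found in the installed package")
  p
}
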