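#' Demographic scenario for training simulations
#'
#' Builds the split/admixture demography used to generate labeled training
#' and test data: an ancestral population of diploid size `N0` splits `T0`
#' generations ago into an archaic population (`Na`) and a modern lineage;
#' the modern lineage splits `Ts` generations ago into a reference (`N1`)
#' and a target (`N2`) population; at `Ta` generations ago the archaic
#' population contributes a single-generation admixture pulse of proportion
#' `m` into the target. Defaults correspond to a Neanderthal-like history
#' (all sizes 10,000; 2% admixture 2,000 generations ago).
#'
#' @param N0,N1,N2,Na Diploid effective sizes of the ancestral, reference,
#'   target and archaic populations.
#' @param m Admixture proportion in `[0, 1]`.
#' @param T0,Ts,Ta Archaic split, reference-target split, and admixture
#'   times in generations before present; must satisfy `T0 > Ts > Ta > 0`.
#' @param mu,r Per-base-pair, per-generation mutation and recombination
#'   rates.
#' @param length_bp Length of each simulated region in base pairs.
#' @param structure Optional list of population sub-structure events, each a
#'   list with elements `population` (`"target"` or `"ancestral"`),
#'   `split_time`, `rejoin_time` (generations; `split_time > rejoin_time`)
#'   and `fraction` (lineage-sampling probability at the split). The
#'   structured deme is fully isolated between the two times.
#' @return An object of class `"archtrace_demography"`.
#' @seealso [structured_demography()], [perturb_demography()],
#'   [simulate_regions()]
#' @examples
#' demography()
#' demography(m = 0.05, Ta = 1500)
#' @export
demography <- function(N0 = 10000, N1 = 10000, N2 = 10000, Na = 10000,
                       m = 0.02, T0 = 12000, Ts = 2500, Ta = 2000,
                       mu = 1.25e-8, r = 1e-8, length_bp = 50000,
                       structure = NULL) {
  sc <- list(N0 = N0, N1 = N1, N2 = N2, Na = Na, m = m,
             T0 = T0, Ts = Ts, Ta = Ta, mu = mu, r = r,
             length_bp = as.integer(length_bp), structure = structure)
  class(sc) <- "archtrace_demography"
  validate_demography(sc)
  sc
}

validate_demography <- function(sc) {
  stopifnot(inherits(sc, "archtrace_demography"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("N0", "N1", "N2", "Na", "m", "T0", "Ts", "Ta", "mu", "r")) {
    if (!num1(sc[[f]])) stop("demography field '", f, "' must be a finite number")
  }
  if (any(c(sc$N0, sc$N1, sc$N2, sc$Na) <= 0))
    stop("population sizes must be positive")
  if (sc$m < 0 || sc$m > 1) stop("admixture proportion m must lie in [0, 1]")
  if (!(sc$T0 > sc$Ts && sc$Ts > sc$Ta && sc$Ta > 0))
    stop("event times must satisfy T0 > Ts > Ta > 0 (got T0=", sc$T0,
         ", Ts=", sc$Ts, ", Ta=", sc$Ta, ")")
  if (sc$mu < 0 || sc$r < 0) stop("mutation and recombination rates must be >= 0")
  if (sc$length_bp < 1) stop("length_bp must be >= 1")
  for (ev in sc$structure) {
    if (!ev$population %in% c("target", "ancestral"))
      stop("structure events must act on 'target' or 'ancestral'")
    if (!(ev$split_time > ev$rejoin_time && ev$rejoin_time > 0))
      stop("structure events need split_time > rejoin_time > 0")
    if (ev$fraction <= 0 || ev$fraction >= 1)
      stop("structure fraction must lie in (0, 1)")
    if (ev$population == "ancestral" && ev$rejoin_time <= sc$Ts)
      stop("ancestral-structure rejoin must predate the target-reference split")
  }
  invisible(sc)
}

#' @export
print.archtrace_demography <- function(x, ...) {
  cat("Split/admixture demography (diploid sizes, generations):\n")
  cat(sprintf("  sizes     N0=%g N1=%g N2=%g Na=%g\n", x$N0, x$N1, x$N2, x$Na))
  cat(sprintf("  times     T0=%g Ts=%g Ta=%g   admixture m=%g\n",
              x$T0, x$Ts, x$Ta, x$m))
  cat(sprintf("  rates     mu=%g r=%g per bp per generation\n", x$mu, x$r))
  cat(sprintf("  region    %d bp\n", x$length_bp))
  for (ev in x$structure)
    cat(sprintf("  structure %s deme: split %g, rejoin %g, fraction %g\n",
                ev$population, ev$split_time, ev$rejoin_time, ev$fraction))
  invisible(x)
}

#' Confounding population-structure scenarios
#'
#' Scenarios used to test whether substructure, rather than archaic
#' admixture, can trigger archaic calls. Both set the admixture proportion
#' to zero so that any positive call is a false positive. `"recent"`: 25%
#' of the target population separates immediately after the
#' target-reference split (2,499 generations ago) and rejoins one
#' generation before the would-be admixture pulse (2,001 generations ago).
#' `"ancestral"`: 25% of the ancestral population separates 12,000
#' generations ago and rejoins just before the target-reference split
#' (2,600 generations ago).
#'
#' @param kind `"recent"` or `"ancestral"`.
#' @return An `"archtrace_demography"` with one structure event and `m = 0`.
#' @examples
#' structured_demography("recent")
#' @export
structured_demography <- function(kind = c("recent", "ancestral")) {
  kind <- match.arg(kind)
  ev <- switch(kind,
    recent = list(population = "target", split_time = 2499,
                  rejoin_time = 2001, fraction = 0.25),
    ancestral = list(population = "ancestral", split_time = 12000,
                     rejoin_time = 2600, fraction = 0.25))
  demography(m = 0, structure = list(ev))
}

#' Perturb one demographic parameter
#'
#' Multiplies a single parameter of a scenario by `factor`, as used in the
#' robustness experiments (parameters halved or doubled one at a time).
#' Combinations that break the event-time ordering (for example doubling
#' the admixture time past the split time) are not sensible demographies
#' and raise an error, which the perturbation harness records as a skip.
#'
#' @param scenario An `"archtrace_demography"`.
#' @param param One of `"m"`, `"N0"`, `"N1"`, `"N2"`, `"Na"`, `"T0"`,
#'   `"Ts"`, `"Ta"`, `"mu"`, `"r"`.
#' @param factor Positive multiplier (0.5 and 2 in the standard grid).
#' @return A validated perturbed scenario.
#' @export
perturb_demography <- function(scenario, param, factor) {
  validate_demography(scenario)
  ok <- c("m", "N0", "N1", "N2", "Na", "T0", "Ts", "Ta", "mu", "r")
  if (!param %in% ok) stop("unknown parameter '", param, "'")
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  scenario[[param]] <- scenario[[param]] * factor
  if (param == "m") scenario$m <- min(scenario$m, 1)
  validate_demography(scenario)
  scenario
}

#' Draw a joint (mutation, recombination) rate pair
#'
#' Samples one `(mu, r)` pair uniformly from a user-supplied empirical list,
#' preserving the joint pairing (rates are never drawn independently). Used
#' to emulate rate heterogeneity along a real genome when simulating test
#' data.
#'
#' @param pairs A two-column matrix or data frame (`mu`, `r`), one row per
#'   empirical pair.
#' @param n Number of draws.
#' @param seed Integer seed (required; draws must be reproducible).
#' @return An `n` x 2 matrix with columns `mu` and `r`.
#' @export
draw_rate_pairs <- function(pairs, n = 1, seed) {
  if (missing(seed)) stop("a seed is required for reproducible rate draws")
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("the list of (mu, r) pairs must be non-empty")
  if (ncol(pairs) != 2L) stop("pairs must have two columns: mu and r")
  idx <- with_seed(seed, sample.int(nrow(pairs), n, replace = TRUE))
  out <- pairs[idx, , drop = FALSE]
  colnames(out) <- c("mu", "r")
  out
}
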