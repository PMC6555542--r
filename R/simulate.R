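#' Simulate haplotype regions with archaic ancestry tracts
#'
#' Runs the bundled coalescent engine (msprime, via Python) under a
#' split/admixture scenario and returns, per replicate, the sampled
#' haplotypes together with the exact base-pair intervals of archaic
#' ancestry on every target haplotype. Haplotypes are sampled at the
#' present: `n_target` from the target population, `n_ref` from the
#' reference, and `n_archaic` from the archaic population (the archaic
#' haplotype is carried along for match diagnostics but is never used as a
#' classification feature). Mutations follow an infinite-sites model mapped
#' to a discrete bp grid; all variants are biallelic with known ancestral
#' state (0 = ancestral, 1 = derived).
#'
#' @param scenario An [demography()] scenario.
#' @param n_rep Number of independent replicate regions.
#' @param n_target,n_ref,n_archaic Haploid sample sizes.
#' @param seed Integer seed (required; per-replicate seeds are derived from
#'   it deterministically).
#' @param tracts_only If `TRUE`, skip mutation and genotype output and
#'   return only the tract table (much faster; used for labeling-scale
#'   runs).
#' @param rates Optional `n_rep` x 2 matrix of per-replicate `(mu, r)`
#'   pairs, e.g. from [draw_rate_pairs()], overriding the scenario rates.
#' @return For `tracts_only = TRUE`, a data frame of tracts (`rep`, `hap`,
#'   `start`, `end`) with attribute `n_rep`. Otherwise a list of
#'   `"archtrace_region"` objects, each containing `positions`, `haps`
#'   (haplotype x variant 0/1 matrix, rows ordered target, reference,
#'   archaic), `panels` (row-index sets), `tracts` (per target haplotype, a
#'   two-column matrix of half-open bp intervals), `length_bp` and `seed`.
#' @examples
#' \donttest{
#' reg <- simulate_region(demography(), seed = 1)
#' reg
#' }
#' @export
simulate_regions <- function(scenario, n_rep, n_target = 100, n_ref = 100,
                             n_archaic = 1, seed, tracts_only = FALSE,
                             rates = NULL) {
  validate_demography(scenario)
  if (missing(seed)) stop("a seed is required: simulations must be reproducible")
  stopifnot(n_rep >= 1, n_target >= 0, n_ref >= 0, n_archaic >= 0)

  dir <- tempfile("archtrace_sim_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- list(
    scenario = scenario[setdiff(names(scenario), "structure")],
    n_target = n_target, n_ref = n_ref, n_archaic = n_archaic,
    n_rep = n_rep, seed = as.integer(seed), tracts_only = tracts_only,
    out_ms = file.path(dir, "regions.ms"),
    out_tracts = file.path(dir, "tracts.tsv"))
  cfg$scenario$structure <- if (is.null(scenario$structure)) list() else
    scenario$structure
  if (!is.null(rates)) {
    rates <- as.matrix(rates)
    stopifnot(nrow(rates) == n_rep, ncol(rates) == 2)
    cfg$mu_list <- rates[, 1]
    cfg$r_list <- rates[, 2]
  }
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)

  out <- suppressWarnings(
    system2(python_binary(), c(driver_path(), cfg_path),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if ((!is.null(status) && status != 0) || !any(grepl("^OK ", out)))
    stop("coalescent driver failed:\n", paste(out, collapse = "\n"))

  tracts <- read_tracts(cfg$out_tracts)
  if (tracts_only) {
    attr(tracts, "n_rep") <- n_rep
    return(tracts)
  }

  reps <- read_ms(cfg$out_ms, scenario$length_bp)
  panels <- list(
    target = seq_len(n_target),
    ref = if (n_ref > 0) n_target + seq_len(n_ref) else integer(0),
    archaic = if (n_archaic > 0) n_target + n_ref + seq_len(n_archaic)
              else integer(0))
  lapply(seq_len(n_rep), function(k) {
    tr <- tracts[tracts$rep == k, , drop = FALSE]
    per_hap <- lapply(seq_len(n_target), function(h) {
      rows <- tr[tr$hap == h, c("start", "end"), drop = FALSE]
      as.matrix(rows)
    })
    structure(list(positions = reps[[k]]$positions, haps = reps[[k]]$haps,
                   panels = panels, tracts = per_hap,
                   length_bp = scenario$length_bp,
                   seed = as.integer(seed), rep = k),
              class = "archtrace_region")
  })
}

#' @rdname simulate_regions
#' @export
simulate_region <- function(scenario, n_target = 100, n_ref = 100,
                            n_archaic = 1, seed) {
  simulate_regions(scenario, n_rep = 1, n_target = n_target, n_ref = n_ref,
                   n_archaic = n_archaic, seed = seed)[[1]]
}

#' @export
print.archtrace_region <- function(x, ...) {
  n_tr <- sum(vapply(x$tracts, nrow, 1L))
  cat(sprintf(
    "Simulated region: %d bp, %d variants, %d/%d/%d target/ref/archaic haplotypes, %d archaic tracts\n",
    x$length_bp, length(x$positions), length(x$panels$target),
    length(x$panels$ref), length(x$panels$archaic), n_tr))
  invisible(x)
}

#' Archaic ancestry fraction of a haplotype over an interval
#'
#' Fraction of bases in `[start, end)` of one target haplotype that descend
#' from the archaic population, computed as total tract overlap divided by
#' interval length. This is the quantity thresholded at 70%/30% to label
#' training haplotypes.
#'
#' @param region An `"archtrace_region"`.
#' @param focal Target-panel haplotype index (1-based).
#' @param start,end Half-open interval in bp within the region.
#' @return A fraction in `[0, 1]`.
#' @export
ancestry_fraction <- function(region, focal, start = 0,
                              end = region$length_bp) {
  if (!focal %in% region$panels$target)
    stop("focal must be a target-panel haplotype")
  if (start < 0 || end > region$length_bp || end <= start)
    stop("interval must be non-empty and within region bounds")
  tr <- region$tracts[[focal]]
  if (is.null(tr) || nrow(tr) == 0L) return(0)
  ov <- pmin(tr[, "end"], end) - pmax(tr[, "start"], start)
  sum(ov[ov > 0]) / (end - start)
}

# Ancestry fractions for every target haplotype over each interval of a
# tiling; returns a (n_windows x n_target) matrix.
ancestry_fraction_matrix <- function(region, windows) {
  n <- length(region$panels$target)
  out <- matrix(0, nrow = nrow(windows), ncol = n)
  for (h in seq_len(n)) {
    tr <- region$tracts[[h]]
    if (is.null(tr) || nrow(tr) == 0L) next
    for (w in seq_len(nrow(windows))) {
      ov <- pmin(tr[, "end"], windows[w, 2]) - pmax(tr[, "start"], windows[w, 1])
      out[w, h] <- sum(ov[ov > 0]) / (windows[w, 2] - windows[w, 1])
    }
  }
  out
}

# True archaic state (0/1) of every (variant, target haplotype) pair: a SNP
# is archaic on a haplotype iff its position falls inside one of that
# haplotype's tracts.
snp_truth_matrix <- function(region) {
  n <- length(region$panels$target)
  S <- length(region$positions)
  out <- matrix(0L, nrow = S, ncol = n)
  for (h in seq_len(n)) {
    tr <- region$tracts[[h]]
    if (is.null(tr) || nrow(tr) == 0L) next
    for (k in seq_len(nrow(tr))) {
      inside <- region$positions >= tr[k, "start"] & region$positions < tr[k, "end"]
      out[inside, h] <- 1L
    }
  }
  out
}
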