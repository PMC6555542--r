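#' Read phased haplotypes from a VCF
#'
#' Empirical-mode input: loads phased, biallelic SNVs from a VCF (via the
#' vcfR package), splits each diploid sample into two haplotype rows, and
#' polarizes alleles to ancestral/derived using the `AA` INFO tag. Sites
#' without a usable ancestral allele (missing, or matching neither REF nor
#' ALT) are dropped with a message, as are unphased or multiallelic
#' records.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A list: `positions` (bp), `haps` (haplotype x variant 0/1
#'   matrix, 1 = derived; rows named `<sample>_1`, `<sample>_2`) and
#'   `n_dropped`.
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  aa <- toupper(sub("\\|.*", "", vcfR::extract.info(v, "AA")))
  polarized <- !is.na(aa) & (aa == toupper(fix[, "REF"]) |
                               aa == toupper(fix[, "ALT"]))
  phased <- apply(gt, 1, function(x) all(grepl("\\|", x)))
  keep <- biallelic & polarized & phased
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropping ", n_dropped,
            " unpolarized, unphased or multiallelic site(s)")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  aa <- aa[keep]
  a1 <- substr(gt, 1, 1) == "1"
  a2 <- substr(gt, 3, 3) == "1"
  haps <- t(cbind(a1, a2)) * 1L
  # a "1" genotype allele is ALT; flip where ALT is the ancestral allele
  flip <- aa == toupper(fix[, "ALT"])
  haps[, flip] <- 1L - haps[, flip]
  rownames(haps) <- paste0(rep(colnames(gt), 2), "_",
                           rep(1:2, each = ncol(gt)))
  list(positions = as.integer(fix[, "POS"]), haps = haps,
       n_dropped = n_dropped)
}

#' Assemble an empirical region from target and reference haplotypes
#'
#' Builds the region container used by the scan functions from
#' already-polarized haplotype sets (e.g. two [read_phased_vcf()] results
#' joined on shared positions). Empirical regions carry no ancestry
#' tracts.
#'
#' @param target,ref Haplotype 0/1 matrices over the same variant set.
#' @param positions Variant positions in bp.
#' @param length_bp Region length in bp.
#' @return An `"archtrace_region"` with empty tract and archaic slots.
#' @export
empirical_region <- function(target, ref, positions, length_bp) {
  target <- as.matrix(target)
  ref <- as.matrix(ref)
  stopifnot(ncol(target) == length(positions), ncol(ref) == length(positions))
  n_t <- nrow(target)
  structure(list(
    positions = as.numeric(positions), haps = rbind(target, ref),
    panels = list(target = seq_len(n_t), ref = n_t + seq_len(nrow(ref)),
                  archaic = integer(0)),
    tracts = rep(list(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("start", "end")))), n_t),
    length_bp = as.integer(length_bp), seed = NA_integer_),
    class = "archtrace_region")
}

#' Write per-haplotype probability tracks as BED-like text
#'
#' One row per (window, haplotype): `chrom`, `start`, `end`, `haplotype`,
#' `probability`. Suitable for intersection with accessibility masks using
#' standard BED tooling.
#'
#' @param scan An `"archtrace_scan"`.
#' @param path Output path.
#' @param chrom Chromosome label for the first column.
#' @export
write_scan_bed <- function(scan, path, chrom = "chr1") {
  wp <- scan$window_probs
  df <- data.frame(
    chrom = chrom,
    start = rep(scan$windows[, 1], ncol(wp)),
    end = rep(scan$windows[, 2], ncol(wp)),
    haplotype = rep(seq_len(ncol(wp)), each = nrow(wp)),
    probability = as.vector(wp))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
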