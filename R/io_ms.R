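#' Read ms-style haplotype output
#'
#' Parses the classic ms text format (`//` replicate separator, `segsites:`,
#' `positions:` as fractions of the region length, one 0/1 string per
#' haplotype) into binary haplotype matrices with integer base-pair
#' positions. This is the exchange format written by the bundled coalescent
#' driver and accepted back by the feature-extraction functions.
#'
#' @param path Path to the ms-style file.
#' @param length_bp Region length used to convert fractional positions to
#'   integer base pairs.
#' @return A list with one element per replicate, each a list of
#'   `positions` (integer bp, strictly increasing) and `haps`
#'   (haplotype-by-variant 0/1 integer matrix).
#' @seealso [read_tracts()], [simulate_regions()]
#' @export
read_ms <- function(path, length_bp) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  nsam <- as.integer(strsplit(lines[1], " +")[[1]][2])
  lapply(seq_along(starts), function(k) {
    i <- starts[k]
    S <- as.integer(sub("segsites: *", "", lines[i + 1L]))
    if (S == 0L) {
      return(list(positions = integer(0),
                  haps = matrix(0L, nrow = nsam, ncol = 0L)))
    }
    frac <- as.numeric(strsplit(sub("positions: *", "", lines[i + 2L]),
                                " +")[[1]])
    pos <- as.integer(round(frac * length_bp))
    hap_lines <- lines[(i + 3L):(i + 2L + nsam)]
    haps <- matrix(0L, nrow = nsam, ncol = S)
    for (j in seq_len(nsam)) haps[j, ] <- utf8ToInt(hap_lines[j]) - 48L
    list(positions = pos, haps = haps)
  })
}

#' Write haplotype regions in ms-style text
#'
#' Inverse of [read_ms()]: serializes a list of regions (or
#' `"archtrace_region"` objects) to the ms text format, with positions
#' written as fractions of `length_bp`.
#'
#' @param regions List of regions with `positions` and `haps` components.
#' @param path Output file path.
#' @param length_bp Region length in bp.
#' @export
write_ms <- function(regions, path, length_bp) {
  con <- file(path, "w")
  on.exit(close(con))
  nsam <- nrow(regions[[1]]$haps)
  writeLines(c(sprintf("ms %d %d (archtrace)", nsam, length(regions)), "0"), con)
  for (reg in regions) {
    writeLines(c("", "//", sprintf("segsites: %d", length(reg$positions))), con)
    if (length(reg$positions)) {
      writeLines(paste("positions:",
                       paste(sprintf("%.10f", reg$positions / length_bp),
                             collapse = " ")), con)
      writeLines(apply(reg$haps, 1, paste, collapse = ""), con)
    }
  }
}

#' Read or write archaic ancestry tract tables
#'
#' Tracts are stored as a BED-like tab-separated table with columns `rep`
#' (replicate, 1-based), `hap` (haplotype index within the target panel,
#' 1-based) and 0-based half-open `start`/`end` coordinates in bp.
#'
#' @param path File path.
#' @return `read_tracts()`: a data frame with columns `rep`, `hap`,
#'   `start`, `end`.
#' @export
read_tracts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "numeric", "numeric"))
}

#' @rdname read_tracts
#' @param tracts Data frame as returned by `read_tracts()`.
#' @export
write_tracts <- function(tracts, path) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
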