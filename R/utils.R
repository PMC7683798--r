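#' Normalize chromosome labels
#'
#' Strips a leading "chr"/"Chr" prefix so that "chr7" and "7" address the same
#' FIS-table key. Labels are otherwise kept verbatim (1-22, X, Y, MT, ...).
#'
#' @param x character vector of chromosome labels.
#' @return character vector without the "chr" prefix.
#' @export
#' @examples
#' normalizeChrom(c("chr7", "7", "chrX"))
normalizeChrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

## Canonical key used to join mutations to the FIS lookup table.
## Alleles are matched exactly but case-insensitively (no revcomp fallback).
fisKey <- function(chrom, pos, ref, alt) {
  paste(normalizeChrom(chrom), as.integer(pos),
        toupper(as.character(ref)), toupper(as.character(alt)),
        sep = ":")
}

## write.table wrapper fixing the TSV dialect used by all exporters
writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
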