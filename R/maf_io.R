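## MAF, FIS-table, effect-dictionary and gene-list I/O.

MAF_ESSENTIAL <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                   "End_Position", "Variant_Classification",
                   "Reference_Allele", "Tumor_Seq_Allele",
                   "Tumor_Sample_Barcode")

EFFECT_LEVELS <- c("silent", "non-coding", "non-silent", "null")

#' Default variant-classification to effect dictionary
#'
#' Maps the standard TCGA MAF `Variant_Classification` labels onto the four
#' mutation effect classes used throughout the package, ordered by increasing
#' protein impact: `silent` (synonymous), `non-coding` (UTR/intron/flank),
#' `non-silent` (amino-acid-altering), and `null` (truncating, frameshift,
#' splice). Override entries by reading a two-column TSV with
#' [readEffectDictionary()].
#'
#' @return named character vector: classification -> effect.
#' @export
#' @examples
#' defaultEffectDictionary()[["Missense_Mutation"]]
defaultEffectDictionary <- function() {
  c(Silent = "silent",
    Missense_Mutation = "non-silent",
    In_Frame_Del = "non-silent",
    In_Frame_Ins = "non-silent",
    Nonstop_Mutation = "non-silent",
    Nonsense_Mutation = "null",
    Splice_Site = "null",
    Frame_Shift_Del = "null",
    Frame_Shift_Ins = "null",
    Translation_Start_Site = "null",
    "3'UTR" = "non-coding",
    "5'UTR" = "non-coding",
    Intron = "non-coding",
    RNA = "non-coding",
    IGR = "non-coding",
    "5'Flank" = "non-coding",
    "3'Flank" = "non-coding")
}

#' Read a variant-classification effect dictionary from TSV
#'
#' Two tab-separated columns (no header): `Variant_Classification`, effect.
#' Every effect must be one of `silent`, `non-coding`, `non-silent`, `null`.
#'
#' @param path file path.
#' @return named character vector usable as `effectDict` in [readMAF()].
#' @export
readEffectDictionary <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(df) < 2L)
    stopf("effect dictionary '%s' must have two tab-separated columns", path)
  eff <- trimws(df[[2L]])
  bad <- setdiff(unique(eff), EFFECT_LEVELS)
  if (length(bad))
    stopf("effect dictionary '%s' contains unknown effect label(s): %s",
          path, paste(bad, collapse = ", "))
  stats::setNames(eff, trimws(df[[1L]]))
}

#' Read somatic mutations from a MAF file
#'
#' Reads a tab-separated Mutation Annotation Format file ("#" comment lines
#' skipped) and returns one record per usable data row with the mutation
#' effect attached from `effectDict`. The eight essential columns
#' (Hugo_Symbol, Chromosome, Start_Position, End_Position,
#' Variant_Classification, Reference_Allele, Tumor_Seq_Allele,
#' Tumor_Sample_Barcode) are matched case-insensitively;
#' `Tumor_Seq_Allele2` is accepted for the alternate allele when
#' `Tumor_Seq_Allele` is absent. Rows with any essential field empty, or with
#' start > end, are skipped and counted (see attribute `skipped`).
#' Chromosome labels are normalized to the prefix-free form.
#'
#' @param path MAF file path.
#' @param effectDict named character vector, classification -> effect;
#'   a classification absent from the dictionary is a fatal error.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `variant_classification`, `ref`, `alt`, `sample`, `effect`, and an
#'   integer attribute `skipped`.
#' @export
readMAF <- function(path, effectDict = defaultEffectDictionary()) {
  if (!file.exists(path)) stopf("MAF file not found: %s", path)
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   comment.char = "#", check.names = FALSE,
                   blank.lines.skip = TRUE)
  lc <- tolower(names(df))
  pick <- function(name, alternates = character()) {
    for (nm in c(name, alternates)) {
      i <- match(tolower(nm), lc)
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }
  idx <- c(gene  = pick("Hugo_Symbol"),
           chrom = pick("Chromosome"),
           start = pick("Start_Position"),
           end   = pick("End_Position"),
           vc    = pick("Variant_Classification"),
           ref   = pick("Reference_Allele"),
           alt   = pick("Tumor_Seq_Allele", "Tumor_Seq_Allele2"),
           samp  = pick("Tumor_Sample_Barcode"))
  if (anyNA(idx)) {
    missing <- MAF_ESSENTIAL[is.na(idx)]
    stopf("MAF '%s' lacks essential column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  out <- data.frame(
    gene = trimws(df[[idx["gene"]]]),
    chrom = normalizeChrom(trimws(df[[idx["chrom"]]])),
    start = suppressWarnings(as.integer(df[[idx["start"]]])),
    end = suppressWarnings(as.integer(df[[idx["end"]]])),
    variant_classification = trimws(df[[idx["vc"]]]),
    ref = trimws(df[[idx["ref"]]]),
    alt = trimws(df[[idx["alt"]]]),
    sample = trimws(df[[idx["samp"]]]),
    stringsAsFactors = FALSE)
  bad <- out$gene == "" | out$chrom == "" | is.na(out$start) | is.na(out$end) |
    out$variant_classification == "" | out$ref == "" | out$alt == "" |
    out$sample == "" | out$start > out$end
  bad[is.na(bad)] <- TRUE
  skipped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  unmapped <- setdiff(unique(out$variant_classification), names(effectDict))
  if (length(unmapped))
    stopf("variant classification(s) not in effect dictionary: %s",
          paste(unmapped, collapse = ", "))
  out$effect <- unname(effectDict[out$variant_classification])
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (skipped > 0L)
    message(sprintf("readMAF: skipped %d row(s) with missing/invalid fields",
                    skipped))
  out
}

#' Write mutation records to a MAF file
#'
#' Inverse of [readMAF()]: writes the eight essential columns so that reading
#' the file back yields field-wise identical records.
#'
#' @param mutations data.frame as returned by [readMAF()] (the `effect`
#'   column, if present, is not written; it is re-derived on read).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMAF <- function(mutations, path) {
  out <- data.frame(
    Hugo_Symbol = mutations$gene,
    Chromosome = mutations$chrom,
    Start_Position = mutations$start,
    End_Position = mutations$end,
    Variant_Classification = mutations$variant_classification,
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele = mutations$alt,
    Tumor_Sample_Barcode = mutations$sample,
    check.names = FALSE)
  writeTSV(out, path)
}

#' Read a per-mutation FIS lookup table
#'
#' Five tab-separated columns — chromosome, position, reference allele,
#' alternate allele, score — in MutationAssessor-release-3 style, with an
#' optional header line. Chromosome labels are normalized exactly as in
#' [readMAF()], so "chr7" and "7" address the same key. Duplicate
#' (chrom, pos, ref, alt) keys keep the first occurrence with a warning; a
#' non-numeric score is a fatal error reporting the offending line.
#'
#' @param path TSV file path.
#' @return a `FISTable`: data.frame (`chrom`, `pos`, `ref`, `alt`, `score`)
#'   with a named-numeric attribute `index` keyed by chrom:pos:ref:alt.
#' @export
readFISTable <- function(path) {
  if (!file.exists(path)) stopf("FIS table not found: %s", path)
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(df) < 5L)
    stopf("FIS table '%s' must have 5 columns (chrom, pos, ref, alt, score)",
          path)
  df <- df[, 1:5]
  names(df) <- c("chrom", "pos", "ref", "alt", "score")
  hasHeader <- is.na(suppressWarnings(as.numeric(df$score[1L]))) ||
    is.na(suppressWarnings(as.numeric(df$pos[1L])))
  offset <- 0L
  if (nrow(df) && hasHeader) {
    df <- df[-1L, , drop = FALSE]
    offset <- 1L
  }
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score))
    stopf("FIS table '%s': non-numeric score at line %d",
          path, which(is.na(score))[1L] + offset)
  tab <- data.frame(chrom = normalizeChrom(df$chrom),
                    pos = as.integer(df$pos),
                    ref = toupper(df$ref), alt = toupper(df$alt),
                    score = score, stringsAsFactors = FALSE)
  key <- fisKey(tab$chrom, tab$pos, tab$ref, tab$alt)
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("FIS table '%s': %d duplicate key(s); keeping first occurrence",
          path, sum(dup))
    tab <- tab[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  rownames(tab) <- NULL
  attr(tab, "index") <- stats::setNames(tab$score, key)
  class(tab) <- c("FISTable", "data.frame")
  tab
}

#' Look up per-mutation FIS scores
#'
#' @param table a `FISTable` from [readFISTable()].
#' @param chrom,pos,ref,alt vectors identifying mutations (chromosome labels
#'   may carry a "chr" prefix).
#' @return numeric vector of scores, NA where the key is absent.
#' @export
fisLookup <- function(table, chrom, pos, ref, alt) {
  idx <- attr(table, "index")
  unname(idx[fisKey(chrom, pos, ref, alt)])
}

#' Read a gene list (one symbol per line)
#'
#' Whitespace is stripped, blank lines dropped, duplicates removed; case is
#' preserved. An empty file gives an empty vector.
#'
#' @param path text file path.
#' @return character vector of unique gene symbols.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
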