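#' Genomic coordinate conventions
#'
#' All coordinates inside circkit are 0-based, half-open `[start, end)` on a
#' named chromosome with strand `+` or `-`. Only readers and writers convert:
#' CIRI tables are 1-based inclusive, BED is already 0-based half-open, GTF
#' (via rtracklayer) is 1-based inclusive. Back-splice (BS) site positions are
#' single-base 0-based positions: on `+` the 5' BS site is `start` and the 3'
#' BS site is `end - 1`; on `-` they swap ends.
#'
#' @name circkit-coordinates
NULL

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad) > 0) {
    abort(sprintf("%d %s(s) violate 0 <= start < end (first at row %d)",
                  length(bad), what, bad[1]))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort(sprintf("%s strand must be '+' or '-'", what))
  }
  invisible(df)
}

# BS-site positions from a 0-based half-open span, strand-aware
bs_sites <- function(start, end, strand) {
  list(bs5 = ifelse(strand == "+", start, end - 1L),
       bs3 = ifelse(strand == "+", end - 1L, start))
}

# 0-based half-open tibble -> GRanges (1-based)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors. Ambiguous bases are preserved.
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANTT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase and collapse IUPAC ambiguity codes other than ACGT to N,
# preserving length
normalize_bases <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}
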