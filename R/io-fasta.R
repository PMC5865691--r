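#' Load a genome FASTA into memory
#'
#' Reads a (optionally gzipped) FASTA into a [Biostrings::DNAStringSet] named
#' by chromosome. Header descriptions after the first whitespace are dropped.
#'
#' @param path FASTA file.
#' @return named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a genomic sequence
#'
#' Returns the uppercase A/C/G/T/N sequence of a 0-based half-open interval.
#' With `orient = TRUE` and `strand == "-"` the reverse complement is
#' returned, i.e. the sequence reads 5'->3' in transcript orientation.
#' Ambiguity codes other than ACGT are normalised to N, preserving length.
#'
#' @param genome named `DNAStringSet` from [read_genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval; `0 <= start < end` required.
#' @param strand `"+"` or `"-"`.
#' @param orient if TRUE, minus-strand intervals are reverse-complemented.
#' @return a single character string of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+",
                           orient = FALSE) {
  stopifnot(length(chrom) == 1, length(start) == 1, length(end) == 1)
  if (!(start >= 0 && start < end)) {
    abort(sprintf("invalid interval [%s, %s): need 0 <= start < end",
                  format(start), format(end)))
  }
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' not present in genome", chrom))
  }
  if (end > length(genome[[chrom]])) {
    abort(sprintf("interval [%d, %d) exceeds %s length %d",
                  start, end, chrom, length(genome[[chrom]])))
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  s <- normalize_bases(s)
  if (orient && strand == "-") s <- revcomp(s)
  s
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector (or tibble with `circ_id`/`id` and
#'   `sequence` columns) of nucleotide sequences; names must be unique.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_named_seqs(seqs)
  if (anyDuplicated(names(seqs))) abort("duplicate sequence ids in FASTA output")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ with constant quality
#'
#' @param reads tibble with `read_id` and `sequence` columns, or a named
#'   character vector.
#' @param path output path (`.gz` suffix compresses).
#' @param quality_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- as_named_seqs(reads, id_cols = c("read_id", "id"))
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep(quality_char, Biostrings::width(x)))
  names(q) <- names(x)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file, optionally gzipped.
#' @return tibble with `read_id` and `sequence` (uppercased, non-ACGT
#'   normalised to N).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) {
                  abort(sprintf("malformed FASTQ %s: %s", path,
                                conditionMessage(e)))
                })
  tibble(read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(normalize_bases(as.character(x))))
}

as_named_seqs <- function(x, id_cols = c("circ_id", "id")) {
  if (is.data.frame(x)) {
    idc <- intersect(id_cols, names(x))
    if (length(idc) == 0 || !"sequence" %in% names(x)) {
      abort(sprintf("need a 'sequence' column and one of: %s",
                    paste(id_cols, collapse = ", ")))
    }
    setNames(as.character(x$sequence), as.character(x[[idc[1]]]))
  } else if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0) abort("sequences must be named")
    x
  } else {
    abort("unsupported sequence container")
  }
}
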