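#' Reconstruct back-splice junction sequences
#'
#' For each circRNA the strand-oriented genomic sequence `S` of its span is
#' taken (reverse complement on `-`). When the span is at least `2 * flank`
#' long, the junction sequence is the last `flank` nt of `S` followed by the
#' first `flank` nt — the two genomic windows abutting the 3' and 5' BS
#' sites, read across the back-splice point. Shorter circRNAs are split in
#' two halves: with `h = ceiling(|S| / 2)` the sequence is the rotation
#' `S[h+1..] + S[..h]`, so the back-splice point sits between the last base
#' of `S` and the first.
#'
#' `junction_offset` is the 0-based index of the first base after the BS
#' point (`flank` for full-width junctions, `|S| - h` for short ones).
#' Flanks are genomic windows: introns inside the span are not spliced out
#' (the windows abut the BS sites, which sit at exon boundaries for exonic
#' circRNAs). Junctions consisting only of N trigger a warning but are still
#' emitted.
#'
#' @param circs circRNA tibble ([read_circ_table()] schema; `circ_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param genome `DNAStringSet` from [read_genome()].
#' @param flank flank length L in nt (default 35, giving 70-nt junctions).
#' @return tibble `circ_id`, `sequence`, `junction_offset`, `span_length`.
#' @export
build_bs_sequences <- function(circs, genome, flank = 35L) {
  stopifnot(flank >= 1)
  validate_intervals(circs, "circRNA")
  one <- function(i) {
    s <- fetch_sequence(genome, circs$chrom[i], circs$start[i], circs$end[i],
                        circs$strand[i], orient = TRUE)
    n <- nchar(s)
    if (n >= 2L * flank) {
      seq <- paste0(substr(s, n - flank + 1L, n), substr(s, 1L, flank))
      off <- as.integer(flank)
    } else {
      h <- as.integer(ceiling(n / 2))
      seq <- paste0(substr(s, h + 1L, n), substr(s, 1L, h))
      off <- n - h
    }
    if (grepl("^N+$", seq)) {
      warn(sprintf("junction of %s contains only N", circs$circ_id[i]))
    }
    tibble(circ_id = circs$circ_id[i], sequence = seq,
           junction_offset = off, span_length = n)
  }
  purrr::map_dfr(seq_len(nrow(circs)), one)
}

#' Write junction sequences to FASTA
#'
#' One record per junction, header = `circ_id`, input order preserved;
#' duplicate ids are an error.
#'
#' @param junctions tibble from [build_bs_sequences()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(junctions, path) {
  if (anyDuplicated(junctions$circ_id)) {
    abort("duplicate circ_id in junction set")
  }
  write_fasta(junctions, path)
}

#' Read junction sequences from FASTA
#'
#' Inverse of [write_junction_fasta()]; `junction_offset` is taken as half
#' the sequence length rounded down (exact for both the full-width and the
#' split-in-halves construction).
#'
#' @param path FASTA of junction sequences.
#' @return tibble `circ_id`, `sequence`, `junction_offset`.
#' @export
read_junction_fasta <- function(path) {
  x <- read_genome(path)
  tibble(circ_id = names(x),
         sequence = unname(normalize_bases(as.character(x))),
         junction_offset = as.integer(floor(Biostrings::width(x) / 2)))
}
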