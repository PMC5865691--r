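#' Read transcript models from an Ensembl-style GTF
#'
#' Parses exon features into a flat exon table, one row per exon, with
#' strand-aware exon ranks (rank 1 is the 5'-most exon in transcript
#' orientation, i.e. the genomically last exon on the minus strand) and the
#' order of first appearance of each transcript in the file (`source_order`,
#' 0-based), used downstream for univocal isoform resolution.
#'
#' Attributes `gene_id`, `gene_name`, `transcript_id` and `transcript_name`
#' are read from the attribute column; missing `gene_name`/`transcript_name`
#' fall back to the corresponding id. Transcript features without any exon
#' feature are dropped with a warning. Coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return a tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `transcript_name`, `gene_id`, `gene_symbol`,
#'   `exon_rank`, `source_order`, sorted by `source_order` then `exon_rank`.
#' @seealso [write_gtf()], [transcript_spans()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"type" %in% names(meta) || !"transcript_id" %in% names(meta)) {
    abort(sprintf("GTF %s lacks type/transcript_id attributes", path))
  }
  tx_ids_seen <- unique(meta$transcript_id[!is.na(meta$transcript_id)])
  ex <- gr[meta$type == "exon"]
  if (length(ex) == 0) abort(sprintf("GTF %s contains no exon features", path))
  m <- S4Vectors::mcols(ex)
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    transcript_id = as.character(m$transcript_id),
    transcript_name = as.character(if ("transcript_name" %in% names(m))
      m$transcript_name else m$transcript_id),
    gene_id = as.character(m$gene_id),
    gene_symbol = as.character(if ("gene_name" %in% names(m))
      m$gene_name else m$gene_id)
  )
  df$transcript_name <- ifelse(is.na(df$transcript_name),
                               df$transcript_id, df$transcript_name)
  df$gene_symbol <- ifelse(is.na(df$gene_symbol), df$gene_id, df$gene_symbol)
  if (!all(df$strand %in% c("+", "-"))) {
    abort("exon features with strand other than +/- are not supported")
  }
  validate_intervals(df, "exon")
  no_exon <- setdiff(tx_ids_seen, unique(df$transcript_id))
  if (length(no_exon) > 0) {
    warn(sprintf("dropping %d transcript(s) with zero exon features: %s",
                 length(no_exon), paste(no_exon, collapse = ", ")))
  }
  order_tbl <- tibble(transcript_id = unique(df$transcript_id)) |>
    mutate(source_order = row_number() - 1L)
  df |>
    left_join(order_tbl, by = "transcript_id") |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "+") row_number()
           else rev(row_number())) |>
    ungroup() |>
    arrange(.data$source_order, .data$exon_rank)
}

# cheap structural pre-check so malformed lines are reported by number
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 9]
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF line %d in %s (expected >= 9 tab-separated fields)",
                  bad[1], path))
  }
  invisible(TRUE)
}

#' Per-transcript genomic spans
#'
#' Summarises an exon table to one row per transcript with the exon hull
#' (`start` = min exon start, `end` = max exon end), used as the transcript's
#' gene span for intergenic calls.
#'
#' @param exons exon tibble as returned by [read_gtf()].
#' @return tibble with one row per transcript.
#' @export
transcript_spans <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      strand = .data$strand[1], transcript_name = .data$transcript_name[1],
      gene_id = .data$gene_id[1], gene_symbol = .data$gene_symbol[1],
      n_exons = n(), source_order = .data$source_order[1], .groups = "drop"
    ) |>
    arrange(.data$source_order)
}

#' Write an exon table back to GTF
#'
#' Emits one `exon` feature per row with Ensembl-style attributes
#' (`gene_id`, `gene_name`, `transcript_id`, `transcript_name`,
#' `exon_number`), in `source_order` so that [read_gtf()] round-trips the
#' models exactly.
#'
#' @param exons exon tibble as returned by [read_gtf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path) {
  validate_intervals(exons, "exon")
  exons <- arrange(exons, .data$source_order, .data$exon_rank)
  gr <- intervals_to_granges(exons)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "circkit", type = "exon",
    gene_id = exons$gene_id, gene_name = exons$gene_symbol,
    transcript_id = exons$transcript_id,
    transcript_name = exons$transcript_name,
    exon_number = as.character(exons$exon_rank)
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
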