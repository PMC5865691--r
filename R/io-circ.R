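#' Read a table of circRNA back-splice coordinates
#'
#' Two dialects are supported. `"ciri"` expects a header-ed TSV with (at
#' least) columns `circRNA_ID`, `chr`, `circRNA_start`, `circRNA_end` and
#' `strand`, with 1-based inclusive coordinates; a junction-read column whose
#' name contains "junction_reads" is kept when present, all other columns are
#' ignored. `"bed"` expects headerless BED6 (0-based half-open; column 5 is
#' carried as `junction_reads` when numeric).
#'
#' Records are normalised to the internal 0-based half-open convention and
#' the strand-aware BS-site positions `bs5` / `bs3` are derived (span of at
#' least 2 bp required). Records with `start >= end` after conversion are
#' rejected with a warning naming them.
#'
#' @param path input file.
#' @param dialect `"ciri"` or `"bed"`.
#' @return tibble with columns `circ_id`, `chrom`, `start`, `end`, `strand`,
#'   `bs5`, `bs3`, `junction_reads` (NA when absent).
#' @export
read_circ_table <- function(path, dialect = c("ciri", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("circRNA table not found: %s", path))
  if (dialect == "ciri") {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           name_repair = "minimal")
    names(tab) <- sub("^#\\s*", "", names(tab))
    need <- c("circRNA_ID", "chr", "circRNA_start", "circRNA_end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss) > 0) {
      abort(sprintf("CIRI table %s lacks column(s): %s",
                    path, paste(miss, collapse = ", ")))
    }
    jr_col <- grep("junction_reads$", names(tab), value = TRUE)
    df <- tibble(
      circ_id = as.character(tab$circRNA_ID),
      chrom = as.character(tab$chr),
      start = as.integer(tab$circRNA_start) - 1L,  # 1-based incl -> 0-based
      end = as.integer(tab$circRNA_end),
      strand = as.character(tab$strand),
      junction_reads = if (length(jr_col) > 0)
        as.integer(tab[[jr_col[1]]]) else NA_integer_
    )
  } else {
    tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    if (ncol(tab) < 6) abort(sprintf("BED file %s needs >= 6 columns", path))
    df <- tibble(
      circ_id = as.character(tab[[4]]),
      chrom = as.character(tab[[1]]),
      start = as.integer(tab[[2]]),
      end = as.integer(tab[[3]]),
      strand = as.character(tab[[6]]),
      junction_reads = suppressWarnings(as.integer(tab[[5]]))
    )
    df$circ_id <- ifelse(is.na(df$circ_id) | df$circ_id == ".",
                         sprintf("%s:%d-%d", df$chrom, df$start, df$end),
                         df$circ_id)
  }
  bad <- which(!(df$start >= 0 & df$end - df$start >= 2))
  if (length(bad) > 0) {
    warn(sprintf("rejecting %d record(s) with invalid span (< 2 bp or start >= end): %s",
                 length(bad), paste(utils::head(df$circ_id[bad], 5), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort("circRNA strand must be '+' or '-'")
  }
  s <- bs_sites(df$start, df$end, df$strand)
  df$bs5 <- as.integer(s$bs5)
  df$bs3 <- as.integer(s$bs3)
  df[, c("circ_id", "chrom", "start", "end", "strand", "bs5", "bs3",
         "junction_reads")]
}

#' Write circRNA records as BED6
#'
#' Inverse of the `"bed"` dialect of [read_circ_table()]: 0-based half-open,
#' `junction_reads` (0 when missing) in the score column.
#'
#' @param circs circRNA tibble (needs `circ_id`, `chrom`, `start`, `end`,
#'   `strand`; `junction_reads` optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(circs, path) {
  validate_intervals(circs, "circRNA")
  score <- if ("junction_reads" %in% names(circs)) {
    ifelse(is.na(circs$junction_reads), 0L, circs$junction_reads)
  } else 0L
  readr::write_tsv(
    tibble(circs$chrom, circs$start, circs$end, circs$circ_id, score,
           circs$strand),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file of stranded intervals
#'
#' Generic BED6 reader for repeat annotations and per-interval read
#' alignments; 0-based half-open coordinates are kept as-is.
#'
#' @param path BED file.
#' @return tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  tab <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 3) abort(sprintf("BED file %s needs >= 3 columns", path))
  tibble(
    chrom = as.character(tab[[1]]),
    start = as.integer(tab[[2]]),
    end = as.integer(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else ".",
    score = if (ncol(tab) >= 5) suppressWarnings(as.numeric(tab[[5]])) else 0,
    strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "+"
  )
}
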