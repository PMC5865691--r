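#' Classify one back-splice event against one transcript
#'
#' Applies the five-way decision tree in fixed precedence:
#' 1. either BS site outside the transcript span -> `intergenic`;
#' 2. either BS site inside an intron -> `intronic`;
#' 3. both BS sites exactly on exon boundaries in transcript orientation
#'    (the 5' BS site at an exon's 5' boundary, the 3' BS site at an exon's
#'    3' boundary, within `wobble` bp) -> `monoexonic` when it is the same
#'    exon, else `multiexonic`, with the exon ranks;
#' 4. otherwise `putative_exonic` (both sites exonic, no precise boundary
#'    match).
#'
#' The precedence makes the five categories mutually exclusive. A
#' chromosome/strand mismatch yields no classification (`NULL`): the caller
#' treats the transcript as non-overlapping.
#'
#' @param circ one-row circRNA tibble (see [read_circ_table()]).
#' @param tx_exons exon rows of a single transcript ([read_gtf()] schema).
#' @param wobble boundary-match tolerance in bp (default 0).
#' @return list with `category`, `rank5`, `rank3`, or NULL on
#'   chromosome/strand mismatch.
#' @export
classify_against_transcript <- function(circ, tx_exons, wobble = 0L) {
  if (nrow(tx_exons) == 0) return(NULL)
  if (circ$chrom != tx_exons$chrom[1] || circ$strand != tx_exons$strand[1]) {
    return(NULL)
  }
  span_start <- min(tx_exons$start)
  span_end <- max(tx_exons$end)
  sites <- c(circ$bs5, circ$bs3)
  if (any(sites < span_start | sites >= span_end)) {
    return(list(category = "intergenic", rank5 = NA_integer_,
                rank3 = NA_integer_))
  }
  in_exon <- function(p) any(p >= tx_exons$start & p < tx_exons$end)
  if (!all(vapply(sites, in_exon, logical(1)))) {
    return(list(category = "intronic", rank5 = NA_integer_,
                rank3 = NA_integer_))
  }
  # 5'/3' exon boundaries in transcript orientation
  plus <- circ$strand == "+"
  b5 <- if (plus) tx_exons$start else tx_exons$end - 1L
  b3 <- if (plus) tx_exons$end - 1L else tx_exons$start
  d5 <- abs(circ$bs5 - b5)
  d3 <- abs(circ$bs3 - b3)
  if (min(d5) <= wobble && min(d3) <= wobble) {
    r5 <- tx_exons$exon_rank[which.min(d5)]
    r3 <- tx_exons$exon_rank[which.min(d3)]
    cat <- if (r5 == r3) "monoexonic" else "multiexonic"
    return(list(category = cat, rank5 = as.integer(r5), rank3 = as.integer(r3)))
  }
  list(category = "putative_exonic", rank5 = NA_integer_, rank3 = NA_integer_)
}

#' Classify circRNAs with univocal isoform resolution
#'
#' For each circRNA the overlapping transcripts (same chromosome and strand,
#' transcript span overlapping the circ span) are collected. When any
#' transcript name carries the main-isoform suffix `001` (optionally after a
#' `-` or `.` separator, as in `GENE-001`), the main isoform's classification
#' is used; otherwise transcripts are evaluated in annotation file order
#' (`source_order`, ties broken by `transcript_id`) and the first
#' classification is kept. circRNAs overlapping no transcript are
#' `intergenic` with no transcript, and are named by their display
#' coordinates.
#'
#' @param circs circRNA tibble from [read_circ_table()].
#' @param exons exon tibble from [read_gtf()].
#' @param wobble boundary tolerance in bp passed to
#'   [classify_against_transcript()].
#' @return tibble with one row per circRNA: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `category`, `transcript_id`, `gene_symbol`, `rank5`,
#'   `rank3`, `name`.
#' @export
classify_circs <- function(circs, exons, wobble = 0L) {
  stopifnot(is.data.frame(circs), is.data.frame(exons))
  if (!"bs5" %in% names(circs)) {
    s <- bs_sites(circs$start, circs$end, circs$strand)
    circs$bs5 <- as.integer(s$bs5)
    circs$bs3 <- as.integer(s$bs3)
  }
  spans <- transcript_spans(exons)
  ex_by_tx <- split(exons, exons$transcript_id)
  is_main <- grepl("([-.]|^)001$", spans$transcript_name)

  one <- function(i) {
    circ <- circs[i, ]
    cand <- spans[spans$chrom == circ$chrom & spans$strand == circ$strand &
                    spans$start < circ$end & spans$end > circ$start, ]
    if (nrow(cand) > 0) {
      main <- which(is_main[match(cand$transcript_id, spans$transcript_id)])
      ord <- order(cand$source_order, cand$transcript_id)
      pick <- if (length(main) > 0) {
        main[order(cand$source_order[main], cand$transcript_id[main])][1]
      } else ord[1]
      tx <- cand$transcript_id[pick]
      cl <- classify_against_transcript(circ, ex_by_tx[[tx]], wobble = wobble)
      tibble(circ_id = circ$circ_id, chrom = circ$chrom, start = circ$start,
             end = circ$end, strand = circ$strand, category = cl$category,
             transcript_id = tx,
             gene_symbol = cand$gene_symbol[pick],
             rank5 = cl$rank5, rank3 = cl$rank3)
    } else {
      tibble(circ_id = circ$circ_id, chrom = circ$chrom, start = circ$start,
             end = circ$end, strand = circ$strand, category = "intergenic",
             transcript_id = NA_character_, gene_symbol = NA_character_,
             rank5 = NA_integer_, rank3 = NA_integer_)
    }
  }
  out <- purrr::map_dfr(seq_len(nrow(circs)), one)
  out$name <- name_circrna(out)
  out
}

#' circRNA nomenclature
#'
#' Builds the field-standard name for each classified circRNA:
#' `Circ_<GENE>_<r>` for monoexonic, `Circ_<GENE>_<r5>-<r3>` for multiexonic,
#' `Circ_<GENE>_I` for intronic, `Circ_<GENE>_PE` for putative exonic, and
#' `Circ_<chrom>:<start>-<end>(<strand>)` with 1-based inclusive display
#' coordinates for intergenic.
#'
#' @param classified classification tibble from [classify_circs()] (columns
#'   `category`, `gene_symbol`, `rank5`, `rank3`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return character vector of names.
#' @export
name_circrna <- function(classified) {
  need_gene <- classified$category != "intergenic"
  if (any(need_gene & (is.na(classified$gene_symbol) |
                       classified$gene_symbol == ""))) {
    abort("gene-overlapping circRNA with missing gene symbol cannot be named")
  }
  dplyr::case_when(
    classified$category == "monoexonic" ~
      sprintf("Circ_%s_%d", classified$gene_symbol, classified$rank5),
    classified$category == "multiexonic" ~
      sprintf("Circ_%s_%d-%d", classified$gene_symbol, classified$rank5,
              classified$rank3),
    classified$category == "intronic" ~
      sprintf("Circ_%s_I", classified$gene_symbol),
    classified$category == "putative_exonic" ~
      sprintf("Circ_%s_PE", classified$gene_symbol),
    TRUE ~ sprintf("Circ_%s:%d-%d(%s)", classified$chrom,
                   classified$start + 1L, classified$end, classified$strand)
  )
}

#' Summarise a set of classifications
#'
#' Counts and fractions per category, per number of exons spanned
#' (multiexonic + monoexonic only; `rank3 - rank5 + 1`), and per 5'/3'
#' circularising-exon rank. Fractions are over all classified circRNAs, so
#' that e.g. the share of two-exon circles is directly comparable across
#' datasets of different category composition.
#'
#' @param classified tibble from [classify_circs()].
#' @return object of class `circ_class_summary`: list of tibbles `category`,
#'   `exon_span`, `rank` (long, with a `side` column).
#' @export
classification_summary <- function(classified) {
  n_tot <- nrow(classified)
  cat_levels <- c("multiexonic", "monoexonic", "putative_exonic", "intronic",
                  "intergenic")
  category <- classified |>
    count(category = factor(.data$category, levels = cat_levels),
          .drop = FALSE, name = "n") |>
    mutate(category = as.character(.data$category),
           fraction = if (n_tot > 0) .data$n / n_tot else numeric(n()))
  if (n_tot == 0) category <- category[0, ]
  exonic <- filter(classified,
                   .data$category %in% c("multiexonic", "monoexonic"))
  exon_span <- exonic |>
    mutate(n_exons = .data$rank3 - .data$rank5 + 1L) |>
    count(.data$n_exons, name = "n") |>
    mutate(fraction = .data$n / n_tot)
  rank <- bind_rows(
    exonic |> count(rank = .data$rank5, name = "n") |> mutate(side = "5'CE"),
    exonic |> count(rank = .data$rank3, name = "n") |> mutate(side = "3'CE")
  ) |>
    mutate(fraction = if (nrow(exonic) > 0) .data$n / nrow(exonic)
           else numeric(n())) |>
    select("side", "rank", "n", "fraction")
  structure(list(category = category, exon_span = exon_span, rank = rank,
                 n_total = n_tot),
            class = "circ_class_summary")
}

#' @export
print.circ_class_summary <- function(x, ...) {
  cat(sprintf("circRNA classification summary (%d circRNAs)\n", x$n_total))
  print(x$category)
  if (nrow(x$exon_span) > 0) {
    cat("\nexons spanned (multiexonic + monoexonic):\n")
    print(x$exon_span)
  }
  invisible(x)
}

#' @export
tidy.circ_class_summary <- function(x, ...) x$category

#' Plot a classification summary
#'
#' Bar panels of category composition and exons-spanned distribution.
#'
#' @param object a `circ_class_summary`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.circ_class_summary <- function(object, ...) {
  df <- bind_rows(
    object$category |>
      mutate(panel = "category", x = .data$category),
    object$exon_span |>
      mutate(panel = "exons spanned", x = as.character(.data$n_exons))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "circRNAs") +
    ggplot2::theme_minimal()
}

#' Write a classification table as TSV
#'
#' @param classified tibble from [classify_circs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classified, path) {
  readr::write_tsv(classified, path)
  invisible(path)
}
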