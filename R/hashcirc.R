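#' HashCirc quantification parameters
#'
#' Bundles the thresholds and scoring scheme of the two-stage quantifier:
#' `k` is the k-mer length, `N` the minimum number of read k-mer positions
#' found in the reference index for a read to become *putative*, and `M` the
#' minimum Smith-Waterman score for a putative read to be counted toward its
#' best-scoring junction. Defaults (k = 21, N = 17, M = 30) are the
#' short-read setting; 50-nt total RNA-seq is typically run at the same
#' values, longer reads at proportionally larger k/N/M (e.g. 22/18/33 or
#' 26/21/40).
#'
#' Alignment uses match reward 2, mismatch penalty 2, and affine gaps costing
#' `sw_gap_open` for the first gapped base plus `sw_gap_extend` for each
#' additional one. With match reward 2, `M = 40` corresponds to roughly 20
#' aligned bases.
#'
#' @param k k-mer length (>= 1).
#' @param N minimum shared k-mers for read selection (>= 0).
#' @param M minimum alignment score for counting (>= 0).
#' @param sw_match,sw_mismatch,sw_gap_open,sw_gap_extend alignment scoring.
#' @param stranded if FALSE (default) the index holds both strands and each
#'   read is scored as the better of itself and its reverse complement.
#' @param strict_gt if TRUE, selection requires strictly more than `N` shared
#'   k-mers instead of at least `N`.
#' @return list of class `hashcirc_params`.
#' @export
hashcirc_params <- function(k = 21L, N = 17L, M = 30L, sw_match = 2L,
                            sw_mismatch = 2L, sw_gap_open = 3L,
                            sw_gap_extend = 1L, stranded = FALSE,
                            strict_gt = FALSE) {
  stopifnot(k >= 1, N >= 0, M >= 0, sw_match > 0, sw_mismatch >= 0,
            sw_gap_open >= 0, sw_gap_extend >= 0)
  structure(list(k = as.integer(k), N = as.integer(N), M = as.integer(M),
                 sw_match = as.integer(sw_match),
                 sw_mismatch = as.integer(sw_mismatch),
                 sw_gap_open = as.integer(sw_gap_open),
                 sw_gap_extend = as.integer(sw_gap_extend),
                 stranded = isTRUE(stranded), strict_gt = isTRUE(strict_gt)),
            class = "hashcirc_params")
}

#' Sliding-window k-mer decomposition
#'
#' Returns every substring `seq[i..i+k-1]` for `i = 1 .. len - k + 1`, in
#' order, duplicates preserved; empty when the sequence is shorter than `k`.
#' K-mers containing N are emitted here but are never indexed or matched.
#'
#' @param seq a single nucleotide string.
#' @param k k-mer length.
#' @return character vector of k-mers.
#' @export
#' @examples
#' generate_kmers("ATCCCGTC", 3)
generate_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1, k >= 1)
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}

#' Build the k-mer membership index over a reference set
#'
#' Implements the `isPresent` contract: a k-mer maps to 1 exactly when it
#' occurs in at least one reference sequence — both strands when
#' `stranded = FALSE`. K-mers containing N are excluded. Membership queries
#' are amortised constant time (hashed set).
#'
#' @param refs junction tibble (`circ_id`, `sequence`), named character
#'   vector, or `DNAStringSet`.
#' @param params [hashcirc_params()].
#' @return object of class `kmer_index`.
#' @export
build_kmer_index <- function(refs, params = hashcirc_params()) {
  seqs <- ref_seqs(refs)
  if (length(seqs) == 0) abort("reference set is empty")
  if (all(nchar(seqs) < params$k)) {
    abort(sprintf("all references are shorter than k = %d", params$k))
  }
  both <- if (params$stranded) seqs else c(seqs, revcomp(seqs))
  km <- unlist(lapply(unname(both), generate_kmers, k = params$k),
               use.names = FALSE)
  km <- unique(km[!grepl("N", km, fixed = TRUE)])
  structure(list(k = params$k, stranded = params$stranded, kmers = km,
                 ref_ids = names(seqs)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k = %d, %d distinct k-mers over %d reference(s)%s\n",
              x$k, length(x$kmers), length(x$ref_ids),
              if (x$stranded) " (stranded)" else " (both strands)"))
  invisible(x)
}

#' Query the k-mer index
#'
#' @param index a `kmer_index`.
#' @param kmers character vector of k-mers.
#' @return logical vector: TRUE where the k-mer occurs in the reference set.
#' @export
is_present <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  kmers %in% index$kmers
}

# shared k-mer position counts for many reads against one index
shared_kmer_counts <- function(seqs, index) {
  n <- nchar(seqs)
  nk <- pmax(n - index$k + 1L, 0L)
  if (sum(nk) == 0) return(integer(length(seqs)))
  ridx <- rep.int(seq_along(seqs), nk)
  starts <- unlist(lapply(nk, function(m) seq_len(m)), use.names = FALSE)
  km <- substring(seqs[ridx], starts, starts + index$k - 1L)
  hits <- km %in% index$kmers
  cnt <- integer(length(seqs))
  if (any(hits)) {
    t <- tabulate(ridx[hits], nbins = length(seqs))
    cnt <- as.integer(t)
  }
  cnt
}

#' Select putative junction-spanning reads
#'
#' Stage-two filter: a read is kept when at least `N` of its k-mer positions
#' (strictly more than `N` with `strict_gt`) carry a k-mer present in the
#' reference index. Reads shorter than `k` are never selected. Selection is
#' order-preserving and single-pass; when `stranded = FALSE` the read is
#' tested as-is because the index already holds both strands.
#'
#' @param reads tibble with `read_id` and `sequence` (see [read_fastq()]).
#' @param index `kmer_index` built with the same `k`.
#' @param params [hashcirc_params()].
#' @return the selected subset of `reads`, with a `shared_kmers` column.
#' @export
select_reads <- function(reads, index, params = hashcirc_params()) {
  stopifnot(inherits(index, "kmer_index"))
  if (index$k != params$k) abort("index k does not match params k")
  cnt <- shared_kmer_counts(reads$sequence, index)
  keep <- if (params$strict_gt) cnt > params$N else cnt >= params$N
  keep <- keep & nchar(reads$sequence) >= index$k  # short reads never pass
  out <- reads[keep, , drop = FALSE]
  out$shared_kmers <- cnt[keep]
  out
}

#' Smith-Waterman local alignment score
#'
#' Best local alignment score of two sequences under the scoring scheme in
#' `params` (affine gaps; a gap of length g costs
#' `sw_gap_open + (g - 1) * sw_gap_extend`). Score is always >= 0. N never
#' matches any base.
#'
#' @param a,b nucleotide strings.
#' @param params [hashcirc_params()].
#' @return integer score.
#' @export
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT")
smith_waterman <- function(a, b, params = hashcirc_params()) {
  .sw_score_pair(a, b, params$sw_match, params$sw_mismatch,
                 params$sw_gap_open, params$sw_gap_extend)
}

# reads x refs score matrix, taking the better of read/revcomp when unstranded
sw_best_scores <- function(read_seqs, refs, params) {
  seqs <- ref_seqs(refs)
  sc <- .sw_score_matrix(read_seqs, unname(seqs), params$sw_match,
                         params$sw_mismatch, params$sw_gap_open,
                         params$sw_gap_extend)
  if (!params$stranded && length(read_seqs) > 0) {
    sc2 <- .sw_score_matrix(revcomp(read_seqs), unname(seqs), params$sw_match,
                            params$sw_mismatch, params$sw_gap_open,
                            params$sw_gap_extend)
    sc <- pmax(sc, sc2)
  }
  colnames(sc) <- names(seqs)
  sc
}

#' Count putative reads against the junction set
#'
#' Confirmation stage: each putative read is aligned (Smith-Waterman)
#' against every reference — and, when `stranded = FALSE`, its reverse
#' complement too, keeping the better score per reference. A read increments
#' exactly one reference, its best-scoring one, and only when that score is
#' at least `M`; ties go to the lexicographically smallest reference id.
#'
#' @param reads putative read tibble (from [select_reads()], or any
#'   `read_id`/`sequence` tibble).
#' @param refs reference set (junction tibble, named vector or FASTA-loaded
#'   `DNAStringSet`).
#' @param params [hashcirc_params()].
#' @param details if TRUE, attach the per-read assignment tibble as
#'   attribute `"assignments"`.
#' @return tibble `circ_id`, `count` covering every reference (zeros kept).
#' @export
count_reads <- function(reads, refs, params = hashcirc_params(),
                        details = FALSE) {
  seqs <- ref_seqs(refs)
  ids <- names(seqs)
  counts <- setNames(integer(length(ids)), ids)
  assign_tbl <- tibble(read_id = character(), circ_id = character(),
                       score = integer())
  if (nrow(reads) > 0) {
    sc <- sw_best_scores(reads$sequence, seqs, params)
    # ties -> lexicographically smallest reference id
    ord <- order(ids)
    sc_o <- sc[, ord, drop = FALSE]
    best_j <- max.col(sc_o, ties.method = "first")
    best_s <- sc_o[cbind(seq_len(nrow(sc_o)), best_j)]
    hit <- best_s >= params$M
    if (any(hit)) {
      assigned <- ids[ord][best_j[hit]]
      t <- table(assigned)
      counts[names(t)] <- counts[names(t)] + as.integer(t)
      assign_tbl <- tibble(read_id = reads$read_id[hit], circ_id = assigned,
                           score = as.integer(best_s[hit]))
    }
  }
  out <- tibble(circ_id = ids, count = as.integer(counts))
  if (details) attr(out, "assignments") <- assign_tbl
  out
}

#' Run the full two-stage quantifier over FASTQ samples
#'
#' For each sample: stream the reads, pre-select putative junction-spanning
#' reads with the k-mer index, confirm and count them by best-hit
#' Smith-Waterman. Output is deterministic for fixed inputs. A sample that
#' fails to read is reported with NA counts and a message; the remaining
#' samples still run (the CLI converts any failure into a non-zero exit).
#'
#' @param samples character vector of FASTQ paths; names become sample ids
#'   (default: basename without extensions).
#' @param junctions junction tibble from [build_bs_sequences()], or a path
#'   to a junction FASTA.
#' @param params [hashcirc_params()].
#' @return object of class `hashcirc_result`: list with `counts` (tibble,
#'   `circ_id` plus one integer column per sample), `report` (per-sample
#'   reads scanned / selected / counted), and `params`.
#' @export
hashcirc_run <- function(samples, junctions, params = hashcirc_params()) {
  if (is.character(junctions) && length(junctions) == 1 &&
      file.exists(junctions)) {
    junctions <- read_junction_fasta(junctions)
  }
  if (is.null(names(samples))) {
    names(samples) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(samples))
  }
  index <- build_kmer_index(junctions, params)
  counts <- tibble(circ_id = names(ref_seqs(junctions)))
  report <- NULL
  for (sm in names(samples)) {
    res <- tryCatch({
      reads <- read_fastq(samples[[sm]])
      putative <- select_reads(reads, index, params)
      ct <- count_reads(putative, junctions, params)
      list(ct = ct, n_reads = nrow(reads), n_selected = nrow(putative),
           n_counted = sum(ct$count), ok = TRUE)
    }, error = function(e) {
      message(sprintf("sample %s failed: %s", sm, conditionMessage(e)))
      list(ct = tibble(circ_id = counts$circ_id, count = NA_integer_),
           n_reads = NA_integer_, n_selected = NA_integer_,
           n_counted = NA_integer_, ok = FALSE)
    })
    counts[[sm]] <- res$ct$count[match(counts$circ_id, res$ct$circ_id)]
    report <- bind_rows(report, tibble(
      sample = sm, n_reads = res$n_reads, n_selected = res$n_selected,
      n_counted = res$n_counted, ok = res$ok))
  }
  structure(list(counts = counts, report = report, params = params),
            class = "hashcirc_result")
}

ref_seqs <- function(refs) {
  if (inherits(refs, "DNAStringSet")) {
    setNames(normalize_bases(as.character(refs)), names(refs))
  } else if (is.data.frame(refs)) {
    as_named_seqs(refs)
  } else if (is.character(refs)) {
    if (is.null(names(refs)) && length(refs) > 0) {
      abort("reference sequences must be named")
    }
    normalize_bases(refs)
  } else {
    abort("unsupported reference container")
  }
}

#' @export
print.hashcirc_result <- function(x, ...) {
  cat(sprintf("HashCirc counts: %d junction(s) x %d sample(s) (k=%d, N=%d, M=%d)\n",
              nrow(x$counts), ncol(x$counts) - 1L, x$params$k, x$params$N,
              x$params$M))
  print(x$report)
  invisible(x)
}

#' Tidy a HashCirc result into long form
#'
#' @param x a `hashcirc_result`.
#' @param ... ignored.
#' @return tibble `circ_id`, `sample`, `count`.
#' @export
tidy.hashcirc_result <- function(x, ...) {
  tidyr::pivot_longer(x$counts, -"circ_id", names_to = "sample",
                      values_to = "count")
}

#' One-row summary of a HashCirc run
#'
#' `detection_rate` is the fraction of junctions with at least one counted
#' read in at least one sample.
#'
#' @param x a `hashcirc_result`.
#' @param ... ignored.
#' @return one-row tibble.
#' @export
glance.hashcirc_result <- function(x, ...) {
  m <- as.matrix(x$counts[, -1, drop = FALSE])
  tibble(
    n_junctions = nrow(x$counts),
    n_samples = ncol(m),
    total_reads = sum(x$report$n_reads, na.rm = TRUE),
    total_selected = sum(x$report$n_selected, na.rm = TRUE),
    total_counted = sum(x$report$n_counted, na.rm = TRUE),
    detection_rate = if (nrow(x$counts) > 0)
      mean(apply(m, 1, function(r) any(r > 0, na.rm = TRUE))) else NA_real_
  )
}

#' Heatmap of a HashCirc count table
#'
#' @param object a `hashcirc_result`.
#' @param ... ignored.
#' @return a ggplot object (log10(count + 1) tile heatmap).
#' @export
autoplot.hashcirc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$circ_id,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(count+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a HashCirc count table as TSV
#'
#' Rows are junction ids, columns sample ids, integer cells.
#'
#' @param x a `hashcirc_result` (or its `counts` tibble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  counts <- if (inherits(x, "hashcirc_result")) x$counts else x
  readr::write_tsv(counts, path)
  invisible(path)
}
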