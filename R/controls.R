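#' Chimeric control sets by permuting junction halves
#'
#' Builds null junction sets: each control sequence is the left half (up to
#' `junction_offset`) of one junction joined to the right half of a
#' *different* junction, with the re-pairing drawn as a random derangement.
#' Per set, the multiset of left halves and of right halves is exactly
#' conserved and no control sequence equals an original junction — the
#' chimeras look like back-splice junctions but are absent from the data.
#' With `subset_size` the input is subsampled (without replacement) before
#' each permutation.
#'
#' @param junctions tibble with `circ_id`, `sequence`, `junction_offset`
#'   (from [build_bs_sequences()]); at least 2 rows.
#' @param n_sets number of control sets (>= 1).
#' @param subset_size optional number of junctions sampled before permuting.
#' @param seed integer seed; results are bit-reproducible given
#'   (seed, inputs, n_sets).
#' @return tibble `set`, `left_id`, `right_id`, `sequence`.
#' @export
permute_halves <- function(junctions, n_sets = 1L, subset_size = NULL,
                           seed = NULL) {
  if (nrow(junctions) < 2) abort("need at least 2 junctions to permute halves")
  stopifnot(n_sets >= 1)
  if (!is.null(subset_size)) {
    stopifnot(subset_size >= 2, subset_size <= nrow(junctions))
  }
  left <- substr(junctions$sequence, 1L, junctions$junction_offset)
  right <- substr(junctions$sequence, junctions$junction_offset + 1L,
                  nchar(junctions$sequence))
  run <- function() {
    purrr::map_dfr(seq_len(n_sets), function(s) {
      idx <- if (is.null(subset_size)) seq_len(nrow(junctions))
             else sort(sample(nrow(junctions), subset_size))
      perm <- random_derangement(length(idx))
      tibble(set = s,
             left_id = junctions$circ_id[idx],
             right_id = junctions$circ_id[idx][perm],
             sequence = paste0(left[idx], right[idx][perm]))
    })
  }
  with_seed_maybe(seed, run())
}

# uniform random derangement by rejection; forced swap for n = 2
random_derangement <- function(n) {
  if (n < 2) abort("derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Nucleotide-shuffle control sets
#'
#' Each control sequence is a uniform random permutation of the nucleotides
#' of the corresponding input sequence: per-sequence length and base
#' composition are exactly conserved, all positional and k-mer structure is
#' destroyed.
#'
#' @param seqs named character vector, or tibble with an id column
#'   (`circ_id` or `id`) and `sequence`.
#' @param n_sets number of control sets.
#' @param seed integer seed for bit-reproducibility.
#' @return tibble `set`, `id`, `sequence`.
#' @export
shuffle_sequences <- function(seqs, n_sets = 1L, seed = NULL) {
  s <- as_named_seqs(seqs)
  stopifnot(n_sets >= 1)
  run <- function() {
    purrr::map_dfr(seq_len(n_sets), function(k) {
      tibble(set = k, id = names(s),
             sequence = vapply(s, function(x) {
               paste(sample(strsplit(x, "")[[1]]), collapse = "")
             }, character(1), USE.NAMES = FALSE))
    })
  }
  with_seed_maybe(seed, run())
}

#' Intron-length-matched control gene pairing
#'
#' Repeatedly pairs each host gene with a control gene of similar first
#' intron length: per iteration each host draws uniformly among controls
#' whose first-intron length is within `tolerance` relative difference; when
#' no control qualifies, the nearest-length control is used and flagged.
#' Controls may be reused across hosts and iterations.
#'
#' @param hosts tibble with `id` and `intron_length`.
#' @param controls tibble with `id` and `intron_length`.
#' @param n_iter number of pairing iterations (default 1000).
#' @param tolerance relative length tolerance (default 0.1, i.e. +/- 10%).
#' @param seed integer seed.
#' @return tibble `iteration`, `host_id`, `control_id`, `host_intron`,
#'   `control_intron`, `fallback`.
#' @export
pair_by_first_intron <- function(hosts, controls, n_iter = 1000L,
                                 tolerance = 0.1, seed = NULL) {
  if (nrow(hosts) == 0 || nrow(controls) == 0) {
    abort("hosts and controls must be non-empty")
  }
  # candidate control indices per host, fixed across iterations
  cand <- lapply(hosts$intron_length, function(h) {
    ok <- which(abs(controls$intron_length - h) <= tolerance * h)
    if (length(ok) > 0) list(idx = ok, fallback = FALSE)
    else list(idx = which.min(abs(controls$intron_length - h))[1],
              fallback = TRUE)
  })
  run <- function() {
    purrr::map_dfr(seq_len(n_iter), function(it) {
      pick <- vapply(cand, function(cc) {
        if (length(cc$idx) == 1) cc$idx else sample(cc$idx, 1)
      }, integer(1))
      tibble(iteration = it, host_id = hosts$id,
             control_id = controls$id[pick],
             host_intron = hosts$intron_length,
             control_intron = controls$intron_length[pick],
             fallback = vapply(cand, function(cc) cc$fallback, logical(1)))
    })
  }
  with_seed_maybe(seed, run())
}

#' First-intron lengths from an exon table
#'
#' Length of the intron between the rank-1 and rank-2 exons of each
#' transcript (transcript orientation); NA for single-exon transcripts.
#'
#' @param exons exon tibble from [read_gtf()].
#' @return tibble `transcript_id`, `gene_symbol`, `intron_length`.
#' @export
first_intron_lengths <- function(exons) {
  exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_symbol = .data$gene_symbol[1],
      intron_length = {
        if (n() < 2) NA_integer_
        else {
          i1 <- which(.data$exon_rank == 1)
          i2 <- which(.data$exon_rank == 2)
          if (.data$strand[1] == "+") .data$start[i2] - .data$end[i1]
          else .data$start[i1] - .data$end[i2]
        }
      },
      .groups = "drop"
    )
}

#' Detect divergent repeat pairs flanking a back-splice
#'
#' Tests each circRNA for an inverted (divergent) repeat configuration in
#' its intronic flanks: a repeat overlapping the `flank`-bp window upstream
#' of the 5' BS site and one overlapping the window downstream of the 3' BS
#' site (both in transcript orientation), on opposite strands oriented
#' toward each other — the upstream repeat on the circRNA's strand, the
#' downstream one on the opposite strand. Such pairs can base-pair across
#' the circularised region and favour back-splicing.
#'
#' @param circs circRNA tibble (needs `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, and `bs5`/`bs3`; derived when absent).
#' @param repeats repeat tibble from [read_bed()] (stranded BED6).
#' @param flank flank width in bp (default 500).
#' @return tibble `circ_id`, `divergent`, `n_pairs`, with a list-column
#'   `pairs` of the qualifying (upstream, downstream) repeat name pairs.
#' @export
find_divergent_repeat_pairs <- function(circs, repeats, flank = 500L) {
  stopifnot(flank >= 1)
  if (!"bs5" %in% names(circs)) {
    s <- bs_sites(circs$start, circs$end, circs$strand)
    circs$bs5 <- as.integer(s$bs5)
    circs$bs3 <- as.integer(s$bs3)
  }
  one <- function(i) {
    ci <- circs[i, ]
    if (ci$strand == "+") {
      up <- c(ci$bs5 - flank, ci$bs5)        # [bs5 - flank, bs5)
      dn <- c(ci$bs3, ci$bs3 + flank)        # [bs3, bs3 + flank)
    } else {
      up <- c(ci$bs5 + 1L, ci$bs5 + 1L + flank)
      dn <- c(ci$bs3 - flank + 1L, ci$bs3 + 1L)
    }
    ov <- function(iv) repeats[repeats$chrom == ci$chrom &
                                 repeats$start < iv[2] &
                                 repeats$end > iv[1], , drop = FALSE]
    rup <- ov(up)
    rdn <- ov(dn)
    up_ok <- rup[rup$strand == ci$strand, , drop = FALSE]
    dn_ok <- rdn[rdn$strand != ci$strand, , drop = FALSE]
    pairs <- if (nrow(up_ok) > 0 && nrow(dn_ok) > 0) {
      tidyr::expand_grid(upstream = up_ok$name, downstream = dn_ok$name)
    } else {
      tibble(upstream = character(), downstream = character())
    }
    tibble(circ_id = ci$circ_id, divergent = nrow(pairs) > 0,
           n_pairs = nrow(pairs), pairs = list(pairs))
  }
  purrr::map_dfr(seq_len(nrow(circs)), one)
}

#' Count fragments overlapping intervals
#'
#' coverage-style counting: a fragment is counted for an interval when they
#' overlap by at least 1 bp (a fragment spanning two intervals is counted
#' once in each). Chromosomes absent from the fragment set yield 0.
#'
#' @param intervals tibble with `chrom`, `start`, `end` (0-based half-open);
#'   extra columns are carried through.
#' @param fragments tibble with `chrom`, `start`, `end` (e.g. [read_bed()]).
#' @return `intervals` with `read_count` and `per_base`
#'   (= `read_count / (end - start)`) columns appended.
#' @export
count_reads_in_intervals <- function(intervals, fragments) {
  if (nrow(intervals) == 0) {
    return(mutate(intervals, read_count = integer(), per_base = numeric()))
  }
  iv <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  if (nrow(fragments) == 0) {
    cnt <- integer(nrow(intervals))
  } else {
    fr <- GenomicRanges::GRanges(fragments$chrom,
                                 IRanges::IRanges(fragments$start + 1L,
                                                  fragments$end))
    # disjoint chromosome sets are a defined case (count 0), not a warning
    cnt <- suppressWarnings(
      GenomicRanges::countOverlaps(iv, fr, minoverlap = 1L,
                                   ignore.strand = TRUE))
  }
  intervals |>
    mutate(read_count = as.integer(cnt),
           per_base = .data$read_count / (.data$end - .data$start))
}

#' Signal ratio between the 5' circularising exon and its upstream exon
#'
#' For every multiexonic/monoexonic circRNA with `rank5 >= 2`, counts
#' fragments (e.g. H3K36me3 ChIP reads as BED intervals) over the 5'CE and
#' over the exon of rank `rank5 - 1` of the same transcript, normalises to
#' per-base coverage, and scores
#' `(ce5_per_base + pseudocount) / (upstream_per_base + pseudocount)`.
#' circRNAs with `rank5 == 1` have no upstream exon and are skipped with a
#' warning.
#'
#' @param classified classification tibble from [classify_circs()].
#' @param exons exon tibble from [read_gtf()].
#' @param fragments fragment tibble ([read_bed()] schema).
#' @param pseudocount per-base pseudocount (default 0.1) guarding against
#'   empty exons.
#' @return tibble `circ_id`, `transcript_id`, `rank5`, `ce5_per_base`,
#'   `upstream_per_base`, `score`.
#' @export
score_ce5_ratio <- function(classified, exons, fragments, pseudocount = 0.1) {
  el <- filter(classified,
               .data$category %in% c("multiexonic", "monoexonic"))
  if (any(el$rank5 == 1)) {
    warn(sprintf("skipping %d circRNA(s) with rank5 == 1 (no upstream exon)",
                 sum(el$rank5 == 1)))
    el <- filter(el, .data$rank5 > 1)
  }
  if (nrow(el) == 0) {
    return(tibble(circ_id = character(), transcript_id = character(),
                  rank5 = integer(), ce5_per_base = numeric(),
                  upstream_per_base = numeric(), score = numeric()))
  }
  grab <- function(tx, rk) {
    e <- exons[exons$transcript_id == tx & exons$exon_rank == rk, , drop = FALSE]
    count_reads_in_intervals(e, fragments)$per_base
  }
  el |>
    mutate(
      ce5_per_base = purrr::map2_dbl(.data$transcript_id, .data$rank5, grab),
      upstream_per_base = purrr::map2_dbl(.data$transcript_id,
                                          .data$rank5 - 1L, grab),
      score = (.data$ce5_per_base + pseudocount) /
        (.data$upstream_per_base + pseudocount)
    ) |>
    select("circ_id", "transcript_id", "rank5", "ce5_per_base",
           "upstream_per_base", "score")
}

with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(seed, expr, .rng_kind = "Mersenne-Twister",
                        .rng_sample_kind = "Rejection")
}
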