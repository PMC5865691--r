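#' Simulate a toy genome and annotation
#'
#' Generates random chromosome sequences carrying non-overlapping,
#' randomly-stranded multi-exon gene models, laid out left to right with
#' random intergenic gaps. Each gene has a single transcript whose name
#' carries the main-isoform suffix (`<SYMBOL>-001`), so univocal isoform
#' resolution is exercised end to end. Base composition is uniform by
#' default; `gc` skews it to stress k-mer collision behaviour.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length,intergenic_gap bp ranges `c(min, max)`.
#' @param n_chroms number of chromosomes (genes distributed round-robin).
#' @param chrom_length optional fixed chromosome length; an error is raised
#'   before anything is written when the requested genes do not fit.
#'   Default NULL sizes each chromosome to its content plus a tail gap.
#' @param gc GC fraction of the random sequence (default 0.5).
#' @param seed integer seed; the same seed reproduces the reference
#'   byte-identically.
#' @return list of class `circ_reference` with `genome` (`DNAStringSet`) and
#'   `exons` (tibble in the [read_gtf()] schema).
#' @export
simulate_reference <- function(n_genes = 10L, exons_per_gene = c(4L, 8L),
                               exon_length = c(120L, 300L),
                               intron_length = c(200L, 800L),
                               intergenic_gap = c(300L, 800L),
                               n_chroms = 1L, chrom_length = NULL,
                               gc = 0.5, seed = NULL) {
  stopifnot(n_genes >= 1, n_chroms >= 1, gc > 0, gc < 1)
  with_seed_maybe(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    rand_seq <- function(n) {
      paste(sample(names(probs), n, replace = TRUE, prob = probs),
            collapse = "")
    }
    rint <- function(rg) sample(rg[1]:rg[2], 1)
    chrom_of <- rep_len(sprintf("chrS%d", seq_len(n_chroms)), n_genes)
    cursor <- setNames(integer(n_chroms), sprintf("chrS%d", seq_len(n_chroms)))
    exons <- NULL
    for (g in seq_len(n_genes)) {
      chrom <- chrom_of[g]
      gap <- rint(intergenic_gap)
      gstart <- cursor[[chrom]] + gap
      n_ex <- rint(exons_per_gene)
      gstrand <- sample(c("+", "-"), 1)
      pos <- gstart
      estarts <- integer(n_ex)
      eends <- integer(n_ex)
      for (e in seq_len(n_ex)) {
        elen <- rint(exon_length)
        estarts[e] <- pos
        eends[e] <- pos + elen
        pos <- eends[e] + if (e < n_ex) rint(intron_length) else 0L
      }
      cursor[[chrom]] <- pos
      sym <- sprintf("SGENE%02d", g)
      exons <- bind_rows(exons, tibble(
        chrom = chrom, start = estarts, end = eends, strand = gstrand,
        transcript_id = sprintf("SIMT%03d", g),
        transcript_name = paste0(sym, "-001"),
        gene_id = sprintf("SIMG%03d", g), gene_symbol = sym,
        exon_rank = if (gstrand == "+") seq_len(n_ex) else rev(seq_len(n_ex)),
        source_order = g - 1L
      ))
    }
    lens <- cursor + vapply(names(cursor),
                            function(ch) rint(intergenic_gap), integer(1))
    if (!is.null(chrom_length)) {
      if (any(cursor > chrom_length)) {
        abort(sprintf("chromosome length %d too short for requested genes (need %d)",
                      chrom_length, max(cursor)))
      }
      lens[] <- chrom_length
    }
    genome <- Biostrings::DNAStringSet(vapply(lens, rand_seq, character(1)))
    names(genome) <- names(lens)
    exons <- arrange(exons, .data$source_order, .data$exon_rank)
    structure(list(genome = genome, exons = exons), class = "circ_reference")
  })
}

#' @export
print.circ_reference <- function(x, ...) {
  cat(sprintf("simulated reference: %d chromosome(s) (%s bp), %d transcript(s)\n",
              length(x$genome),
              paste(Biostrings::width(x$genome), collapse = ", "),
              length(unique(x$exons$transcript_id))))
  invisible(x)
}

#' Plant circRNAs of known category in a simulated reference
#'
#' Places back-splice events so that classification must recover the
#' requested category: multiexonic at the exact boundaries of two distinct
#' exons, monoexonic on one full exon, putative exonic offset 3 bp inside
#' one exon, intronic with the 5' BS site mid first intron, intergenic fully
#' inside an intergenic gap. Host transcripts are cycled so names stay
#' distinct. The returned truth table records the expected category, ranks
#' and name of every planted event.
#'
#' @param reference a `circ_reference` from [simulate_reference()].
#' @param n_per_category named integer vector over
#'   `multiexonic`, `monoexonic`, `putative_exonic`, `intronic`,
#'   `intergenic` (missing names default to 0).
#' @param seed integer seed.
#' @return tibble: circRNA records (`circ_id` .. `bs3`) plus truth columns
#'   `category`, `transcript_id`, `gene_symbol`, `rank5`, `rank3`, `name`.
#' @export
plant_circrnas <- function(reference,
                           n_per_category = c(multiexonic = 2L,
                                              monoexonic = 2L,
                                              putative_exonic = 2L,
                                              intronic = 2L,
                                              intergenic = 2L),
                           seed = NULL) {
  exons <- reference$exons
  cats <- c("multiexonic", "monoexonic", "putative_exonic", "intronic",
            "intergenic")
  want <- setNames(integer(5), cats)
  want[names(n_per_category)] <- as.integer(n_per_category)
  spans <- transcript_spans(exons)
  with_seed_maybe(seed, {
    txs <- spans$transcript_id
    tx_cursor <- 0L
    next_tx <- function(min_exons) {
      for (step in seq_along(txs)) {
        tx_cursor <<- tx_cursor %% length(txs) + 1L
        if (spans$n_exons[tx_cursor] >= min_exons) return(txs[tx_cursor])
      }
      NULL
    }
    gaps <- intergenic_gaps(reference)
    gap_cursor <- 0L
    rows <- list()
    idx <- 0L
    for (cat in cats) {
      for (j in seq_len(want[[cat]])) {
        idx <- idx + 1L
        cid <- sprintf("CIRC%03d", idx)
        if (cat == "intergenic") {
          if (nrow(gaps) == 0) abort("no intergenic gap can host category intergenic")
          gap_cursor <- gap_cursor %% nrow(gaps) + 1L
          gp <- gaps[gap_cursor, ]
          mid <- floor((gp$start + gp$end) / 2)
          rows[[idx]] <- tibble(
            circ_id = cid, chrom = gp$chrom,
            start = as.integer(mid - 75), end = as.integer(mid + 75),
            strand = sample(c("+", "-"), 1), category = cat,
            transcript_id = NA_character_, gene_symbol = NA_character_,
            rank5 = NA_integer_, rank3 = NA_integer_)
          next
        }
        tx <- next_tx(if (cat == "monoexonic") 1L
                      else if (cat == "putative_exonic") 1L else 2L)
        if (is.null(tx)) {
          abort(sprintf("gene structure cannot host category %s", cat))
        }
        te <- exons[exons$transcript_id == tx, ]
        te <- te[order(te$exon_rank), ]
        strand <- te$strand[1]
        mk <- function(start, end, r5, r3) {
          tibble(circ_id = cid, chrom = te$chrom[1],
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, category = cat, transcript_id = tx,
                 gene_symbol = te$gene_symbol[1],
                 rank5 = as.integer(r5), rank3 = as.integer(r3))
        }
        n_ex <- nrow(te)
        rows[[idx]] <- switch(cat,
          multiexonic = {
            r5 <- resample(seq_len(n_ex - 1))
            r3 <- resample((r5 + 1):n_ex)
            e5 <- te[te$exon_rank == r5, ]
            e3 <- te[te$exon_rank == r3, ]
            if (strand == "+") mk(e5$start, e3$end, r5, r3)
            else mk(e3$start, e5$end, r5, r3)
          },
          monoexonic = {
            r <- resample(seq_len(n_ex))
            e <- te[te$exon_rank == r, ]
            mk(e$start, e$end, r, r)
          },
          putative_exonic = {
            r <- resample(seq_len(n_ex))
            e <- te[te$exon_rank == r, ]
            mk(e$start + 3L, e$end - 3L, NA, NA)
          },
          intronic = {
            # 5' BS site mid first intron (transcript orientation)
            e1 <- te[te$exon_rank == 1, ]
            e2 <- te[te$exon_rank == 2, ]
            elast <- te[te$exon_rank == n_ex, ]
            if (strand == "+") {
              m <- floor((e1$end + e2$start) / 2)
              mk(m, elast$end, NA, NA)
            } else {
              m <- floor((e2$end + e1$start) / 2)
              mk(elast$start, m + 1L, NA, NA)
            }
          })
      }
    }
    out <- bind_rows(rows)
    if (nrow(out) == 0) {
      return(tibble(circ_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    bs5 = integer(), bs3 = integer(), category = character(),
                    transcript_id = character(), gene_symbol = character(),
                    rank5 = integer(), rank3 = integer(), name = character()))
    }
    s <- bs_sites(out$start, out$end, out$strand)
    out$bs5 <- as.integer(s$bs5)
    out$bs3 <- as.integer(s$bs3)
    out$name <- name_circrna(out)
    out[, c("circ_id", "chrom", "start", "end", "strand", "bs5", "bs3",
            "category", "transcript_id", "gene_symbol", "rank5", "rank3",
            "name")]
  })
}

# intergenic gaps (between and around transcript spans) wide enough to host
# a 150-bp event with margin
intergenic_gaps <- function(reference, min_width = 250L) {
  spans <- transcript_spans(reference$exons)
  out <- NULL
  for (ch in names(reference$genome)) {
    len <- length(reference$genome[[ch]])
    sp <- spans[spans$chrom == ch, ]
    sp <- sp[order(sp$start), ]
    edges <- sort(c(0L, sp$start, sp$end, len))
    starts <- edges[seq(1, length(edges), by = 2)]
    ends <- edges[seq(2, length(edges), by = 2)]
    keep <- ends - starts >= min_width
    if (any(keep)) {
      out <- bind_rows(out, tibble(chrom = ch, start = starts[keep],
                                   end = ends[keep]))
    }
  }
  out %||% tibble(chrom = character(), start = integer(), end = integer())
}

#' Simulate sequencing reads with known per-junction truth
#'
#' Emits three read classes: (a) back-splice reads — windows of the rotated
#' circle sequence crossing the BS point at uniformly random offsets,
#' exactly `bs_depth` per circRNA, each side of the junction covered by at
#' least `min_side_overlap` bases; (b) linear reads — windows of the spliced
#' transcript sequence, never crossing a back-splice; (c) background reads —
#' uniform random sequence. Substitution errors are applied i.i.d. per base
#' at `error_rate`. Read names carry provenance
#' (`<class>:<origin>:<offset>:<serial>`), so truth reconciliation needs no
#' auxiliary file.
#'
#' @param reference `circ_reference` from [simulate_reference()].
#' @param circs planted circRNA tibble from [plant_circrnas()] (or any
#'   circRNA tibble); may be empty for a linear-only sample.
#' @param bs_depth BS-spanning reads per circRNA.
#' @param linear_depth linear reads per transcript.
#' @param n_background background reads.
#' @param read_length read length in nt (must not exceed any circ span).
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param min_side_overlap minimum bases on each side of the BS point
#'   (default 1 = any crossing window).
#' @param linear_transcripts transcripts to draw linear reads from (default
#'   all).
#' @param seed integer seed.
#' @return list with `reads` (tibble `read_id`, `sequence`, `class`,
#'   `origin`) and `truth` (tibble `circ_id`, `true_count`).
#' @export
simulate_reads <- function(reference, circs, bs_depth = 5L, linear_depth = 0L,
                           n_background = 0L, read_length = 50L,
                           error_rate = 0, min_side_overlap = 1L,
                           linear_transcripts = NULL, seed = NULL) {
  stopifnot(read_length >= 2, error_rate >= 0, error_rate < 1,
            min_side_overlap >= 1,
            2 * min_side_overlap <= read_length)
  with_seed_maybe(seed, {
    reads <- list()
    serial <- 0L
    add <- function(class, origin, offset, sequence) {
      serial <<- serial + 1L
      reads[[serial]] <<- tibble(
        read_id = sprintf("%s:%s:%d:%05d", class, origin, offset, serial),
        sequence = sequence, class = class, origin = origin)
    }
    if (nrow(circs) > 0 && bs_depth > 0) {
      too_short <- circs$end - circs$start < read_length
      if (any(too_short)) {
        abort(sprintf("circ span shorter than read_length for: %s",
                      paste(circs$circ_id[too_short], collapse = ", ")))
      }
      for (i in seq_len(nrow(circs))) {
        s <- fetch_sequence(reference$genome, circs$chrom[i], circs$start[i],
                            circs$end[i], circs$strand[i], orient = TRUE)
        n <- nchar(s)
        for (d in seq_len(bs_depth)) {
          a <- resample(min_side_overlap:(read_length - min_side_overlap))
          rd <- paste0(substr(s, n - a + 1L, n),
                       substr(s, 1L, read_length - a))
          add("bs", circs$circ_id[i], a, rd)
        }
      }
    }
    if (linear_depth > 0) {
      txs <- linear_transcripts %||% unique(reference$exons$transcript_id)
      for (tx in txs) {
        sp <- spliced_sequence(reference, tx)
        if (nchar(sp) < read_length) next
        for (d in seq_len(linear_depth)) {
          p <- sample(nchar(sp) - read_length + 1L, 1)
          add("lin", tx, p, substr(sp, p, p + read_length - 1L))
        }
      }
    }
    if (n_background > 0) {
      for (d in seq_len(n_background)) {
        add("bg", "na", d,
            paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                  collapse = ""))
      }
    }
    out <- if (length(reads) > 0) bind_rows(reads) else
      tibble(read_id = character(), sequence = character(),
             class = character(), origin = character())
    if (error_rate > 0 && nrow(out) > 0) {
      out$sequence <- vapply(out$sequence, apply_substitutions,
                             character(1), rate = error_rate,
                             USE.NAMES = FALSE)
    }
    truth <- if (nrow(circs) > 0) {
      tibble(circ_id = circs$circ_id,
             true_count = if (bs_depth > 0) as.integer(bs_depth) else 0L)
    } else tibble(circ_id = character(), true_count = integer())
    list(reads = out, truth = truth)
  })
}

# sample() treats a scalar first argument as 1:n; this keeps length-1 pools
resample <- function(x) x[sample.int(length(x), 1)]

apply_substitutions <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (p in hit) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Spliced transcript sequence
#'
#' Concatenation of the exon sequences in rank order, 5'->3' in transcript
#' orientation.
#'
#' @param reference `circ_reference`.
#' @param transcript_id transcript to splice.
#' @return a single character string.
#' @export
spliced_sequence <- function(reference, transcript_id) {
  te <- reference$exons[reference$exons$transcript_id == transcript_id, ]
  if (nrow(te) == 0) abort(sprintf("unknown transcript: %s", transcript_id))
  te <- te[order(te$exon_rank), ]
  paste(vapply(seq_len(nrow(te)), function(i) {
    fetch_sequence(reference$genome, te$chrom[i], te$start[i], te$end[i],
                   te$strand[i], orient = TRUE)
  }, character(1)), collapse = "")
}

#' Write a complete simulated dataset to disk
#'
#' Materialises a reference, planted circRNAs and one or more read samples
#' as plain files: `genome.fa`, `ann.gtf`, `circs.tsv` (BED dialect),
#' `reads_<sample>.fq.gz` and `truth.tsv`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_samples number of FASTQ samples (seeds derived from `seed`).
#' @param seed master integer seed.
#' @param ... passed on to [simulate_reference()], [plant_circrnas()] and
#'   [simulate_reads()] (matched by name).
#' @return invisible list of written paths.
#' @export
simulate_dataset <- function(out_dir, n_samples = 1L, seed = 1L, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- do.call(simulate_reference,
                 c(take(simulate_reference), list(seed = seed)))
  circs <- do.call(plant_circrnas,
                   c(list(reference = ref), take(plant_circrnas),
                     list(seed = seed + 1L)))
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "ann.gtf"),
    circs = file.path(out_dir, "circs.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  write_gtf(ref$exons, paths$gtf)
  write_circ_bed(circs, paths$circs)
  truth_all <- NULL
  for (s in seq_len(n_samples)) {
    sim <- do.call(simulate_reads,
                   c(list(reference = ref, circs = circs),
                     take(simulate_reads), list(seed = seed + 1L + s)))
    fq <- file.path(out_dir, sprintf("reads_sample%d.fq.gz", s))
    write_fastq(sim$reads, fq)
    paths[[sprintf("sample%d", s)]] <- fq
    truth_all <- bind_rows(truth_all,
                           mutate(sim$truth, sample = sprintf("sample%d", s)))
  }
  readr::write_tsv(circs, paths$truth)
  if (!is.null(truth_all)) {
    readr::write_tsv(truth_all, file.path(out_dir, "truth_counts.tsv"))
    paths$truth_counts <- file.path(out_dir, "truth_counts.tsv")
  }
  invisible(paths)
}
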