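make_junctions <- function(n, len = 70, seed = 61) {
  withr::with_seed(seed, {
    tibble::tibble(circ_id = sprintf("j%03d", 1:n),
                   sequence = vapply(1:n, function(i) rand_dna(len),
                                     character(1)),
                   junction_offset = as.integer(len / 2))
  })
}

test_that("half permutation conserves half multisets and avoids identities", {
  jn <- make_junctions(12)
  out <- permute_halves(jn, n_sets = 5, seed = 7)
  left <- substr(jn$sequence, 1, jn$junction_offset)
  right <- substr(jn$sequence, jn$junction_offset + 1, nchar(jn$sequence))
  for (s in split(out, out$set)) {
    expect_equal(nrow(s), nrow(jn))
    expect_equal(sort(substr(s$sequence, 1, 35)), sort(left))
    expect_equal(sort(substr(s$sequence, 36, 70)), sort(right))
    # derangement: the right half never comes from the same junction
    expect_false(any(s$left_id == s$right_id))
    expect_false(any(s$sequence %in% jn$sequence))
  }
  # reproducibility and RNG isolation
  expect_identical(permute_halves(jn, n_sets = 5, seed = 7), out)
  # two junctions force the single swap
  two <- permute_halves(jn[1:2, ], seed = 1)
  expect_equal(two$right_id, rev(two$left_id))
  expect_error(permute_halves(jn[1, ]), "at least 2")
})

test_that("subsetting before permutation yields sets of the requested size", {
  jn <- make_junctions(20)
  out <- permute_halves(jn, n_sets = 3, subset_size = 8, seed = 99)
  expect_equal(as.integer(table(out$set)), rep(8L, 3))
})

test_that("nucleotide shuffling conserves per-sequence composition", {
  jn <- make_junctions(6, len = 40)
  out <- shuffle_sequences(jn, n_sets = 4, seed = 3)
  expect_equal(nrow(out), 24L)
  comp <- function(s) sort(strsplit(s, "")[[1]])
  for (i in seq_len(nrow(out))) {
    orig <- jn$sequence[jn$circ_id == out$id[i]]
    expect_equal(comp(out$sequence[i]), comp(orig))
  }
  expect_identical(shuffle_sequences(jn, n_sets = 4, seed = 3), out)
  # worked case: composition preserved exactly
  one <- shuffle_sequences(c(x = "AAAACCC"), seed = 5)
  expect_equal(nchar(one$sequence), 7L)
  expect_equal(comp(one$sequence), comp("AAAACCC"))
})

test_that("shuffled controls share no long k-mers with their originals", {
  jn <- make_junctions(10)
  out <- shuffle_sequences(jn, n_sets = 2, seed = 11)
  p <- hashcirc_params(k = 26, stranded = TRUE)
  idx <- build_kmer_index(jn, p)
  shared <- vapply(out$sequence, shared_kmers_oracle, integer(1),
                   kset = idx$kmers, k = 26, USE.NAMES = FALSE)
  expect_equal(mean(shared), 0)
})

test_that("intron-length pairing respects tolerance with nearest fallback", {
  hosts <- tibble::tibble(id = "h1", intron_length = 1000)
  controls <- tibble::tibble(id = c("near", "far"),
                             intron_length = c(950, 5000))
  got <- pair_by_first_intron(hosts, controls, n_iter = 50, seed = 2)
  expect_true(all(got$control_id == "near"))
  expect_false(any(got$fallback))
  # no qualifying candidate -> nearest, flagged
  got2 <- pair_by_first_intron(hosts,
                               tibble::tibble(id = "far",
                                              intron_length = 5000),
                               n_iter = 5, seed = 2)
  expect_true(all(got2$control_id == "far"))
  expect_true(all(got2$fallback))
})

test_that("pairing frequencies follow the uniform candidate distribution", {
  hosts <- tibble::tibble(id = sprintf("h%d", 1:10),
                          intron_length = rep(1000, 10))
  controls <- tibble::tibble(id = sprintf("c%d", 1:4),
                             intron_length = c(950, 1000, 1050, 9000))
  got <- pair_by_first_intron(hosts, controls, n_iter = 1000, seed = 8)
  expect_equal(nrow(got), 10000L)
  freq <- prop.table(table(got$control_id))
  # three qualifying controls drawn uniformly; binomial 4-sigma envelope
  expect_false("c4" %in% names(freq))
  sigma <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq - 1 / 3) < 4 * sigma))
})

test_that("divergent repeat pairs require opposite strands facing the circ", {
  circ <- toy_circ(2000, 3000, "+")
  mk_rep <- function(start, end, strand, name) {
    tibble::tibble(chrom = "chrT", start = start, end = end, name = name,
                   score = 0, strand = strand)
  }
  up_plus <- mk_rep(1600, 1900, "+", "aluUp")
  dn_minus <- mk_rep(3100, 3400, "-", "aluDn")
  got <- find_divergent_repeat_pairs(circ, rbind(up_plus, dn_minus),
                                     flank = 500)
  expect_true(got$divergent)
  expect_equal(got$pairs[[1]]$upstream, "aluUp")
  # same strand on both flanks -> no inverted pair
  got2 <- find_divergent_repeat_pairs(
    circ, rbind(up_plus, mk_rep(3100, 3400, "+", "aluDn")), flank = 500)
  expect_false(got2$divergent)
  # minus-strand circ mirrors the geometry
  circm <- toy_circ(2000, 3000, "-")
  gotm <- find_divergent_repeat_pairs(
    circm, rbind(mk_rep(3100, 3400, "-", "up"), mk_rep(1600, 1900, "+", "dn")),
    flank = 500)
  expect_true(gotm$divergent)
})

test_that("divergent-pair calls agree with a brute-force orientation check", {
  withr::with_seed(71, {
    circs <- purrr::map_dfr(1:100, function(i) {
      st <- sample(2000:20000, 1)
      toy_circ(st, st + sample(200:2000, 1), sample(c("+", "-"), 1),
               id = sprintf("c%03d", i))
    })
    reps <- tibble::tibble(
      chrom = "chrT",
      start = sample(0:25000, 300, replace = TRUE)) |>
      dplyr::mutate(end = start + sample(50:400, 300, replace = TRUE),
                    name = sprintf("r%03d", 1:300), score = 0,
                    strand = sample(c("+", "-"), 300, replace = TRUE))
  })
  got <- find_divergent_repeat_pairs(circs, reps, flank = 500)
  for (i in seq_len(nrow(circs))) {
    ci <- circs[i, ]
    if (ci$strand == "+") {
      up <- c(ci$bs5 - 500, ci$bs5); dn <- c(ci$bs3, ci$bs3 + 500)
    } else {
      up <- c(ci$bs5 + 1, ci$bs5 + 501); dn <- c(ci$bs3 - 499, ci$bs3 + 1)
    }
    hit <- FALSE
    for (a in seq_len(nrow(reps))) {
      for (b in seq_len(nrow(reps))) {
        if (reps$start[a] < up[2] && reps$end[a] > up[1] &&
            reps$start[b] < dn[2] && reps$end[b] > dn[1] &&
            reps$strand[a] == ci$strand && reps$strand[b] != ci$strand) {
          hit <- TRUE
        }
      }
    }
    expect_equal(got$divergent[i], hit)
  }
})

test_that("interval read counting equals the O(nm) overlap oracle", {
  # worked cases
  exon <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  frags <- tibble::tibble(chrom = "chr1", start = c(150L, 300L),
                          end = c(160L, 310L))
  got <- count_reads_in_intervals(exon, frags)
  expect_equal(got$read_count, 1L)
  expect_equal(got$per_base, 0.01)
  # a fragment spanning two intervals counts once in each
  two <- tibble::tibble(chrom = "chr1", start = c(100L, 200L),
                        end = c(200L, 300L))
  span <- tibble::tibble(chrom = "chr1", start = 190L, end = 210L)
  expect_equal(count_reads_in_intervals(two, span)$read_count, c(1L, 1L))
  # absent chromosome -> zero
  expect_equal(count_reads_in_intervals(
    tibble::tibble(chrom = "chrZ", start = 0L, end = 10L), frags)$read_count,
    0L)
  # randomised equivalence
  withr::with_seed(83, {
    iv <- tibble::tibble(chrom = sample(c("c1", "c2"), 400, TRUE),
                         start = sample(0:5000, 400, TRUE)) |>
      dplyr::mutate(end = start + sample(1:200, 400, TRUE))
    fr <- tibble::tibble(chrom = sample(c("c1", "c2"), 600, TRUE),
                         start = sample(0:5000, 600, TRUE)) |>
      dplyr::mutate(end = start + sample(1:200, 600, TRUE))
  })
  expect_equal(count_reads_in_intervals(iv, fr)$read_count,
               overlap_count_oracle(iv, fr))
})

test_that("5'CE signal ratio follows the pseudocount formula and ranking", {
  ex <- toy_exons()
  # fragments concentrated on CDYL exon 2 (the 5'CE of a rank-2 circ)
  frags <- tibble::tibble(chrom = "chrT",
                          start = as.integer(seq(800, 880, by = 10))) |>
    dplyr::mutate(end = start + 30L)
  classified <- classify_circs(
    toy_circ(800, 1500, "+", id = "r2circ"), ex)
  expect_equal(classified$rank5, 2L)
  got <- score_ce5_ratio(classified, ex, frags, pseudocount = 0.1)
  ce5 <- count_reads_in_intervals(
    dplyr::filter(ex, transcript_id == "TX_CDYL", exon_rank == 2), frags)
  up <- count_reads_in_intervals(
    dplyr::filter(ex, transcript_id == "TX_CDYL", exon_rank == 1), frags)
  expect_equal(got$score, (ce5$per_base + 0.1) / (up$per_base + 0.1))
  # upstream signal zero: score = (x + eps) / eps
  expect_equal(up$read_count, 0L)
  # equal signals give exactly 1
  eq <- score_ce5_ratio(classified, ex,
                        tibble::tibble(chrom = "chrT", start = c(510L, 810L),
                                       end = c(520L, 820L)))
  expect_equal(eq$score, 1)
  # rank-1 circs are skipped with a warning
  r1 <- classify_circs(toy_circ(500, 1500, "+", id = "r1circ"), ex)
  expect_warning(none <- score_ce5_ratio(r1, ex, frags), "rank5 == 1")
  expect_equal(nrow(none), 0L)
})

test_that("ranking by signal ratio matches brute-force recomputation", {
  ref <- shared_ref()
  circs <- plant_circrnas(ref, c(multiexonic = 6L), seed = 91)
  classified <- classify_circs(circs, ref$exons)
  classified <- dplyr::filter(classified, rank5 > 1)
  withr::with_seed(93, {
    frags <- tibble::tibble(
      chrom = names(ref$genome)[1],
      start = sample(0:(length(ref$genome[[1]]) - 60), 800, TRUE)) |>
      dplyr::mutate(end = start + 50L)
  })
  got <- score_ce5_ratio(classified, ref$exons, frags)
  manual <- vapply(seq_len(nrow(classified)), function(i) {
    tx <- classified$transcript_id[i]
    e5 <- ref$exons[ref$exons$transcript_id == tx &
                      ref$exons$exon_rank == classified$rank5[i], ]
    eu <- ref$exons[ref$exons$transcript_id == tx &
                      ref$exons$exon_rank == classified$rank5[i] - 1, ]
    pb <- function(e) overlap_count_oracle(e, frags) / (e$end - e$start)
    (pb(e5) + 0.1) / (pb(eu) + 0.1)
  }, numeric(1))
  expect_equal(got$score, manual)
  expect_equal(order(got$score), order(manual))
})
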