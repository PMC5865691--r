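# Independent oracles, deliberately naive: these re-derive expectations by
# brute force and must not share code paths with the implementation.

# textbook local alignment DP with affine gaps; gap of length g costs
# open + (g - 1) * extend (same convention as the package scoring)
sw_oracle <- function(a, b, match = 2, mismatch = 2, open = 3, extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0L)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  as.integer(best)
}

# brute-force k-mer set of a sequence collection (forward strand only)
kmer_set_oracle <- function(seqs, k) {
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) out <- c(out, substr(s, i, i + k - 1))
  }
  unique(out[!grepl("N", out)])
}

# brute-force count of read k-mer positions present in a k-mer set
shared_kmers_oracle <- function(read, kset, k) {
  n <- nchar(read)
  if (n < k) return(0L)
  cnt <- 0L
  for (i in 1:(n - k + 1)) {
    if (substr(read, i, i + k - 1) %in% kset) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive no-filter quantification: align every read against every
# reference (both strands), best hit, ties to smallest id, count when >= M
exhaustive_count_oracle <- function(read_seqs, refs, M,
                                    match = 2, mismatch = 2,
                                    open = 3, extend = 1,
                                    sw_fun = sw_oracle) {
  ids <- sort(names(refs))
  counts <- setNames(integer(length(ids)), ids)
  for (rd in read_seqs) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
    best_id <- NA_character_; best_s <- -1L
    for (id in ids) {
      s <- max(sw_fun(rd, refs[[id]], match, mismatch, open, extend),
               sw_fun(rc, refs[[id]], match, mismatch, open, extend))
      if (s > best_s) { best_s <- s; best_id <- id }
    }
    if (best_s >= M) counts[[best_id]] <- counts[[best_id]] + 1L
  }
  counts
}

# O(n*m) interval/fragment overlap counting
overlap_count_oracle <- function(intervals, fragments) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(fragments$chrom == intervals$chrom[i] &
          fragments$start < intervals$end[i] &
          fragments$end > intervals$start[i])
  }, integer(1))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# expose shared k-mer counts through the public selection API
shared_kmer_counts_via_select <- function(seqs, idx, p) {
  reads <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                          sequence = seqs)
  p0 <- hashcirc_params(k = p$k, N = 0, stranded = p$stranded)
  sel <- circkit::select_reads(reads, idx, p0)
  out <- integer(length(seqs))
  out[match(sel$read_id, reads$read_id)] <- sel$shared_kmers
  out
}
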