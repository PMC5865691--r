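# Hand-built two-gene annotation on a small random genome, used by the
# classification and junction tests. Gene symbols follow well-known circRNA
# host genes so the nomenclature cases are read off directly.
#
#   CDYL  : + strand, 5 exons of 100 bp starting at 500, introns 200 bp
#   MAN1A2: - strand, 6 exons of 80 bp starting at 3000, introns 150 bp
toy_exons <- function() {
  cdyl_starts <- 500 + (0:4) * 300
  man_starts <- 3000 + (0:5) * 230
  dplyr::bind_rows(
    tibble::tibble(
      chrom = "chrT", start = as.integer(cdyl_starts),
      end = as.integer(cdyl_starts + 100), strand = "+",
      transcript_id = "TX_CDYL", transcript_name = "CDYL-001",
      gene_id = "G_CDYL", gene_symbol = "CDYL",
      exon_rank = 1:5, source_order = 0L),
    tibble::tibble(
      chrom = "chrT", start = as.integer(man_starts),
      end = as.integer(man_starts + 80), strand = "-",
      transcript_id = "TX_MAN1A2", transcript_name = "MAN1A2-001",
      gene_id = "G_MAN1A2", gene_symbol = "MAN1A2",
      exon_rank = 6:1, source_order = 1L)
  )
}

toy_genome <- function(len = 6000, seed = 424) {
  withr::with_seed(seed, {
    g <- Biostrings::DNAStringSet(rand_dna(len))
    names(g) <- "chrT"
    g
  })
}

# one-row circ record tibble with derived BS sites
toy_circ <- function(start, end, strand, id = "c1", chrom = "chrT") {
  bs5 <- if (strand == "+") start else end - 1L
  bs3 <- if (strand == "+") end - 1L else start
  tibble::tibble(circ_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 bs5 = as.integer(bs5), bs3 = as.integer(bs3),
                 junction_reads = NA_integer_)
}

# shared simulated reference for the heavier tests (built once per run)
shared_ref <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- circkit::simulate_reference(n_genes = 8, seed = 101)
    }
    val
  }
})
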