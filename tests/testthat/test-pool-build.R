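# A tiny genome with sequence for exact-match pool building.
seq_genome <- function() {
  fixture("seq_genome", function() {
    sim_genome(4, 6000, seed = 17, gene_length = c(800, 1200),
               sequence = TRUE)
  })
}

frag_at <- function(genome, pos, len = 30, revcomp = FALSE) {
  s <- substr(genome$sequence[[1]], pos, pos + len - 1)
  if (revcomp) {
    s <- chartr("ACGT", "TGCA", s)
    s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }
  s
}

test_that("consistent reads are retained at their mapped location", {
  g <- seq_genome()
  reads <- tibble::tibble(
    barcode = rep("AAAACCCCGGGGTTTTACGT", 3),
    fragment = rep(frag_at(g, 1500), 3)
  )
  pool <- build_pool_from_tnseq(reads, g)
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$pos, 1500L)
  expect_equal(pool$strand, "+")
})

test_that("reverse-complement fragments map with minus strand", {
  g <- seq_genome()
  reads <- tibble::tibble(
    barcode = rep("CCCCAAAATTTTGGGGACGT", 2),
    fragment = rep(frag_at(g, 2200, revcomp = TRUE), 2)
  )
  pool <- build_pool_from_tnseq(reads, g)
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$pos, 2200L)
  expect_equal(pool$strand, "-")
})

test_that("split locations and singleton barcodes are dropped", {
  g <- seq_genome()
  reads <- tibble::tibble(
    barcode = c("A", "A", "B") |> vapply(strrep, character(1), 20),
    fragment = c(frag_at(g, 1000), frag_at(g, 3000), frag_at(g, 2000))
  )
  pool <- build_pool_from_tnseq(reads, g, min_reads = 2,
                                majority_fraction = 0.75)
  expect_equal(nrow(pool), 0L)
  expect_equal(attr(pool, "n_dropped_barcodes"), 2L)
})

test_that("majority agreement at three of four reads retains the barcode", {
  g <- seq_genome()
  bc <- strrep("G", 20)
  reads <- tibble::tibble(
    barcode = rep(bc, 4),
    fragment = c(rep(frag_at(g, 1200), 3), frag_at(g, 4000))
  )
  pool <- build_pool_from_tnseq(reads, g)
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$pos, 1200L)
})

test_that("multi-mapping fragments are discarded as ambiguous", {
  g <- seq_genome()
  # plant an exact repeat so the fragment matches two positions
  s <- g$sequence[[1]]
  rep_frag <- substr(s, 500, 529)
  substr(s, 5000, 5029) <- rep_frag
  g$sequence[[1]] <- s
  reads <- tibble::tibble(barcode = rep(strrep("T", 20), 2),
                          fragment = rep(rep_frag, 2))
  pool <- build_pool_from_tnseq(reads, g)
  expect_equal(nrow(pool), 0L)
  expect_equal(attr(pool, "n_ambiguous"), 2L)
})

test_that("retained barcodes are annotated like simulated pools", {
  g <- seq_genome()
  gene <- g$genes[1, ]
  mid <- as.integer((gene$start + gene$end) / 2)
  reads <- tibble::tibble(barcode = rep(strrep("C", 20), 2),
                          fragment = rep(frag_at(g, mid), 2))
  pool <- build_pool_from_tnseq(reads, g)
  ref <- annotate_insertions(g, gene$scaffold, mid)
  expect_equal(pool$locus_tag, ref$locus_tag)
  expect_equal(pool$gene_fraction, ref$gene_fraction)
  expect_equal(pool$central, ref$central)
})
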