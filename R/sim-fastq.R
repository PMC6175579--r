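#' Emit synthetic BarSeq FASTQ files from a count matrix
#'
#' Writes one FASTQ file per sample containing exactly the reads implied by
#' the count matrix: each barcode appears in as many reads as its count. A
#' read is a random 5' pad (length drawn from the layout's allowed offsets),
#' the pre-barcode flank, the barcode, the post-barcode flank, and a random
#' 3' pad filling the read out to `layout$read_length`; qualities are fixed
#' at "I". Reads are shuffled within each file. Running
#' [extract_barcodes()] on the output reproduces the counts exactly.
#'
#' @param counts A [count_matrix()].
#' @param pool A `pool_table`; every barcode in `counts` must be present.
#' @param layout A [read_layout()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for pads and read order.
#' @return Invisibly, a named character vector of written FASTQ paths.
#' @examples
#' \donttest{
#' g <- sim_genome(5, 2e4, seed = 1)
#' d <- sim_design(conditions = "alone", timepoints = "day1",
#'                 replicates = 1, depth = 200)
#' tr <- sim_truth(g, d, fractions = NULL, seed = 1)
#' cm <- sim_counts(sim_pool(g, 50, seed = 1), tr, d, genome = g)
#' paths <- write_barseq_fastq(cm, sim_pool(g, 50, seed = 1),
#'                             dir = tempfile(), seed = 1)
#' }
#' @export
write_barseq_fastq <- function(counts, pool, layout = read_layout(),
                               dir = ".", seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_pool(pool)
  missing_bc <- setdiff(rownames(counts$counts), pool$barcode)
  if (length(missing_bc)) {
    abort(sprintf("%d barcode(s) in counts are absent from the pool.",
                  length(missing_bc)))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  bases <- c("A", "C", "G", "T")
  paths <- setNames(
    file.path(dir, paste0(counts$samples$sample, ".fastq")),
    counts$samples$sample
  )
  with_seed(seed, {
    for (smp in counts$samples$sample) {
      cnt <- counts$counts[, smp]
      bc <- rep(rownames(counts$counts), times = cnt)
      n_reads <- length(bc)
      rec <- character(0)
      if (n_reads > 0) {
        bc <- sample(bc)
        pad5_len <- sample(layout$offsets, n_reads, replace = TRUE)
        pad5 <- vapply(pad5_len, function(k) {
          if (k == 0) "" else paste(sample(bases, k, replace = TRUE),
                                    collapse = "")
        }, character(1))
        core <- paste0(pad5, layout$preseq, bc, layout$postseq)
        pad3_len <- pmax(layout$read_length - nchar(core), 0L)
        pad3 <- vapply(pad3_len, function(k) {
          if (k == 0) "" else paste(sample(bases, k, replace = TRUE),
                                    collapse = "")
        }, character(1))
        seqs <- paste0(core, pad3)
        qual <- strrep("I", nchar(seqs))
        rec <- paste0("@", smp, ":", seq_len(n_reads), "\n", seqs,
                      "\n+\n", qual)
      }
      writeLines(rec, paths[[smp]])
    }
  })
  invisible(paths)
}
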