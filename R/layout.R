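#' Describe the layout of a BarSeq read
#'
#' A BarSeq read carries a random transposon barcode flanked by fixed vector
#' sequence: some leading bases, the pre-barcode flank (`preseq`), the barcode
#' itself, then the post-barcode flank (`postseq`). Barcode extraction searches
#' for `preseq` at each allowed offset and reads the following
#' `barcode_length` bases as the barcode. Defaults correspond to the flanks of
#' the pKMW7-style Tn5 barcode cassette (20 nt barcodes) but every field is
#' configurable because the flanks depend on the sequencing primer design.
#'
#' @param preseq Fixed sequence immediately 5' of the barcode (ACGT string).
#' @param postseq Fixed sequence immediately 3' of the barcode (ACGT string).
#' @param barcode_length Barcode length in nucleotides (default 20).
#' @param offsets Integer vector of allowed 0-based read offsets at which
#'   `preseq` may start (default `0:8`, mimicking the variable-length phasing
#'   pad used in BarSeq primers).
#' @param read_length Total read length used when synthesising FASTQ reads
#'   (default 60).
#' @return A `read_layout` object (a named list).
#' @examples
#' read_layout()
#' @export
read_layout <- function(preseq = "GTCGACCTGCAGCGTACG",
                        postseq = "AGAGACC",
                        barcode_length = 20L,
                        offsets = 0:8,
                        read_length = 60L) {
  for (s in c(preseq = preseq, postseq = postseq)) {
    if (!is.character(s) || length(s) != 1L || nchar(s) < 1L ||
        grepl("[^ACGT]", s)) {
      abort("`preseq` and `postseq` must be non-empty ACGT strings.")
    }
  }
  assert_scalar_number(barcode_length, "barcode_length", lower = 1)
  if (!is.numeric(offsets) || any(offsets < 0)) {
    abort("`offsets` must be non-negative integers.")
  }
  min_len <- max(offsets) + nchar(preseq) + barcode_length + nchar(postseq)
  if (read_length < min_len) {
    abort(sprintf(
      "`read_length` (%d) too short for layout (needs >= %d).",
      as.integer(read_length), as.integer(min_len)
    ))
  }
  structure(
    list(
      preseq = preseq, postseq = postseq,
      barcode_length = as.integer(barcode_length),
      offsets = as.integer(sort(unique(offsets))),
      read_length = as.integer(read_length)
    ),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat("<read_layout> ", x$preseq, "[N", x$barcode_length, "]", x$postseq,
      " offsets ", paste(range(x$offsets), collapse = "-"),
      ", read length ", x$read_length, "\n", sep = "")
  invisible(x)
}
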