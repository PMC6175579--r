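#' Extract transposon barcodes from BarSeq reads
#'
#' Scans each read for the pre-barcode flank at every allowed offset (exact
#' match, lowest offset wins). When the flank is found, the following
#' `barcode_length` bases must all be A/C/G/T and must be followed by an
#' exact match to the post-barcode flank (or to as much of it as remains in
#' the read). Reads failing any of these checks are tallied as unmatched, so
#' that matched + unmatched equals the total number of reads.
#'
#' @param fastq Path to a FASTQ file (plain or gzip-compressed), or a
#'   character vector of read sequences.
#' @param layout A [read_layout()].
#' @return A list: `counts` (named integer vector, barcode -> read count),
#'   `matched`, `unmatched`, `total`.
#' @examples
#' lay <- read_layout()
#' bc <- strrep("A", 20)
#' read <- paste0("TT", lay$preseq, bc, lay$postseq, "GGAA")
#' extract_barcodes(c(read, "ACGTACGT"), lay)
#' @export
extract_barcodes <- function(fastq, layout = read_layout()) {
  stopifnot(inherits(layout, "read_layout"))
  seqs <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else {
    as.character(fastq)
  }

  n <- length(seqs)
  pre_w <- nchar(layout$preseq)
  post <- layout$postseq
  bl <- layout$barcode_length
  barcode <- rep(NA_character_, n)

  for (off in layout$offsets) {
    open <- which(is.na(barcode))
    if (!length(open)) break
    s <- seqs[open]
    hit <- substr(s, off + 1L, off + pre_w) == layout$preseq
    if (!any(hit)) next
    cand <- open[hit]
    s <- seqs[cand]
    bc_start <- off + pre_w + 1L
    bc <- substr(s, bc_start, bc_start + bl - 1L)
    ok <- nchar(bc) == bl & !grepl("[^ACGT]", bc)
    remaining <- pmax(nchar(s) - (bc_start + bl - 1L), 0L)
    post_w <- pmin(nchar(post), remaining)
    ok <- ok & substr(s, bc_start + bl, bc_start + bl + post_w - 1L) ==
      substr(post, 1L, post_w)
    barcode[cand[ok]] <- bc[ok]
  }

  matched <- sum(!is.na(barcode))
  counts <- integer(0)
  if (matched > 0) {
    tab <- table(barcode[!is.na(barcode)])
    counts <- setNames(as.integer(tab), names(tab))
  }
  list(counts = counts, matched = matched,
       unmatched = n - matched, total = n)
}

# Light FASTQ reader: 4-line records, plain or gzip (compression handled
# transparently by file()). Validates record structure so malformed files
# fail loudly with the offending record index.
read_fastq_sequences <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "malformed FASTQ in '%s': truncated record %d (line count %d not a multiple of 4).",
      path, length(lines) %/% 4L + 1L, length(lines)
    ))
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ in '%s': record %d.", path, bad[1]))
  }
  lines[seq(2L, length(lines), by = 4L)]
}

#' Assemble a count matrix from per-sample barcode counts
#'
#' Joins per-sample extraction results against a pool table and a sample
#' sheet. Rows are restricted to pool barcodes; reads whose barcode is not in
#' the pool are added to the per-sample unmatched tally; pool barcodes unseen
#' in a sample get a zero.
#'
#' @param sample_counts Named list (one element per sample) of either the
#'   result of [extract_barcodes()] or a bare named integer vector of
#'   barcode counts.
#' @param sample_sheet Tibble with `sample`, `condition`, `timepoint`,
#'   `replicate`, `role`; sample ids must match `names(sample_counts)`.
#' @param pool A `pool_table`.
#' @return A [count_matrix()].
#' @export
assemble_count_matrix <- function(sample_counts, sample_sheet, pool) {
  validate_pool(pool)
  assert_columns(sample_sheet, c("sample", "condition", "timepoint",
                                 "replicate", "role"), "sample_sheet")
  if (anyDuplicated(sample_sheet$sample)) abort("duplicate sample id.")
  if (!setequal(names(sample_counts), sample_sheet$sample)) {
    abort("`sample_counts` names must match `sample_sheet$sample`.")
  }
  if (!any(sample_sheet$role == "T0")) abort("no T0 sample designated.")

  mat <- matrix(0L, nrow = nrow(pool), ncol = nrow(sample_sheet),
                dimnames = list(pool$barcode, sample_sheet$sample))
  unmatched <- setNames(rep(0L, nrow(sample_sheet)), sample_sheet$sample)
  for (smp in sample_sheet$sample) {
    x <- sample_counts[[smp]]
    if (is.list(x)) {
      unmatched[smp] <- unmatched[smp] + as.integer(x$unmatched %||% 0L)
      x <- x$counts
    }
    if (length(x)) {
      known <- names(x) %in% pool$barcode
      unmatched[smp] <- unmatched[smp] + sum(x[!known])
      x <- x[known]
      mat[names(x), smp] <- as.integer(x)
    }
  }
  count_matrix(mat, sample_sheet, unmatched)
}
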