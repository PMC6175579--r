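#' Construct a barcode-by-sample count matrix
#'
#' Bundles an integer matrix of barcode read counts (rows = barcodes,
#' columns = samples) with its sample metadata and the per-sample tally of
#' reads whose barcode could not be matched.
#'
#' @param counts Integer matrix, rownames = barcodes, colnames = sample ids.
#' @param samples Tibble with columns `sample`, `condition`, `timepoint`,
#'   `replicate`, `role` (`role` is `"T0"` for the shared inoculum reference,
#'   `"harvest"` otherwise). Exactly one sample must have role `T0`.
#' @param unmatched Optional named integer vector (per sample) of unmatched
#'   reads; defaults to zeros.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, unmatched = NULL) {
  assert_columns(samples, c("sample", "condition", "timepoint", "replicate",
                            "role"), "samples")
  if (!is.matrix(counts)) abort("`counts` must be a matrix.")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have barcode rownames and sample colnames.")
  }
  if (anyDuplicated(samples$sample)) abort("sample ids must be unique.")
  if (!setequal(colnames(counts), samples$sample)) {
    abort("`counts` columns and `samples$sample` must match.")
  }
  if (sum(samples$role == "T0") != 1L) {
    abort("exactly one sample must have role 'T0'.")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.")
  }
  counts <- counts[, samples$sample, drop = FALSE]
  storage.mode(counts) <- "integer"
  if (is.null(unmatched)) {
    unmatched <- setNames(rep(0L, nrow(samples)), samples$sample)
  }
  structure(
    list(counts = counts, samples = as_tibble(samples),
         unmatched = unmatched[samples$sample]),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %s barcode(s) x %d sample(s); T0 = '%s'; %s matched reads\n",
    format(nrow(x$counts), big.mark = ","), ncol(x$counts),
    t0_sample(x), format(sum(as.numeric(x$counts)), big.mark = ",")
  ))
  invisible(x)
}

#' @describeIn count_matrix Long-format tibble (`barcode`, `sample`, `count`)
#'   joined with sample metadata.
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.count_matrix <- function(x, ...) {
  long <- tibble(
    barcode = rep(rownames(x$counts), times = ncol(x$counts)),
    sample = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  left_join(long, x$samples, by = "sample")
}

t0_sample <- function(counts) {
  counts$samples$sample[counts$samples$role == "T0"][1]
}

harvest_samples <- function(counts) {
  counts$samples[counts$samples$role != "T0", , drop = FALSE]
}
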