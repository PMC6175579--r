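#' Build a pool table from TnSeq barcode-to-fragment reads
#'
#' Lite pool construction for synthetic libraries: each TnSeq read pairs a
#' barcode with a genomic fragment adjacent to the insertion. Fragments are
#' located in the genome by exact string match (forward strand first, then
#' reverse complement); reads whose fragment matches more than one genomic
#' position are discarded as ambiguous. A barcode is retained iff it has at
#' least `min_reads` usable reads and at least `majority_fraction` of them
#' agree on a single location; retained barcodes are annotated with gene
#' assignment, within-gene fraction and central flag.
#'
#' @param reads Tibble with columns `barcode` and `fragment` (one row per
#'   TnSeq read; fragments are exact genome substrings or their reverse
#'   complements).
#' @param genome A `genome_annotation` carrying its `sequence` (see
#'   [sim_genome()] with `sequence = TRUE`).
#' @param min_reads Minimum usable reads per retained barcode (default 2).
#' @param majority_fraction Minimum fraction of a barcode's reads agreeing on
#'   one location (default 0.75).
#' @return A `pool_table` tibble (see [sim_pool()] for columns), plus
#'   attributes `n_ambiguous` (reads discarded for multi-mapping) and
#'   `n_dropped_barcodes`.
#' @export
build_pool_from_tnseq <- function(reads, genome, min_reads = 2,
                                  majority_fraction = 0.75) {
  assert_columns(reads, c("barcode", "fragment"), "reads")
  validate_genome(genome)
  if (is.null(genome$sequence)) {
    abort("`genome` must carry its sequence (sim_genome(sequence = TRUE)).")
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("package 'Biostrings' is required for fragment matching.")
  }

  subjects <- lapply(genome$sequence, Biostrings::DNAString)

  locate <- function(frag) {
    hits <- list()
    for (sc in names(subjects)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") frag else {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
        }
        m <- Biostrings::matchPattern(pat, subjects[[sc]])
        for (st in Biostrings::start(m)) {
          hits[[length(hits) + 1L]] <- list(scaffold = sc, pos = st,
                                            strand = str)
        }
      }
    }
    hits
  }

  frags <- unique(reads$fragment)
  loc <- lapply(frags, locate)
  n_hits <- vapply(loc, length, integer(1))
  frag_loc <- tibble(
    fragment = frags,
    scaffold = vapply(loc, function(h) if (length(h) == 1L) h[[1]]$scaffold else NA_character_, character(1)),
    pos = vapply(loc, function(h) if (length(h) == 1L) h[[1]]$pos else NA_integer_, numeric(1)),
    strand = vapply(loc, function(h) if (length(h) == 1L) h[[1]]$strand else NA_character_, character(1)),
    ambiguous = n_hits > 1L
  )

  ann_reads <- left_join(reads, frag_loc, by = "fragment")
  n_ambiguous <- sum(ann_reads$ambiguous)
  usable <- ann_reads[!ann_reads$ambiguous & !is.na(ann_reads$pos), ]

  per_bc <- usable |>
    group_by(.data$barcode, .data$scaffold, .data$pos, .data$strand) |>
    summarise(n_loc = n(), .groups = "drop") |>
    group_by(.data$barcode) |>
    mutate(n_total = sum(.data$n_loc)) |>
    ungroup() |>
    arrange(dplyr::desc(.data$n_loc))
  best <- per_bc[!duplicated(per_bc$barcode), ]
  retained <- best[best$n_total >= min_reads &
                     best$n_loc / best$n_total >= majority_fraction, ]

  ann <- if (nrow(retained)) {
    annotate_insertions(genome, retained$scaffold, retained$pos)
  } else {
    tibble(locus_tag = character(0), gene_fraction = numeric(0),
           central = logical(0))
  }
  pool <- tibble(
    barcode = retained$barcode,
    scaffold = retained$scaffold,
    strand = retained$strand,
    pos = as.integer(retained$pos),
    locus_tag = ann$locus_tag,
    gene_fraction = ann$gene_fraction,
    central = ann$central
  ) |> arrange(.data$scaffold, .data$pos)
  class(pool) <- c("pool_table", class(pool))
  attr(pool, "n_ambiguous") <- n_ambiguous
  attr(pool, "n_dropped_barcodes") <-
    length(unique(reads$barcode)) - nrow(pool)
  pool
}
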