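# Tabular and sequence-format IO. Tables move through readr; genome
# sequence and annotation through Biostrings / rtracklayer.

#' Read and write the package's standard tables
#'
#' TSV round-trips for pool tables, sample sheets, count matrices, truth
#' tables, fitness tables, differential-expression tables and plate counts.
#' Count matrices are written as two files: `<stem>.counts.tsv` (barcode rows,
#' sample columns) and `<stem>.samples.tsv` (the sample sheet, including the
#' per-sample unmatched tally).
#'
#' @param path File path (for count matrices, the `<stem>` path).
#' @param pool,counts,x Object to write.
#' @name barseq_io
NULL

#' @rdname barseq_io
#' @export
write_pool <- function(pool, path) {
  validate_pool(pool)
  readr::write_tsv(pool, path)
  invisible(path)
}

#' @rdname barseq_io
#' @export
read_pool <- function(path) {
  pool <- readr::read_tsv(
    path,
    col_types = readr::cols(
      barcode = "c", scaffold = "c", strand = "c", pos = "i",
      locus_tag = "c", gene_fraction = "d", central = "l"
    )
  )
  validate_pool(pool)
  class(pool) <- c("pool_table", class(pool))
  pool
}

#' @rdname barseq_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample = "c", condition = "c", timepoint = "c",
      replicate = "i", role = "c"
    )
  )
  assert_columns(sheet, c("sample", "condition", "timepoint", "replicate",
                          "role"), "sample sheet")
  sheet
}

#' @rdname barseq_io
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  wide <- dplyr::bind_cols(
    tibble(barcode = rownames(counts$counts)),
    as_tibble(counts$counts)
  )
  readr::write_tsv(wide, paste0(path, ".counts.tsv"))
  sheet <- counts$samples
  sheet$unmatched <- as.integer(counts$unmatched[sheet$sample])
  readr::write_tsv(sheet, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' @rdname barseq_io
#' @export
read_counts <- function(path) {
  wide <- readr::read_tsv(paste0(path, ".counts.tsv"),
                          col_types = readr::cols(barcode = "c",
                                                  .default = "i"))
  sheet <- readr::read_tsv(
    paste0(path, ".samples.tsv"),
    col_types = readr::cols(
      sample = "c", condition = "c", timepoint = "c",
      replicate = "i", role = "c", unmatched = "i"
    )
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$barcode
  count_matrix(mat, sheet[, c("sample", "condition", "timepoint",
                              "replicate", "role")],
               setNames(sheet$unmatched, sheet$sample))
}

#' @rdname barseq_io
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(
    path,
    col_types = readr::cols(
      locus_tag = "c", contrast = "c", timepoint = "c",
      log2FC = "d", padj = "d"
    )
  )
  assert_columns(de, c("locus_tag", "contrast", "timepoint", "log2FC",
                       "padj"), "DE table")
  de
}

#' @rdname barseq_io
#' @export
read_plate_counts <- function(path) {
  pc <- readr::read_tsv(
    path,
    col_types = readr::cols(
      mutant = "c", replicate = "i", timepoint = "c",
      colonies = "d", dilution = "d", volume_ul = "d", selective = "l"
    )
  )
  assert_columns(pc, c("mutant", "replicate", "timepoint", "colonies",
                       "dilution", "volume_ul", "selective"), "plate counts")
  pc
}

#' Write a simulated genome as FASTA and GFF3
#'
#' @param genome A `genome_annotation` (FASTA output requires its sequence).
#' @param fasta,gff3 Output paths (`NULL` to skip either).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta = NULL, gff3 = NULL) {
  validate_genome(genome)
  if (!is.null(fasta)) {
    if (is.null(genome$sequence)) {
      abort("FASTA output requires a genome simulated with `sequence = TRUE`.")
    }
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("package 'Biostrings' is required to write FASTA.")
    }
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$sequence), fasta
    )
  }
  if (!is.null(gff3)) {
    g <- genome$genes
    lines <- c(
      "##gff-version 3",
      sprintf("##sequence-region %s 1 %d",
              genome$scaffolds$scaffold, genome$scaffolds$length),
      sprintf("%s\tbarseqfit\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
              g$scaffold, g$start, g$end, g$strand, g$locus_tag, g$locus_tag)
    )
    writeLines(lines, gff3)
  }
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read gene annotation from a GFF3 file
#'
#' Builds a `genome_annotation` from a GFF3 of `gene` features (via
#' rtracklayer). Scaffold lengths come from `##sequence-region` directives
#' when present, otherwise from the furthest gene end.
#'
#' @param path GFF3 path.
#' @param circular Circular flag applied to all scaffolds.
#' @return A `genome_annotation` (without sequence).
#' @export
read_genome_gff3 <- function(path, circular = TRUE) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("package 'rtracklayer' is required to read GFF3.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  tags <- gr$locus_tag %||% gr$ID
  genes <- tibble(
    locus_tag = as.character(tags),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr))
  ) |> arrange(.data$scaffold, .data$start)
  region <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(region)) {
    parts <- strsplit(trimws(region), "\\s+")
    scaffolds <- tibble(
      scaffold = vapply(parts, `[`, character(1), 2),
      length = as.integer(vapply(parts, `[`, character(1), 4)),
      circular = circular
    )
  } else {
    scaffolds <- genes |>
      group_by(scaffold = .data$scaffold) |>
      summarise(length = max(.data$end), .groups = "drop") |>
      mutate(circular = circular)
  }
  structure(list(scaffolds = scaffolds, genes = genes, sequence = NULL),
            class = "genome_annotation")
}
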