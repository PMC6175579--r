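#' Simulate a bacterial genome annotation
#'
#' Lays out `n_genes` non-overlapping protein-coding genes in coordinate order
#' on a single scaffold, with randomised gene lengths and inter-gene gaps.
#' This stands in for a real annotation: it carries exactly the information the
#' fitness pipeline uses — gene positions for the chromosome-position
#' (smoothed-median) normalisation and gene boundaries for the 10-90% central
#' insertion rule. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param n_genes Number of genes (>= 1).
#' @param scaffold_length Scaffold length in bp.
#' @param circular Is the scaffold circular (default `TRUE`, as for a
#'   bacterial chromosome)?
#' @param seed Integer seed; the same seed reproduces the same annotation.
#' @param gene_length Length-2 numeric range of gene lengths in bp
#'   (default 600-3000).
#' @param scaffold Scaffold name.
#' @param sequence If `TRUE`, also simulate a random nucleotide sequence for
#'   the scaffold (needed only for TnSeq pool building from reads).
#' @return A `genome_annotation`: list with tibbles `scaffolds`
#'   (scaffold, length, circular) and `genes`
#'   (locus_tag, scaffold, start, end, strand), plus `sequence` (named
#'   character vector or `NULL`).
#' @examples
#' g <- sim_genome(n_genes = 10, scaffold_length = 5e4, seed = 1)
#' g$genes
#' @export
sim_genome <- function(n_genes, scaffold_length, circular = TRUE, seed = 1,
                       gene_length = c(600, 3000), scaffold = "chr1",
                       sequence = FALSE) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(scaffold_length, "scaffold_length", lower = 1)
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    lens <- sample(seq(gene_length[1], gene_length[2]), n_genes, replace = TRUE)
    slack <- scaffold_length - sum(lens)
    if (slack < 0) {
      abort(sprintf(
        "cannot fit %d genes (total %d bp) in a %d bp scaffold.",
        n_genes, sum(lens), as.integer(scaffold_length)
      ))
    }
    # Distribute the non-genic slack over the n_genes gaps preceding each gene
    # (the remainder after the last gene closes the circle / trails the end).
    gaps <- if (slack > 0) {
      as.vector(rmultinom(1, slack, rep(1, n_genes)))
    } else {
      rep(0L, n_genes)
    }
    trailing <- gaps[1] %/% 2  # keep some slack after the final gene too
    gaps[1] <- gaps[1] - trailing
    starts <- cumsum(c(1 + gaps[1], gaps[-1] + head(lens, -1)))
    ends <- starts + lens - 1L
    genes <- tibble(
      locus_tag = sprintf("g%05d", seq_len(n_genes)),
      scaffold = scaffold,
      start = as.integer(starts),
      end = as.integer(ends),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    seq_chr <- NULL
    if (sequence) {
      seq_chr <- setNames(
        paste(sample(c("A", "C", "G", "T"), scaffold_length, replace = TRUE),
              collapse = ""),
        scaffold
      )
    }
    structure(
      list(
        scaffolds = tibble(
          scaffold = scaffold,
          length = as.integer(scaffold_length),
          circular = isTRUE(circular)
        ),
        genes = genes,
        sequence = seq_chr
      ),
      class = "genome_annotation"
    )
  })
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d gene(s) on %d scaffold(s) (%s bp)%s\n",
    nrow(x$genes), nrow(x$scaffolds),
    format(sum(x$scaffolds$length), big.mark = ","),
    if (is.null(x$sequence)) "" else ", with sequence"
  ))
  invisible(x)
}

validate_genome <- function(genome) {
  if (!inherits(genome, "genome_annotation")) {
    abort("expected a `genome_annotation` (see `sim_genome()`).")
  }
  invisible(genome)
}
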