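#' Simulate a barcoded transposon insertion pool
#'
#' Generates a pool table for a library of uniquely barcoded insertion
#' mutants: each mutant carries a random barcode and a genomic insertion
#' position, annotated with its gene assignment, within-gene fraction and
#' central flag (see [annotate_insertions()]). The default scaled-down pool
#' (3,300 genes, ~55,000 mutants) mirrors a genome-scale library's per-gene
#' statistics (median ~16 insertions per gene) at desk scale.
#'
#' Two placement modes are available. By default, a fixed fraction of mutants
#' is placed uniformly in intergenic space and the remainder uniformly within
#' genes. Alternatively, `central_per_gene` places exactly that many
#' insertions uniformly within the central 10-90% region of every gene (plus
#' the intergenic fraction), which is convenient for calibration studies where
#' per-gene strain support should be constant.
#'
#' @param genome A `genome_annotation`.
#' @param n_mutants Number of insertion mutants (ignored when
#'   `central_per_gene` is given).
#' @param layout A [read_layout()]; supplies the barcode length.
#' @param intergenic_fraction Proportion of mutants placed outside genes
#'   (in `[0, 1)`).
#' @param central_per_gene If not `NULL`, place exactly this many central
#'   insertions in every gene.
#' @param seed Integer seed.
#' @param max_retries Retry budget for barcode collisions before failing.
#' @return A `pool_table` tibble: `barcode`, `scaffold`, `strand`, `pos`,
#'   `locus_tag`, `gene_fraction`, `central`.
#' @examples
#' g <- sim_genome(20, 1e5, seed = 1)
#' pool <- sim_pool(g, n_mutants = 200, seed = 1)
#' table(pool$central)
#' @export
sim_pool <- function(genome, n_mutants = 55000, layout = read_layout(),
                     intergenic_fraction = 0.15, central_per_gene = NULL,
                     seed = 1, max_retries = 100L) {
  validate_genome(genome)
  assert_scalar_number(intergenic_fraction, "intergenic_fraction",
                       lower = 0, upper = 1 - 1e-12)
  genes <- genome$genes
  sc_len <- setNames(genome$scaffolds$length, genome$scaffolds$scaffold)

  with_seed(seed, {
    if (!is.null(central_per_gene)) {
      assert_scalar_number(central_per_gene, "central_per_gene", lower = 1)
      k <- as.integer(central_per_gene)
      span <- genes$end - genes$start
      lo <- ceiling(genes$start + 0.1 * span)
      hi <- floor(genes$start + 0.9 * span)
      genic_pos <- as.integer(unlist(Map(function(a, b) {
        sample(seq(a, b), k, replace = TRUE)
      }, lo, hi)))
      genic_sc <- rep(genes$scaffold, each = k)
      n_genic <- length(genic_pos)
      n_inter <- round(intergenic_fraction / (1 - intergenic_fraction) * n_genic)
    } else {
      assert_scalar_number(n_mutants, "n_mutants", lower = 1)
      n_mutants <- as.integer(n_mutants)
      n_inter <- round(intergenic_fraction * n_mutants)
      n_genic <- n_mutants - n_inter
      gi <- sample(nrow(genes), n_genic, replace = TRUE,
                   prob = genes$end - genes$start + 1)
      genic_pos <- genes$start[gi] +
        as.integer(floor(runif(n_genic) * (genes$end[gi] - genes$start[gi] + 1)))
      genic_sc <- genes$scaffold[gi]
    }

    inter_pos <- integer(0)
    inter_sc <- character(0)
    if (n_inter > 0) {
      # rejection-sample uniform scaffold positions until they fall outside genes
      sc <- sample(names(sc_len), n_inter, replace = TRUE, prob = sc_len)
      pos <- as.integer(ceiling(runif(n_inter) * sc_len[sc]))
      ann <- annotate_insertions(genome, sc, pos)
      bad <- which(!is.na(ann$locus_tag))
      tries <- 0L
      while (length(bad) > 0 && tries < max_retries) {
        pos[bad] <- as.integer(ceiling(runif(length(bad)) * sc_len[sc[bad]]))
        ann2 <- annotate_insertions(genome, sc[bad], pos[bad])
        bad <- bad[!is.na(ann2$locus_tag)]
        tries <- tries + 1L
      }
      keep <- seq_len(n_inter)
      if (length(bad)) keep <- setdiff(keep, bad)
      inter_pos <- pos[keep]
      inter_sc <- sc[keep]
    }

    all_sc <- c(genic_sc, inter_sc)
    all_pos <- c(genic_pos, inter_pos)
    n <- length(all_pos)

    barcodes <- random_barcodes(n, layout$barcode_length, max_retries)
    ann <- annotate_insertions(genome, all_sc, all_pos)
    pool <- tibble(
      barcode = barcodes,
      scaffold = all_sc,
      strand = sample(c("+", "-"), n, replace = TRUE),
      pos = as.integer(all_pos),
      locus_tag = ann$locus_tag,
      gene_fraction = ann$gene_fraction,
      central = ann$central
    )
    class(pool) <- c("pool_table", class(pool))
    pool
  })
}

# Unique random fixed-length barcodes; regenerates colliding ones, erroring
# out if the barcode space is effectively exhausted.
random_barcodes <- function(n, width, max_retries = 100L) {
  draw <- function(m) {
    mat <- matrix(sample(c("A", "C", "G", "T"), m * width, replace = TRUE),
                  nrow = m)
    do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  bc <- draw(n)
  tries <- 0L
  while (anyDuplicated(bc)) {
    if (tries >= max_retries) {
      abort("barcode space exhausted: could not generate unique barcodes.")
    }
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
    tries <- tries + 1L
  }
  bc
}

validate_pool <- function(pool) {
  assert_columns(pool, c("barcode", "scaffold", "strand", "pos",
                         "locus_tag", "gene_fraction", "central"), "pool")
  if (anyDuplicated(pool$barcode)) abort("pool barcodes must be unique.")
  invisible(pool)
}
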