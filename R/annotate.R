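#' Assign insertion positions to genes and flag central insertions
#'
#' Maps each insertion position to the gene containing it (if any), computes
#' the within-gene fraction measured from the gene's translational start
#' (strand-aware), and flags insertions in the central 10-90% of the coding
#' sequence. Only central insertions are used for fitness scoring, because
#' insertions near either end of a gene often fail to disrupt its function.
#' The central flag is inclusive at both boundaries (fraction exactly 0.1 or
#' 0.9 counts as central).
#'
#' @param genome A `genome_annotation`.
#' @param scaffold Character vector of scaffold names (recycled if length 1).
#' @param pos Integer vector of insertion positions (1-based bp).
#' @return A tibble with one row per input position: `scaffold`, `pos`,
#'   `locus_tag` (`NA` for intergenic), `gene_fraction` (`NA` for intergenic)
#'   and `central` (always `FALSE` for intergenic).
#' @examples
#' g <- sim_genome(5, 2e4, seed = 2)
#' annotate_insertions(g, "chr1", c(100L, g$genes$start[1] + 50L))
#' @export
annotate_insertions <- function(genome, scaffold, pos) {
  validate_genome(genome)
  if (length(scaffold) == 1L) scaffold <- rep(scaffold, length(pos))
  if (length(scaffold) != length(pos)) {
    abort("`scaffold` and `pos` must have the same length.")
  }
  sc_len <- setNames(genome$scaffolds$length, genome$scaffolds$scaffold)
  unknown <- setdiff(unique(scaffold), names(sc_len))
  if (length(unknown)) {
    abort(sprintf("unknown scaffold(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (any(pos < 1L | pos > sc_len[scaffold])) {
    abort("`pos` outside scaffold bounds.")
  }

  out <- tibble(
    scaffold = scaffold, pos = as.integer(pos),
    locus_tag = NA_character_, gene_fraction = NA_real_, central = FALSE
  )
  for (sc in unique(scaffold)) {
    idx <- which(scaffold == sc)
    genes <- genome$genes[genome$genes$scaffold == sc, ]
    if (nrow(genes) == 0L) next
    genes <- genes[order(genes$start), ]
    hit <- findInterval(out$pos[idx], genes$start)
    inside <- hit >= 1L & out$pos[idx] <= genes$end[pmax(hit, 1L)]
    gi <- hit[inside]
    p <- out$pos[idx][inside]
    span <- genes$end[gi] - genes$start[gi]
    frac <- ifelse(genes$strand[gi] == "+",
                   (p - genes$start[gi]) / span,
                   (genes$end[gi] - p) / span)
    out$locus_tag[idx[inside]] <- genes$locus_tag[gi]
    out$gene_fraction[idx[inside]] <- frac
    out$central[idx[inside]] <- frac >= 0.1 & frac <= 0.9
  }
  out
}
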