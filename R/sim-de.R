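#' Simulate a differential-expression result table
#'
#' Emulates the output columns of an external DE tool for fixture and
#' recovery testing: planted genes get `|log2FC| >= lfc` with the requested
#' sign and `padj < 0.001`; null genes get `log2FC ~ Normal(0, 0.2)` and
#' `padj ~ Uniform(0.2, 1)`.
#'
#' @param genes Character vector of gene ids.
#' @param planted_up,planted_down Disjoint subsets of `genes` to plant as
#'   up-/down-regulated.
#' @param lfc Minimum planted |log2FC| (default 2).
#' @param contrast,timepoint Labels stamped on every row.
#' @param seed Integer seed.
#' @return A DE tibble: `locus_tag`, `contrast`, `timepoint`, `log2FC`,
#'   `padj`.
#' @examples
#' sim_de_table(letters[1:5], planted_up = "a", seed = 1)
#' @export
sim_de_table <- function(genes, planted_up = character(0),
                         planted_down = character(0), lfc = 2,
                         contrast = "pairwise_1", timepoint = "day1",
                         seed = 1) {
  if (length(intersect(planted_up, planted_down))) {
    abort("`planted_up` and `planted_down` must be disjoint.")
  }
  stray <- setdiff(c(planted_up, planted_down), genes)
  if (length(stray)) {
    abort("planted genes must be a subset of `genes`.")
  }
  n <- length(genes)
  with_seed(seed, {
    log2FC <- rnorm(n, 0, 0.2)
    padj <- runif(n, 0.2, 1)
    up <- genes %in% planted_up
    down <- genes %in% planted_down
    log2FC[up] <- lfc + abs(rnorm(sum(up), 0, 0.5))
    log2FC[down] <- -lfc - abs(rnorm(sum(down), 0, 0.5))
    padj[up | down] <- 10^(-runif(sum(up | down), 4, 10))
    tibble(locus_tag = genes, contrast = contrast, timepoint = timepoint,
           log2FC = log2FC, padj = padj)
  })
}
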