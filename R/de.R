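#' Threshold differential-expression tables into up/down gene sets
#'
#' Applies the standard significance rule per timepoint — adjusted p-value
#' below `alpha` and `|log2FC|` at or above `lfc` (inclusive by default) —
#' then pools timepoints by union within each contrast and direction.
#'
#' @param de Tibble with columns `locus_tag`, `contrast`, `timepoint`,
#'   `log2FC`, `padj` (from any external DE tool).
#' @param alpha Adjusted p-value threshold (default 0.01).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @param strict_gt Require `|log2FC|` strictly greater than `lfc` instead of
#'   at-or-above (default `FALSE`).
#' @return A tibble: `contrast`, `direction` (`up`/`down`), `locus_tag`,
#'   `timepoints` (provenance). Records with missing `padj` are skipped with
#'   a warning.
#' @examples
#' de <- tibble::tibble(locus_tag = c("a", "b"), contrast = "p1",
#'                      timepoint = "day1", log2FC = c(1, -2),
#'                      padj = c(0.005, 0.2))
#' de_sets(de)
#' @export
de_sets <- function(de, alpha = 0.01, lfc = 1, strict_gt = FALSE) {
  assert_columns(de, c("locus_tag", "contrast", "timepoint", "log2FC",
                       "padj"), "de")
  if (anyNA(de$padj)) {
    warn(sprintf("skipping %d record(s) with missing padj.",
                 sum(is.na(de$padj))))
    de <- de[!is.na(de$padj), ]
  }
  pass_lfc <- if (strict_gt) abs(de$log2FC) > lfc else abs(de$log2FC) >= lfc
  hits <- de[de$padj < alpha & pass_lfc, ]
  hits$direction <- ifelse(hits$log2FC > 0, "up", "down")
  hits |>
    group_by(.data$contrast, .data$direction, .data$locus_tag) |>
    summarise(
      timepoints = paste(sort(unique(.data$timepoint)), collapse = ","),
      .groups = "drop"
    )
}

#' Compare pairwise and community differential-expression sets
#'
#' For one direction (up or down): takes the union of the per-partner
#' pairwise sets and splits it against the community set into genes
#' regulated in both (conserved), only in pairwise conditions
#' (pairwise-specific), and only in the community (community-specific).
#'
#' @param pairwise_sets Named list of per-partner gene sets (one direction).
#' @param community_set Character vector (same direction, community vs
#'   alone).
#' @return List: `conserved`, `pairwise_specific`, `community_specific`,
#'   plus `pairwise_union`.
#' @examples
#' compare_de_sets(list(p1 = c("a", "b"), p2 = c("b", "c")), c("b", "d"))
#' @export
compare_de_sets <- function(pairwise_sets, community_set) {
  if (!is.list(pairwise_sets)) pairwise_sets <- list(pairwise_sets)
  u <- unique(unlist(pairwise_sets, use.names = FALSE))
  community_set <- unique(community_set)
  list(
    conserved = intersect(u, community_set),
    pairwise_specific = setdiff(u, community_set),
    community_specific = setdiff(community_set, u),
    pairwise_union = u
  )
}

#' Amplified-response genes within a conserved DE set
#'
#' Among genes regulated in the same direction both pairwise and in the
#' community, finds those whose response is significantly stronger in the
#' community: adjusted p below `alpha` and `log2FC >= lfc` in a
#' community-versus-pairwise contrast table.
#'
#' @param conserved Character vector of conserved genes.
#' @param contrast_de Tibble (`locus_tag`, `log2FC`, `padj`) for the
#'   community-vs-pairwise contrast. Genes absent from it are excluded.
#' @param alpha Adjusted p threshold (default 0.01).
#' @param lfc log2 fold-change threshold (default 1).
#' @return Character vector: the amplified subset.
#' @export
amplified_genes <- function(conserved, contrast_de, alpha = 0.01, lfc = 1) {
  assert_columns(contrast_de, c("locus_tag", "log2FC", "padj"), "contrast_de")
  hit <- contrast_de[contrast_de$locus_tag %in% conserved &
                       !is.na(contrast_de$padj) &
                       contrast_de$padj < alpha &
                       contrast_de$log2FC >= lfc, ]
  unique(hit$locus_tag)
}

#' Hypergeometric category enrichment with BH correction
#'
#' Tests each category for over-representation in a query gene set using the
#' hypergeometric upper tail:
#' `p = P(X >= k)` with `X ~ Hypergeometric(M, K, n)`, where `M` is the
#' universe size, `K` the category size, `n` the query size and `k` the
#' overlap. P-values are Benjamini-Hochberg adjusted across categories; a
#' category is flagged enriched when `padj < alpha`. By the upper-tail
#' convention `k = 0` gives `p = 1`.
#'
#' @param query Character vector of genes (must be a subset of `universe`).
#' @param universe Character vector: all scorable genes.
#' @param categories Tibble mapping `locus_tag` to `category` (one row per
#'   pair; genes outside the universe are dropped, empty categories skipped).
#' @param alpha Adjusted p-value threshold for the enriched flag
#'   (default 0.05).
#' @return A tibble: `category`, `overlap` (k), `query_size` (n),
#'   `category_size` (K), `universe_size` (M), `p`, `padj`, `enriched`,
#'   sorted by `p`.
#' @examples
#' cats <- tibble::tibble(locus_tag = letters[1:10],
#'                        category = rep(c("x", "y"), each = 5))
#' hypergeometric_enrichment(letters[1:4], letters[1:10], cats)
#' @export
hypergeometric_enrichment <- function(query, universe, categories,
                                      alpha = 0.05) {
  assert_columns(categories, c("locus_tag", "category"), "categories")
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) abort("`query` must not be empty.")
  stray <- setdiff(query, universe)
  if (length(stray)) {
    abort(sprintf("%d query gene(s) are not in the universe.", length(stray)))
  }
  categories <- categories[categories$locus_tag %in% universe, ]
  M <- length(universe)
  n <- length(query)
  out <- categories |>
    group_by(category = .data$category) |>
    summarise(
      overlap = sum(unique(.data$locus_tag) %in% query),
      category_size = dplyr::n_distinct(.data$locus_tag),
      .groups = "drop"
    ) |>
    filter(.data$category_size > 0)
  out$query_size <- n
  out$universe_size <- M
  out$p <- phyper(out$overlap - 1, out$category_size,
                  M - out$category_size, n, lower.tail = FALSE)
  out$padj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$padj < alpha
  out[order(out$p, out$category),
      c("category", "overlap", "query_size", "category_size",
        "universe_size", "p", "padj", "enriched")]
}

#' Full DE cross-classification pipeline
#'
#' Thresholds a DE table (pairwise and community contrasts versus growth
#' alone), pools timepoints, and cross-classifies each direction's pairwise
#' union against the community set; optionally identifies the amplified
#' subset of the conserved upregulated genes from a community-vs-pairwise
#' contrast table.
#'
#' @param de DE tibble (see [de_sets()]); `contrast` values must include the
#'   pairwise and community labels.
#' @param pairwise Character vector of pairwise contrast labels.
#' @param community Community contrast label.
#' @param amplification_de Optional community-vs-pairwise contrast tibble for
#'   [amplified_genes()].
#' @param alpha,lfc,strict_gt Thresholds passed to [de_sets()].
#' @return A `de_classification` list: `sets` (the [de_sets()] tibble),
#'   `up` and `down` ([compare_de_sets()] results), `amplified_up`
#'   (character vector or `NULL`).
#' @export
classify_de <- function(de, pairwise, community, amplification_de = NULL,
                        alpha = 0.01, lfc = 1, strict_gt = FALSE) {
  sets <- de_sets(de, alpha = alpha, lfc = lfc, strict_gt = strict_gt)
  pick <- function(contrast, direction) {
    sets$locus_tag[sets$contrast == contrast & sets$direction == direction]
  }
  res <- lapply(setNames(c("up", "down"), c("up", "down")), function(dir) {
    compare_de_sets(lapply(setNames(pairwise, pairwise), pick,
                           direction = dir),
                    pick(community, dir))
  })
  amplified <- NULL
  if (!is.null(amplification_de)) {
    amplified <- amplified_genes(res$up$conserved, amplification_de,
                                 alpha = alpha, lfc = lfc)
  }
  structure(
    list(sets = sets, up = res$up, down = res$down,
         amplified_up = amplified),
    class = "de_classification"
  )
}

#' @export
print.de_classification <- function(x, ...) {
  cat("<de_classification>\n")
  for (dir in c("up", "down")) {
    cat(sprintf(
      "  %s: pairwise union %d | conserved %d | pairwise-specific %d | community-specific %d\n",
      dir, length(x[[dir]]$pairwise_union), length(x[[dir]]$conserved),
      length(x[[dir]]$pairwise_specific), length(x[[dir]]$community_specific)
    ))
  }
  if (!is.null(x$amplified_up)) {
    cat(sprintf("  amplified (conserved up): %d\n", length(x$amplified_up)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.de_classification <- function(x, ...) {
  rows <- list()
  for (dir in c("up", "down")) {
    for (lab in c("conserved", "pairwise_specific", "community_specific")) {
      g <- x[[dir]][[lab]]
      if (length(g)) {
        rows[[length(rows) + 1L]] <- tibble(locus_tag = g, direction = dir,
                                            label = lab)
      }
    }
  }
  if (length(x$amplified_up)) {
    rows[[length(rows) + 1L]] <- tibble(locus_tag = x$amplified_up,
                                        direction = "up",
                                        label = "amplified")
  }
  bind_rows(rows)
}
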