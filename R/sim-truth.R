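#' Plant ground-truth fitness effects for a simulated library
#'
#' Assigns interaction categories to disjoint random subsets of genes and
#' fills in the true cumulative log2 relative-abundance effect `phi` for every
#' gene x condition x timepoint. `phi = 0` means neutral; negative values mean
#' the gene's mutants are depleted. Effects accumulate linearly over
#' timepoints (`phi` at the d-th timepoint is `d * effect`), modelling a
#' constant per-day growth defect.
#'
#' Categories name requirement patterns over the three context roles
#' (alone, pairwise, community); a gene is "required" in a context when its
#' `phi` there is negative:
#' \describe{
#'   \item{conserved}{required in every condition.}
#'   \item{alone_required}{required alone only — every partner and the
#'     community alleviate it.}
#'   \item{pairwise_induced}{not required alone, required in all pairwise
#'     co-cultures; persists in the community when
#'     `persist_in_community = TRUE` (default), otherwise pairwise-only.}
#'   \item{pairwise_alleviated}{required alone and in the community but
#'     alleviated in every pairwise co-culture (a higher-order pattern).}
#'   \item{community_specific_induced}{required in the community only.}
#'   \item{community_specific_alleviated}{required alone and in all pairwise
#'     co-cultures but alleviated in the community.}
#' }
#' Remaining genes are `neutral`.
#'
#' @param genome A `genome_annotation`.
#' @param design A [sim_design()].
#' @param fractions Named numeric vector of gene-fraction per category
#'   (names among the categories above, excluding `neutral`); must sum to
#'   at most 1. Defaults mirror the rough proportions seen in genome-scale
#'   interaction screens (a few percent of genes per category).
#' @param effect Per-timepoint log2 effect for planted genes (negative for
#'   deleterious; default -2).
#' @param persist_in_community Should pairwise-induced effects persist in the
#'   community condition (default `TRUE`)?
#' @param seed Integer seed.
#' @return A `truth_table` tibble: `locus_tag`, `category`, `condition`,
#'   `timepoint`, `phi`.
#' @examples
#' g <- sim_genome(50, 2e5, seed = 1)
#' tr <- sim_truth(g, sim_design(), fractions = c(conserved = 0.1), seed = 1)
#' dplyr::count(tr, category)
#' @export
sim_truth <- function(genome, design,
                      fractions = c(
                        conserved = 0.02,
                        alone_required = 0.02,
                        pairwise_induced = 0.015,
                        pairwise_alleviated = 0.01,
                        community_specific_induced = 0.005,
                        community_specific_alleviated = 0.005
                      ),
                      effect = -2, persist_in_community = TRUE, seed = 1) {
  validate_genome(genome)
  stopifnot(inherits(design, "sim_design"))
  cats <- c("conserved", "alone_required", "pairwise_induced",
            "pairwise_alleviated", "community_specific_induced",
            "community_specific_alleviated")
  if (length(fractions)) {
    bad <- setdiff(names(fractions), cats)
    if (length(bad)) {
      abort(sprintf("unknown categories: %s.", paste(bad, collapse = ", ")))
    }
    if (any(fractions < 0) || sum(fractions) > 1) {
      abort("category fractions must be >= 0 and sum to at most 1.")
    }
  }

  tags <- genome$genes$locus_tag
  n <- length(tags)
  with_seed(seed, {
    category <- rep("neutral", n)
    pool_idx <- sample.int(n)  # random order, carved into disjoint blocks
    offset <- 0L
    for (cat in names(fractions)) {
      k <- floor(fractions[[cat]] * n)
      if (k > 0) {
        category[pool_idx[offset + seq_len(k)]] <- cat
        offset <- offset + k
      }
    }

    affected <- truth_condition_patterns(design, persist_in_community)
    grid <- tidyr::expand_grid(
      locus_tag = tags,
      condition = design$conditions,
      timepoint = design$timepoints
    )
    grid$category <- category[match(grid$locus_tag, tags)]
    day <- match(grid$timepoint, design$timepoints)
    combos <- distinct(grid[, c("category", "condition")])
    combos$hit <- mapply(function(cat, cond) cond %in% affected[[cat]],
                         combos$category, combos$condition)
    hit <- combos$hit[match(paste(grid$category, grid$condition),
                            paste(combos$category, combos$condition))]
    grid$phi <- unname(ifelse(hit, effect * day, 0))
    out <- grid[, c("locus_tag", "category", "condition", "timepoint", "phi")]
    out <- as_tibble(out)
    class(out) <- c("truth_table", class(out))
    out
  })
}

# Which conditions carry the planted effect, per category.
truth_condition_patterns <- function(design, persist_in_community = TRUE) {
  alone <- design$alone
  pw <- design$pairwise
  comm <- design$community
  list(
    neutral = character(0),
    conserved = c(alone, pw, comm),
    alone_required = alone,
    pairwise_induced = c(pw, if (persist_in_community) comm),
    pairwise_alleviated = c(alone, comm),
    community_specific_induced = comm,
    community_specific_alleviated = c(alone, pw)
  )
}
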