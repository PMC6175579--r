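#' Significant-negative gene sets per condition
#'
#' A gene is significant-negative at a timepoint when `|t| >= t_threshold`
#' (inclusive) and its fitness is strictly negative. Per-condition sets pool
#' timepoints by union: a gene belongs to a condition's set when it is
#' significant-negative at at least one timepoint (provenance recorded).
#'
#' @param fitness A `tnseq_fitness` object or its tidy fitness tibble.
#' @param t_threshold Threshold on `|t|` (default 3).
#' @return A tibble: `condition`, `locus_tag`, `timepoints` (comma-joined
#'   provenance), `n_timepoints`.
#' @export
significant_sets <- function(fitness, t_threshold = 3) {
  f <- if (inherits(fitness, "tnseq_fitness")) fitness$fitness else fitness
  assert_columns(f, c("locus_tag", "condition", "timepoint", "fitness", "t"),
                 "fitness")
  f |>
    filter(abs(.data$t) >= t_threshold, .data$fitness < 0) |>
    group_by(.data$condition, .data$locus_tag) |>
    summarise(
      timepoints = paste(sort(unique(.data$timepoint)), collapse = ","),
      n_timepoints = dplyr::n_distinct(.data$timepoint),
      .groups = "drop"
    )
}

# Gene set (character vector) for one condition from a significant_sets tibble
# or from a named list of sets.
condition_set <- function(sets, condition) {
  if (is.list(sets) && !is.data.frame(sets)) {
    return(unique(sets[[condition]] %||% character(0)))
  }
  unique(sets$locus_tag[sets$condition == condition])
}

#' Classify genes relative to growth alone
#'
#' Compares the significant-negative set for growth alone (`A`) with one or
#' more interactive-context sets (`S1..Sk`, e.g. the pairwise co-cultures, or
#' a single community set):
#' \describe{
#'   \item{conserved}{negative both alone and in context. With
#'     `rule = "all"` (default) a gene must be negative in every context set
#'     (`A` intersected with all `Si`); with `rule = "any"` in at least one.}
#'   \item{induced}{negative in at least one context set but not alone.}
#'   \item{alleviated}{negative alone but not conserved (the complement of
#'     conserved within `A`).}
#' }
#' By construction `conserved + alleviated = |A|` and
#' `induced = |union(Si)| - |union(Si) & A|`.
#'
#' @param alone Character vector: the growth-alone set `A`.
#' @param contexts Named list of character vectors (one per context
#'   condition), or a single character vector.
#' @param rule `"all"` (conserved requires every context) or `"any"`.
#' @return An `interaction_classes` list with elements `conserved`,
#'   `induced`, `alleviated` (character vectors), and attributes recording
#'   the inputs and rule.
#' @examples
#' classify_vs_alone(c("a", "b", "c"), list(p1 = c("b", "c", "d")))
#' @export
classify_vs_alone <- function(alone, contexts, rule = c("all", "any")) {
  rule <- match.arg(rule)
  if (!is.list(contexts)) contexts <- list(context = contexts)
  stopifnot(length(contexts) >= 1)
  alone <- unique(alone)
  contexts <- lapply(contexts, unique)
  ctx_union <- unique(unlist(contexts, use.names = FALSE))
  ctx_inter <- Reduce(intersect, contexts)
  conserved_ctx <- if (rule == "all") ctx_inter else ctx_union
  structure(
    list(
      conserved = intersect(alone, conserved_ctx),
      induced = setdiff(ctx_union, alone),
      alleviated = setdiff(alone, conserved_ctx)
    ),
    class = "interaction_classes",
    alone = alone, contexts = contexts, rule = rule
  )
}

#' @export
print.interaction_classes <- function(x, ...) {
  cat(sprintf(
    "<interaction_classes> conserved %d | induced %d | alleviated %d (rule '%s', |A| = %d)\n",
    length(x$conserved), length(x$induced), length(x$alleviated),
    attr(x, "rule"), length(attr(x, "alone"))
  ))
  invisible(x)
}

#' Partner-specific breakdown of an induced or alleviated family
#'
#' For the alleviated family: a gene is "alleviated with partner i" when it
#' is in `A` but absent from that partner's set; it is alleviated by
#' "all" partners when absent from every set, and "specific" to partner i
#' when absent only from that one. The induced family is symmetric (present
#' in partner i's set but not in `A`).
#'
#' @param family `"induced"` or `"alleviated"`.
#' @param alone The growth-alone set `A`.
#' @param partner_sets Named list of per-partner significant sets.
#' @return A tibble: `locus_tag`, `pattern` (`all`, `specific:<partner>`, or
#'   `other`), plus one logical column per partner.
#' @export
partner_breakdown <- function(family = c("induced", "alleviated"),
                              alone, partner_sets) {
  family <- match.arg(family)
  stopifnot(is.list(partner_sets), length(partner_sets) >= 1)
  cls <- classify_vs_alone(alone, partner_sets, rule = "all")
  members <- cls[[family]]
  if (!length(members)) {
    return(tibble(locus_tag = character(0), pattern = character(0)))
  }
  # flag per partner: does the partner exhibit the interaction for this gene?
  flags <- vapply(partner_sets, function(s) {
    if (family == "induced") members %in% s else !(members %in% s)
  }, logical(length(members)))
  flags <- matrix(flags, nrow = length(members),
                  dimnames = list(NULL, names(partner_sets)))
  k <- rowSums(flags)
  if (any(k == 0)) {
    abort("inconsistent inputs: family member matches no partner pattern.")
  }
  pattern <- dplyr::case_when(
    k == ncol(flags) ~ "all",
    k == 1L ~ paste0("specific:",
                     colnames(flags)[apply(flags, 1, which.max)]),
    TRUE ~ "other"
  )
  out <- tibble(locus_tag = members, pattern = pattern)
  bind_cols(out, as_tibble(flags))
}

#' Cross-classify pairwise and community interaction families
#'
#' Given the same family (induced or alleviated) computed once against the
#' pairwise conditions and once against the community, splits it into
#' interactions conserved from pairwise to community, pairwise-specific
#' ones, and community-specific (emergent, higher-order) ones.
#'
#' @param pairwise_family Character vector (family computed vs pairwise).
#' @param community_family Character vector (same family vs community).
#' @return List: `conserved_interaction`, `pairwise_specific`,
#'   `community_specific`.
#' @examples
#' cross_classify(c("a", "b"), c("b", "c"))
#' @export
cross_classify <- function(pairwise_family, community_family) {
  p <- unique(pairwise_family)
  c_ <- unique(community_family)
  list(
    conserved_interaction = intersect(p, c_),
    pairwise_specific = setdiff(p, c_),
    community_specific = setdiff(c_, p)
  )
}

#' Core negative-fitness set
#'
#' Genes with significant negative fitness in every tested condition.
#'
#' @param sets Named list of per-condition gene sets (>= 2 conditions), or a
#'   [significant_sets()] tibble.
#' @return Character vector: the intersection of all condition sets.
#' @export
core_set <- function(sets) {
  if (is.data.frame(sets)) {
    sets <- split(sets$locus_tag, sets$condition)
  }
  if (length(sets) < 2) abort("core set needs at least 2 conditions.")
  Reduce(intersect, lapply(sets, unique))
}

#' Pairwise-derived versus higher-order interaction summary
#'
#' Counts the interactions observed in the community that are conserved from
#' pairwise conditions (`pairwise_derived` = conserved-induced +
#' conserved-alleviated) against those involved in higher-order patterns
#' (pairwise-specific and community-specific pieces of both families), and
#' expresses both as percentages of their total (rounded to the nearest
#' integer percent, half to even).
#'
#' @param cross_induced,cross_alleviated Results of [cross_classify()] for
#'   the induced and alleviated families (lists or counts in the order
#'   conserved, pairwise-specific, community-specific).
#' @return A one-row tibble: `pairwise_derived`, `higher_order`,
#'   `fraction_pairwise_pct`, `fraction_higher_pct` (percent columns are
#'   `NA` when both counts are zero).
#' @examples
#' higher_order_summary(
#'   list(conserved_interaction = 29, pairwise_specific = 46,
#'        community_specific = 8),
#'   list(conserved_interaction = 68, pairwise_specific = 14,
#'        community_specific = 3)
#' )
#' @export
higher_order_summary <- function(cross_induced, cross_alleviated) {
  n <- function(x) if (is.numeric(x)) sum(x) else length(x)
  pairwise_derived <- n(cross_induced$conserved_interaction) +
    n(cross_alleviated$conserved_interaction)
  higher_order <- n(cross_induced$pairwise_specific) +
    n(cross_induced$community_specific) +
    n(cross_alleviated$pairwise_specific) +
    n(cross_alleviated$community_specific)
  total <- pairwise_derived + higher_order
  tibble(
    pairwise_derived = pairwise_derived,
    higher_order = higher_order,
    fraction_pairwise_pct = if (total > 0) round(100 * pairwise_derived / total)
      else NA_real_,
    fraction_higher_pct = if (total > 0) round(100 * higher_order / total)
      else NA_real_
  )
}
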