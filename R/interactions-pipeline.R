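#' Full interaction classification across growth contexts
#'
#' Runs the whole comparative analysis on a fitness result: builds
#' per-condition significant-negative sets (timepoints pooled), classifies
#' genes relative to growth alone against the pairwise co-cultures and
#' against the community, breaks the pairwise families down by partner,
#' cross-classifies pairwise and community families, extracts the core set,
#' and summarises the pairwise-derived versus higher-order decomposition.
#'
#' @param fitness A `tnseq_fitness` object or tidy fitness tibble.
#' @param alone,community Condition labels for growth alone and the full
#'   community.
#' @param pairwise Character vector of pairwise-condition labels.
#' @param t_threshold Threshold on `|t|` (default 3, inclusive).
#' @param rule Conserved rule for the pairwise comparison: `"all"` (default)
#'   requires significance in every pairwise condition, `"any"` in at least
#'   one (see [classify_vs_alone()]).
#' @return An `interaction_classification` object: list with `sets` (named
#'   list of per-condition gene sets), `vs_pairwise` and `vs_community`
#'   ([classify_vs_alone()] results), `partner_induced` /
#'   `partner_alleviated` (breakdown tibbles), `cross_induced` /
#'   `cross_alleviated`, `core`, and `higher_order` (summary tibble).
#' @examples
#' # see vignette("barseqfit-methods") for an end-to-end example
#' @export
classify_interactions <- function(fitness, alone = "alone",
                                  pairwise = c("pairwise_1", "pairwise_2",
                                               "pairwise_3"),
                                  community = "community",
                                  t_threshold = 3, rule = c("all", "any")) {
  rule <- match.arg(rule)
  sig <- significant_sets(fitness, t_threshold)
  conds <- c(alone, pairwise, community)
  missing_conds <- setdiff(conds, unique(
    if (inherits(fitness, "tnseq_fitness")) fitness$fitness$condition
    else fitness$condition
  ))
  if (length(missing_conds)) {
    abort(sprintf("condition(s) not in fitness table: %s.",
                  paste(missing_conds, collapse = ", ")))
  }
  sets <- lapply(setNames(conds, conds), condition_set, sets = sig)

  vs_pairwise <- classify_vs_alone(sets[[alone]], sets[pairwise], rule = rule)
  vs_community <- classify_vs_alone(sets[[alone]], sets[[community]])

  structure(
    list(
      sets = sets,
      significant = sig,
      vs_pairwise = vs_pairwise,
      vs_community = vs_community,
      partner_induced = partner_breakdown("induced", sets[[alone]],
                                          sets[pairwise]),
      partner_alleviated = partner_breakdown("alleviated", sets[[alone]],
                                             sets[pairwise]),
      cross_induced = cross_classify(vs_pairwise$induced,
                                     vs_community$induced),
      cross_alleviated = cross_classify(vs_pairwise$alleviated,
                                        vs_community$alleviated),
      core = core_set(sets),
      labels = list(alone = alone, pairwise = pairwise,
                    community = community),
      t_threshold = t_threshold, rule = rule
    ),
    class = "interaction_classification"
  )
}

#' @export
print.interaction_classification <- function(x, ...) {
  ho <- higher_order_summary(x$cross_induced, x$cross_alleviated)
  cat("<interaction_classification>\n")
  cat(sprintf("  per-condition set sizes: %s\n",
              paste(sprintf("%s=%d", names(x$sets), lengths(x$sets)),
                    collapse = ", ")))
  cat(sprintf("  vs pairwise: conserved %d / induced %d / alleviated %d\n",
              length(x$vs_pairwise$conserved), length(x$vs_pairwise$induced),
              length(x$vs_pairwise$alleviated)))
  cat(sprintf("  vs community: conserved %d / induced %d / alleviated %d\n",
              length(x$vs_community$conserved),
              length(x$vs_community$induced),
              length(x$vs_community$alleviated)))
  cat(sprintf("  core %d; pairwise-derived %d (%s%%) vs higher-order %d (%s%%)\n",
              length(x$core), ho$pairwise_derived, ho$fraction_pairwise_pct,
              ho$higher_order, ho$fraction_higher_pct))
  invisible(x)
}

#' Tidy an interaction classification
#'
#' @param x An `interaction_classification`.
#' @param ... Unused.
#' @return A long tibble, one row per gene and classification label:
#'   `locus_tag`, `comparison` (`condition`, `vs_pairwise`, `vs_community`,
#'   `cross_induced`, `cross_alleviated`, `core`), `label`.
#' @exportS3Method generics::tidy
tidy.interaction_classification <- function(x, ...) {
  rows <- list()
  add <- function(comparison, label, genes) {
    if (length(genes)) {
      rows[[length(rows) + 1L]] <<- tibble(
        locus_tag = genes, comparison = comparison, label = label
      )
    }
  }
  for (cond in names(x$sets)) add("condition", cond, x$sets[[cond]])
  for (lab in c("conserved", "induced", "alleviated")) {
    add("vs_pairwise", lab, x$vs_pairwise[[lab]])
    add("vs_community", lab, x$vs_community[[lab]])
  }
  for (lab in names(x$cross_induced)) {
    add("cross_induced", lab, x$cross_induced[[lab]])
    add("cross_alleviated", lab, x$cross_alleviated[[lab]])
  }
  add("core", "core", x$core)
  bind_rows(rows)
}

#' One-row count summary of an interaction classification
#'
#' @param x An `interaction_classification`.
#' @param ... Unused.
#' @return One-row tibble with all category counts and the higher-order
#'   percentages.
#' @exportS3Method generics::glance
glance.interaction_classification <- function(x, ...) {
  ho <- higher_order_summary(x$cross_induced, x$cross_alleviated)
  bind_cols(
    tibble(
      n_alone = length(x$sets[[x$labels$alone]]),
      n_community = length(x$sets[[x$labels$community]]),
      pairwise_conserved = length(x$vs_pairwise$conserved),
      pairwise_induced = length(x$vs_pairwise$induced),
      pairwise_alleviated = length(x$vs_pairwise$alleviated),
      community_conserved = length(x$vs_community$conserved),
      community_induced = length(x$vs_community$induced),
      community_alleviated = length(x$vs_community$alleviated),
      core = length(x$core)
    ),
    ho
  )
}

#' Category-count bar chart for an interaction classification
#'
#' @param object An `interaction_classification`.
#' @param ... Unused.
#' @return A ggplot of category sizes by comparison.
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_classification <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::count(.data$comparison, .data$label)
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Recover planted interaction categories from a classification
#'
#' Maps each gene's per-condition significant-set memberships back onto the
#' interaction-category vocabulary of [sim_truth()], using the same three
#' comparisons the analysis performs: required alone (`A`), required in all
#' pairwise co-cultures (the intersection, matching the default conserved
#' rule), and required in the community. Genes matching no named pattern are
#' labelled `other`. Useful for validating the pipeline against a known
#' truth table.
#'
#' @param classification An `interaction_classification`.
#' @param locus_tags Genes to classify (default: every gene in any set).
#' @return A tibble: `locus_tag`, `category`.
#' @export
recover_categories <- function(classification,
                               locus_tags = NULL) {
  stopifnot(inherits(classification, "interaction_classification"))
  labs <- classification$labels
  sets <- classification$sets
  if (is.null(locus_tags)) {
    locus_tags <- unique(unlist(sets, use.names = FALSE))
  }
  a <- locus_tags %in% sets[[labs$alone]]
  p <- locus_tags %in% Reduce(intersect, sets[labs$pairwise])
  cm <- locus_tags %in% sets[[labs$community]]
  category <- dplyr::case_when(
    a & p & cm ~ "conserved",
    a & !p & !cm ~ "alone_required",
    !a & p & cm ~ "pairwise_induced",
    a & !p & cm ~ "pairwise_alleviated",
    !a & !p & cm ~ "community_specific_induced",
    a & p & !cm ~ "community_specific_alleviated",
    !a & !p & !cm ~ "neutral",
    TRUE ~ "other"
  )
  tibble(locus_tag = locus_tags, category = category)
}

#' Write classification outputs
#'
#' Writes per-condition gene-set TSVs, the long-format classification table,
#' and a JSON summary of all category counts and higher-order fractions.
#'
#' @param x An `interaction_classification`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_classification <- function(x, dir = ".") {
  stopifnot(inherits(x, "interaction_classification"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (cond in names(x$sets)) {
    p <- file.path(dir, sprintf("set_%s.tsv", cond))
    readr::write_tsv(tibble(locus_tag = sort(x$sets[[cond]])), p)
    paths <- c(paths, p)
  }
  long <- file.path(dir, "classification.tsv")
  readr::write_tsv(tidy(x), long)
  paths <- c(paths, long)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    js <- file.path(dir, "classification_summary.json")
    jsonlite::write_json(as.list(glance(x)), js, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, js)
  }
  invisible(paths)
}
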