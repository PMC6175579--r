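#' @export
print.tnseq_fitness <- function(x, ...) {
  cat(sprintf(
    "<tnseq_fitness> %d gene(s) x %d condition-timepoint(s); %d retained strain(s)\n",
    length(x$scored_genes),
    nrow(distinct(x$fitness[, c("condition", "timepoint")])),
    x$attrition[["retained"]]
  ))
  invisible(x)
}

#' Tidy a fitness result
#'
#' @param x A `tnseq_fitness` object.
#' @param ... Unused.
#' @return The gene fitness tibble (one row per gene x condition x
#'   timepoint).
#' @exportS3Method generics::tidy
tidy.tnseq_fitness <- function(x, ...) {
  x$fitness
}

#' One-row summary of a fitness result
#'
#' @param x A `tnseq_fitness` object.
#' @param ... Unused.
#' @return A one-row tibble: genes scored, retained strains, number of
#'   condition-timepoints, fraction of records passing the significance rule
#'   (`|t| >=` threshold with negative fitness), and the median |fitness|.
#' @exportS3Method generics::glance
glance.tnseq_fitness <- function(x, ...) {
  tau <- x$config$t_threshold
  f <- x$fitness
  tibble(
    n_genes = length(x$scored_genes),
    n_strains = unname(x$attrition[["retained"]]),
    n_condition_timepoints =
      nrow(distinct(f[, c("condition", "timepoint")])),
    frac_significant_negative = mean(abs(f$t) >= tau & f$fitness < 0),
    median_abs_fitness = median(abs(f$fitness))
  )
}

#' Volcano plot of gene fitness versus t-score
#'
#' @param object A `tnseq_fitness` object.
#' @param ... Unused.
#' @return A ggplot: fitness on x, t-score on y, faceted by condition,
#'   significant-negative genes highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.tnseq_fitness <- function(object, ...) {
  tau <- object$config$t_threshold
  df <- object$fitness |>
    mutate(significant = abs(.data$t) >= tau & .data$fitness < 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$fitness, .data$t,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = c(-tau, tau), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "black")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "gene fitness (log2)", y = "t-score",
                  colour = sprintf("|t| >= %g & f < 0", tau)) +
    ggplot2::theme_bw()
}

#' Write per-condition fitness tables
#'
#' Writes one TSV per condition-timepoint plus a combined long-format TSV.
#'
#' @param x A `tnseq_fitness` object.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_fitness <- function(x, dir = ".") {
  stopifnot(inherits(x, "tnseq_fitness"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  combined <- file.path(dir, "fitness_all.tsv")
  readr::write_tsv(x$fitness, combined)
  paths <- combined
  combos <- distinct(x$fitness[, c("condition", "timepoint")])
  for (i in seq_len(nrow(combos))) {
    sub <- x$fitness[x$fitness$condition == combos$condition[i] &
                       x$fitness$timepoint == combos$timepoint[i], ]
    p <- file.path(dir, sprintf("fitness_%s_%s.tsv", combos$condition[i],
                                combos$timepoint[i]))
    readr::write_tsv(sub, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
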