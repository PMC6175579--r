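#' Describe a pooled-fitness experimental design
#'
#' Captures the study layout the simulator and the fitness pipeline share:
#' growth conditions (growth alone, pairwise co-cultures with each partner,
#' and the full community), harvest timepoints, replicates per
#' condition-timepoint, sequencing depth per sample, and the amplitude of the
#' chromosome-position bias. A single shared T0 (inoculum) sample is implied.
#'
#' @param conditions Character vector of condition labels. Defaults to one
#'   `alone` condition, three pairwise co-cultures and one `community`.
#' @param alone,community The labels within `conditions` playing the
#'   growth-alone and full-community roles.
#' @param pairwise The labels playing pairwise-co-culture roles.
#' @param timepoints Character vector of harvest timepoints, in chronological
#'   order (planted effects accumulate linearly across them).
#' @param replicates Replicates per condition-timepoint (default 3).
#' @param depth Sequencing reads per sample (default 2e6, within the
#'   1.5-7.5 million reads per sample typical of BarSeq runs).
#' @param position_bias Multiplicative log2 amplitude of the cosine
#'   chromosome-position bias applied to harvest samples (default 0.3),
#'   emulating replication-associated copy-number variation along the
#'   chromosome.
#' @param seed Integer seed driving all simulation randomness downstream.
#' @return A `sim_design` object (named list).
#' @examples
#' sim_design(replicates = 3, depth = 2e6)
#' @export
sim_design <- function(conditions = c("alone", "pairwise_1", "pairwise_2",
                                      "pairwise_3", "community"),
                       alone = "alone",
                       pairwise = grep("^pairwise", conditions, value = TRUE),
                       community = "community",
                       timepoints = c("day1", "day2", "day3"),
                       replicates = 3, depth = 2e6,
                       position_bias = 0.3, seed = 1) {
  assert_scalar_number(replicates, "replicates", lower = 1)
  assert_scalar_number(depth, "depth", lower = 1)
  assert_scalar_number(position_bias, "position_bias", lower = 0)
  stopifnot(length(conditions) >= 1, length(timepoints) >= 1)
  roles <- c(alone, pairwise, community)
  roles <- roles[roles %in% conditions]
  structure(
    list(
      conditions = conditions,
      alone = if (alone %in% conditions) alone else NULL,
      pairwise = intersect(pairwise, conditions),
      community = if (community %in% conditions) community else NULL,
      timepoints = timepoints,
      replicates = as.integer(replicates),
      depth = as.integer(depth),
      position_bias = position_bias,
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> %d condition(s) x %d timepoint(s) x %d replicate(s) + T0; depth %s reads; bias %.2f; seed %d\n",
    length(x$conditions), length(x$timepoints), x$replicates,
    format(x$depth, big.mark = ","), x$position_bias, x$seed
  ))
  invisible(x)
}

#' Sample sheet implied by a design
#'
#' @param design A [sim_design()].
#' @return Tibble with `sample`, `condition`, `timepoint`, `replicate`,
#'   `role` (one `T0` row plus one row per condition-timepoint-replicate).
#' @examples
#' design_samples(sim_design(replicates = 2))
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  grid <- tidyr::expand_grid(
    condition = design$conditions,
    timepoint = design$timepoints,
    replicate = seq_len(design$replicates)
  )
  bind_rows(
    tibble(sample = "T0", condition = NA_character_,
           timepoint = NA_character_, replicate = NA_integer_, role = "T0"),
    tibble(
      sample = sprintf("%s_%s_rep%d", grid$condition, grid$timepoint,
                       grid$replicate),
      condition = grid$condition, timepoint = grid$timepoint,
      replicate = grid$replicate, role = "harvest"
    )
  )
}
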