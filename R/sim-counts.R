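#' Simulate BarSeq read counts for a designed experiment
#'
#' Draws a barcode-by-sample count matrix with the statistical structure the
#' fitness analysis assumes. Each strain gets a T0 (inoculum) relative
#' abundance drawn log-normal, modelling uneven library representation. For a
#' harvest sample of condition c and timepoint d, strain s in gene g has
#' relative weight
#' `a0_s * 2^phi(g, c, d) * 2^(b * cos(2 * pi * pos_s / L))`,
#' where `phi` is the planted cumulative log2 effect and the cosine term is a
#' chromosome-position copy-number bias (amplitude `b =
#' design$position_bias`) applied to harvest samples only. Each sample's
#' counts are a single multinomial draw of `design$depth` reads over strains,
#' so column sums equal the depth exactly. The T0 sample is drawn from the
#' `a0` weights alone. All randomness derives from `design$seed`.
#'
#' @param pool A `pool_table` (see [sim_pool()]).
#' @param truth A `truth_table` (see [sim_truth()]); genes absent from it are
#'   treated as neutral, as are intergenic insertions.
#' @param design A [sim_design()].
#' @param genome The `genome_annotation` the pool was drawn from; required
#'   when `design$position_bias > 0` (supplies scaffold lengths for the
#'   cosine bias).
#' @param t0_sdlog Standard deviation (natural-log scale) of the log-normal
#'   T0 abundances (default 0.5).
#' @return A [count_matrix()].
#' @examples
#' g <- sim_genome(30, 1e5, seed = 1)
#' d <- sim_design(conditions = "alone", timepoints = "day1",
#'                 replicates = 2, depth = 1e4)
#' tr <- sim_truth(g, d, fractions = c(conserved = 0.1), seed = 1)
#' cm <- sim_counts(sim_pool(g, 300, seed = 1), tr, d, genome = g)
#' colSums(cm$counts)
#' @export
sim_counts <- function(pool, truth, design, genome = NULL, t0_sdlog = 0.5) {
  validate_pool(pool)
  stopifnot(inherits(design, "sim_design"))
  assert_columns(truth, c("locus_tag", "condition", "timepoint", "phi"),
                 "truth")

  samples <- design_samples(design)
  n <- nrow(pool)

  # phi per gene x (condition, timepoint), strains mapped via locus_tag
  phi_tbl <- truth[truth$condition %in% design$conditions &
                     truth$timepoint %in% design$timepoints, ]
  phi_key <- paste(phi_tbl$condition, phi_tbl$timepoint)

  # cosine chromosome-position bias (harvest samples only)
  bias <- rep(1, n)
  if (design$position_bias > 0) {
    if (is.null(genome)) {
      abort("`genome` is required when `design$position_bias > 0`.")
    }
    validate_genome(genome)
    sc_len <- setNames(genome$scaffolds$length, genome$scaffolds$scaffold)
    bias <- 2^(design$position_bias *
                 cos(2 * pi * pool$pos / sc_len[pool$scaffold]))
  }

  with_seed(design$seed, {
    a0 <- rlnorm(n, meanlog = 0, sdlog = t0_sdlog)

    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(pool$barcode, samples$sample))
    counts[, "T0"] <- as.integer(rmultinom(1, design$depth, a0))

    for (cond in design$conditions) {
      for (tp in design$timepoints) {
        rows <- phi_tbl[phi_key == paste(cond, tp), ]
        phi_g <- setNames(rows$phi, rows$locus_tag)
        phi_s <- phi_g[pool$locus_tag]
        phi_s[is.na(phi_s)] <- 0
        w <- a0 * 2^phi_s * bias
        for (r in seq_len(design$replicates)) {
          smp <- sprintf("%s_%s_rep%d", cond, tp, r)
          counts[, smp] <- as.integer(rmultinom(1, design$depth, w))
        }
      }
    }
    count_matrix(counts, samples)
  })
}
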