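#' Configuration for the fitness pipeline
#'
#' @param pseudocount Pseudocount (reads) added to strain counts in the
#'   log-ratio, guarding zeros (default 1).
#' @param min_t0_reads Minimum T0 reads for a barcode to be retained
#'   (default 3; barcodes with fewer are ignored).
#' @param min_t0_gene_reads Minimum summed T0 reads (over retained barcodes)
#'   for a gene to be scored (default 30).
#' @param central_only Use only insertions in the central 10-90% of genes
#'   (default `TRUE`).
#' @param window Gene-count width of the smoothed-median position
#'   normalisation window (odd, default 251).
#' @param t_threshold Significance threshold on `|t|` (default 3, inclusive).
#' @param mode_grid Grid points for the kernel-density mode estimate
#'   (default 512).
#' @return A `fitness_config` (named list).
#' @examples
#' fitness_config()
#' @export
fitness_config <- function(pseudocount = 1, min_t0_reads = 3,
                           min_t0_gene_reads = 30, central_only = TRUE,
                           window = 251, t_threshold = 3, mode_grid = 512) {
  assert_scalar_number(pseudocount, "pseudocount", lower = 1e-9)
  assert_scalar_number(window, "window", lower = 3)
  assert_scalar_number(t_threshold, "t_threshold", lower = 1e-9)
  assert_scalar_number(min_t0_reads, "min_t0_reads", lower = 0)
  assert_scalar_number(min_t0_gene_reads, "min_t0_gene_reads", lower = 0)
  if (window %% 2 == 0) abort("`window` must be odd.")
  structure(
    list(pseudocount = pseudocount, min_t0_reads = min_t0_reads,
         min_t0_gene_reads = min_t0_gene_reads,
         central_only = isTRUE(central_only), window = as.integer(window),
         t_threshold = t_threshold, mode_grid = as.integer(mode_grid)),
    class = "fitness_config"
  )
}

#' Strain filters and gene scoring eligibility
#'
#' Applies the three count-based filters: (i) only insertions in the central
#' 10-90% of genes are considered, (ii) barcodes with fewer than
#' `min_t0_reads` reads in the T0 sample are ignored, and (iii) genes whose
#' retained barcodes sum to fewer than `min_t0_gene_reads` T0 reads are not
#' scored.
#'
#' @param counts A [count_matrix()].
#' @param pool A `pool_table`.
#' @param config A [fitness_config()].
#' @return A list: `strains` (tibble of pool rows joined with T0 counts and a
#'   `retained` flag), `scored_genes` (character vector), and `attrition`
#'   (named counts of what each rule removed).
#' @export
apply_filters <- function(counts, pool, config = fitness_config()) {
  stopifnot(inherits(counts, "count_matrix"))
  validate_pool(pool)
  pool <- pool[pool$barcode %in% rownames(counts$counts), ]
  t0 <- unname(counts$counts[pool$barcode, t0_sample(counts)])

  in_gene <- !is.na(pool$locus_tag)
  central_ok <- if (config$central_only) pool$central & in_gene else in_gene
  t0_ok <- t0 >= config$min_t0_reads
  retained <- central_ok & t0_ok

  gene_t0 <- rowsum(t0[retained], pool$locus_tag[retained])
  scored <- rownames(gene_t0)[gene_t0[, 1] >= config$min_t0_gene_reads]
  if (length(scored) == 0L) {
    abort(paste0(
      "no gene passes the T0 filters (", sum(retained), " retained strain(s), ",
      "max per-gene T0 total ",
      if (nrow(gene_t0)) max(gene_t0) else 0, "); check depth and pool."
    ))
  }

  strains <- pool
  strains$t0 <- as.integer(t0)
  strains$retained <- retained
  list(
    strains = strains,
    scored_genes = scored,
    attrition = c(
      barcodes_total = nrow(pool),
      dropped_not_central = sum(!central_ok),
      dropped_low_t0 = sum(central_ok & !t0_ok),
      retained = sum(retained),
      genes_with_retained_strains = nrow(gene_t0),
      genes_scored = length(scored)
    )
  )
}

#' Per-strain fitness: depth-normalised log2 abundance ratio
#'
#' `f_s = log2((n_h + psi) / (n_0 + psi)) - log2(N_h / N_0)`: the log2 change
#' in a mutant's abundance between a harvest sample and the T0 inoculum,
#' where abundance is read count normalised by the sample total over retained
#' barcodes.
#'
#' @param n_h,n_0 Strain read counts at harvest and T0 (vectors).
#' @param total_h,total_0 Sample total reads over retained barcodes.
#' @param pseudocount Pseudocount added to strain counts (default 1).
#' @return Numeric vector of strain fitness values (log2 units).
#' @examples
#' strain_fitness(12, 3, 2000, 1000)  # log2(13/4) - 1
#' @export
strain_fitness <- function(n_h, n_0, total_h, total_0, pseudocount = 1) {
  stopifnot(total_h > 0, total_0 > 0, all(n_h >= 0), all(n_0 >= 0))
  log2((n_h + pseudocount) / (n_0 + pseudocount)) - log2(total_h / total_0)
}

#' Count-based strain weights for gene averaging
#'
#' `w_s = 1 / (1/(1 + n_0) + 1/(1 + n_h))` — the inverse of the
#' Poisson-approximate variance of the strain log-ratio (up to a constant),
#' so well-measured strains dominate the gene average.
#'
#' @param n_0,n_h Strain read counts at T0 and harvest.
#' @return Numeric vector of positive weights.
#' @export
strain_weights <- function(n_0, n_h) {
  1 / (1 / (1 + n_0) + 1 / (1 + n_h))
}

#' Raw gene fitness: weighted average of strain fitness
#'
#' @param f Strain fitness values.
#' @param w Positive strain weights.
#' @return The weighted mean `sum(w * f) / sum(w)`.
#' @examples
#' gene_fitness_raw(c(-1, -2), c(1, 3))  # -1.75
#' @export
gene_fitness_raw <- function(f, w) {
  stopifnot(length(f) == length(w), length(f) >= 1, all(w > 0))
  sum(w * f) / sum(w)
}

#' Chromosome-position (smoothed-median) normalisation
#'
#' Subtracts from each gene's raw fitness the median raw fitness of the
#' `window` genes centred on it in chromosome order, removing slowly varying
#' position effects such as replication-associated copy-number bias. On
#' circular scaffolds the window wraps around; on linear scaffolds it
#' truncates at the ends. Scaffolds with fewer scored genes than `window`
#' fall back to subtracting the scaffold-wide median.
#'
#' @param f Raw gene fitness values.
#' @param pos Gene positions (bp); ordering within scaffold is what matters.
#' @param scaffold Scaffold of each gene (single string or vector).
#' @param circular Named logical (per scaffold) or single flag (default
#'   `TRUE`).
#' @param window Odd window width in genes (default 251).
#' @return Adjusted fitness values, in input order.
#' @export
normalize_position <- function(f, pos, scaffold = "chr1", circular = TRUE,
                               window = 251) {
  stopifnot(length(f) == length(pos))
  if (length(scaffold) == 1L) scaffold <- rep(scaffold, length(f))
  out <- f
  for (sc in unique(scaffold)) {
    idx <- which(scaffold == sc)
    ord <- idx[order(pos[idx])]
    v <- f[ord]
    circ <- if (length(circular) == 1L) circular else isTRUE(circular[[sc]])
    out[ord] <- v - running_median(v, window, circ)
  }
  out
}

# Running median of width W (odd) over v; circular wrap or truncated ends.
# Falls back to the global median when length(v) < W.
running_median <- function(v, window, circular) {
  n <- length(v)
  if (n < window) return(rep(median(v), n))
  h <- (window - 1L) %/% 2L
  if (circular) {
    padded <- c(tail(v, h), v, head(v, h))
    stats::runmed(padded, window, endrule = "keep")[(h + 1L):(h + n)]
  } else {
    vapply(seq_len(n), function(i) {
      median(v[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
  }
}

#' Mode normalisation of gene fitness
#'
#' Centres the fitness distribution on its mode, under the assumption that
#' disrupting most genes has little or no fitness effect, so the bulk of
#' genes should sit at exactly 0. The mode is the argmax of a Gaussian kernel
#' density (Silverman's rule-of-thumb bandwidth) evaluated on a uniform grid
#' spanning the data range.
#'
#' @param f Position-adjusted gene fitness values (at least 10).
#' @param grid Number of grid points (default 512).
#' @return `f` minus its estimated mode.
#' @seealso [estimate_mode()]
#' @export
normalize_mode <- function(f, grid = 512) {
  f - estimate_mode(f, grid)
}

#' @rdname normalize_mode
#' @export
estimate_mode <- function(f, grid = 512) {
  if (length(f) < 10) {
    abort("mode estimation needs at least 10 values.")
  }
  if (diff(range(f)) < .Machine$double.eps^0.5) return(f[1])
  d <- density(f, bw = "nrd0", n = grid, from = min(f), to = max(f))
  d$x[which.max(d$y)]
}

#' Moderated t-scores from per-replicate gene fitness
#'
#' Combines per-replicate gene fitness and variance into a single moderated
#' t-statistic per gene: the ratio of the replicate-mean fitness to a
#' variance-stabilised standard deviation. The gene variance is
#' `V_g = (1/R^2) * sum_r V_r + ((R - 1) / R) * C`, where `V_r` is the
#' per-replicate variance (strain-to-strain spread, floored by the
#' Poisson-counting variance) and `C` is the T0 counting component of the
#' variance, which does not average away across replicates because all
#' replicates share one T0 reference. Moderation shrinks `V_g` halfway
#' toward the across-gene median before forming
#' `t = mean fitness / sqrt((V_g + median(V_g)) / 2)`.
#'
#' @param fitness Matrix (genes x replicates) of normalised per-replicate
#'   gene fitness.
#' @param variance Matrix (genes x replicates) of per-replicate gene
#'   variances.
#' @param t0_component Vector (genes) of the shared-T0 variance component
#'   (default 0, appropriate when each replicate has its own reference).
#' @return Tibble: `fitness` (replicate mean), `variance` (moderated), `t`.
#' @export
t_scores <- function(fitness, variance, t0_component = 0) {
  fitness <- as.matrix(fitness)
  variance <- as.matrix(variance)
  stopifnot(identical(dim(fitness), dim(variance)))
  R <- ncol(fitness)
  if (length(t0_component) == 1L) {
    t0_component <- rep(t0_component, nrow(fitness))
  }
  fbar <- rowMeans(fitness)
  v_gene <- rowSums(variance) / R^2 + (R - 1) / R * t0_component
  v_mod <- (v_gene + median(v_gene)) / 2
  tibble(fitness = fbar, variance = v_mod, t = fbar / sqrt(v_mod))
}

#' Run the full gene-fitness pipeline
#'
#' For every condition and timepoint: applies the T0/centrality filters,
#' computes depth-normalised strain fitness against the shared T0, averages
#' strains into raw gene fitness with count-based weights, normalises for
#' chromosome position (smoothed median) and distribution mode per
#' replicate, then averages replicates and attaches a moderated t-score
#' (see [t_scores()]).
#'
#' @param counts A [count_matrix()].
#' @param pool A `pool_table`.
#' @param config A [fitness_config()].
#' @param genome Optional `genome_annotation`; supplies per-scaffold circular
#'   flags for the position normalisation (default: circular).
#' @return A `tnseq_fitness` object. Its `fitness` element (also returned by
#'   [tidy()]) has one row per scored gene x condition x timepoint:
#'   `locus_tag`, `condition`, `timepoint`, `fitness` (replicate-mean
#'   normalised, log2), `t`, `n_strains`, `t0_reads`, `mean_harvest_reads`.
#' @examples
#' g <- sim_genome(60, 3e5, seed = 1)
#' d <- sim_design(conditions = "alone", timepoints = "day1", depth = 2e5,
#'                 position_bias = 0, seed = 1)
#' tr <- sim_truth(g, d, fractions = c(conserved = 0.1), effect = -3, seed = 1)
#' cm <- sim_counts(sim_pool(g, 2000, seed = 1), tr, d)
#' fit <- run_fitness(cm, sim_pool(g, 2000, seed = 1))
#' head(tidy(fit))
#' @export
run_fitness <- function(counts, pool, config = fitness_config(),
                        genome = NULL) {
  flt <- apply_filters(counts, pool, config)
  strains <- flt$strains[flt$strains$retained, ]
  strains <- strains[strains$locus_tag %in% flt$scored_genes, ]
  gene_f <- factor(strains$locus_tag)
  genes <- levels(gene_f)
  n_genes <- length(genes)
  psi <- config$pseudocount
  inv_ln2_sq <- 1 / log(2)^2

  circ <- TRUE
  if (!is.null(genome)) {
    circ <- setNames(genome$scaffolds$circular, genome$scaffolds$scaffold)
  }

  # per-gene chromosome anchor for the position normalisation
  gene_pos <- tibble(
    locus_tag = genes,
    scaffold = as.character(tapply(strains$scaffold, gene_f, `[`, 1)),
    pos = as.numeric(tapply(strains$pos, gene_f, median))
  )

  t0s <- strains$t0
  total_0 <- sum(t0s)
  gene_t0 <- as.vector(rowsum(t0s, gene_f))
  n_strains <- as.vector(table(gene_f))

  hs <- harvest_samples(counts)
  combos <- distinct(hs[, c("condition", "timepoint")])
  records <- vector("list", nrow(combos))

  for (i in seq_len(nrow(combos))) {
    cond <- combos$condition[i]
    tp <- combos$timepoint[i]
    reps <- hs$sample[hs$condition == cond & hs$timepoint == tp]
    R <- length(reps)
    f_norm <- v_rep <- matrix(NA_real_, n_genes, R)
    c_shared <- matrix(NA_real_, n_genes, R)
    nh_gene <- matrix(NA_real_, n_genes, R)

    for (r in seq_len(R)) {
      nh <- counts$counts[strains$barcode, reps[r]]
      total_h <- sum(nh)
      f_s <- strain_fitness(nh, t0s, total_h, total_0, psi)
      w <- strain_weights(t0s, nh)
      sw <- as.vector(rowsum(w, gene_f))
      f_g <- as.vector(rowsum(w * f_s, gene_f)) / sw
      resid <- f_s - f_g[as.integer(gene_f)]
      v_strain <- as.vector(rowsum(w^2 * resid^2, gene_f)) / sw^2
      nh_g <- as.vector(rowsum(nh, gene_f))
      v_floor <- inv_ln2_sq * (1 / (1 + gene_t0) + 1 / (1 + nh_g))
      v_rep[, r] <- pmax(v_strain, v_floor)
      c_shared[, r] <- inv_ln2_sq *
        pmax(as.vector(rowsum(w^2 / (1 + t0s), gene_f)) / sw^2,
             1 / (1 + gene_t0))
      nh_gene[, r] <- nh_g

      adj <- normalize_position(f_g, gene_pos$pos, gene_pos$scaffold,
                                circular = circ, window = config$window)
      f_norm[, r] <- normalize_mode(adj, config$mode_grid)
    }

    ts <- t_scores(f_norm, v_rep, rowMeans(c_shared))
    records[[i]] <- tibble(
      locus_tag = genes, condition = cond, timepoint = tp,
      fitness = ts$fitness, t = ts$t, n_strains = n_strains,
      t0_reads = gene_t0, mean_harvest_reads = rowMeans(nh_gene)
    )
  }

  structure(
    list(
      fitness = bind_rows(records),
      config = config,
      attrition = flt$attrition,
      scored_genes = genes,
      gene_pos = gene_pos
    ),
    class = "tnseq_fitness"
  )
}
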