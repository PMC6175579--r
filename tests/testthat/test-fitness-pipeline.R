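test_that("the T0 filters drop the documented strains and genes", {
  g <- sim_genome(3, 12000, seed = 23, gene_length = c(2000, 3000))
  genes <- g$genes$locus_tag
  pool <- tibble::tibble(
    barcode = replicate(6, paste(sample(c("A", "C", "G", "T"), 20,
                                        replace = TRUE), collapse = "")),
    scaffold = "chr1",
    strand = "+",
    pos = as.integer(g$genes$start[c(1, 1, 2, 2, 3, 3)] +
                       0.5 * (g$genes$end[c(1, 1, 2, 2, 3, 3)] -
                                g$genes$start[c(1, 1, 2, 2, 3, 3)])),
    locus_tag = genes[c(1, 1, 2, 2, 3, 3)],
    gene_fraction = 0.5,
    central = TRUE
  )
  pool$gene_fraction[6] <- 0.95  # non-central insertion
  pool$central[6] <- FALSE
  class(pool) <- c("pool_table", class(pool))
  sheet <- tibble::tibble(sample = c("T0", "s1"), condition = c(NA, "alone"),
                          timepoint = c(NA, "day1"), replicate = c(NA, 1L),
                          role = c("T0", "harvest"))
  # gene1: strains 20+20 (scored); gene2: 2 reads (barcode dropped) + 28
  #   (gene total 28 < 30, not scored); gene3: 40 central + 500 non-central
  t0 <- c(20L, 20L, 2L, 28L, 40L, 500L)
  mat <- cbind(T0 = t0, s1 = t0)
  rownames(mat) <- pool$barcode
  cm <- count_matrix(mat, sheet)
  flt <- apply_filters(cm, pool)
  expect_setequal(flt$scored_genes, genes[c(1, 3)])
  expect_identical(flt$strains$retained,
                   c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(unname(flt$attrition["dropped_low_t0"]), 1L)
  expect_equal(unname(flt$attrition["dropped_not_central"]), 1L)
})

test_that("an empty scored gene set is a hard error with diagnostics", {
  pool <- tiny_pool()
  sheet <- tibble::tibble(sample = c("T0", "s1"), condition = c(NA, "alone"),
                          timepoint = c(NA, "day1"), replicate = c(NA, 1L),
                          role = c("T0", "harvest"))
  mat <- matrix(1L, nrow = nrow(pool), ncol = 2,
                dimnames = list(pool$barcode, c("T0", "s1")))
  cm <- count_matrix(mat, sheet)
  expect_error(apply_filters(cm, pool), "no gene passes")
})

test_that("identical T0 and harvest counts give zero fitness and t", {
  g <- sim_genome(30, 1.5e5, seed = 24)
  pool <- sim_pool(g, central_per_gene = 3, intergenic_fraction = 0,
                   seed = 24)
  sheet <- tibble::tibble(
    sample = c("T0", "s1", "s2"), condition = c(NA, "alone", "alone"),
    timepoint = c(NA, "day1", "day1"), replicate = c(NA, 1L, 2L),
    role = c("T0", "harvest", "harvest")
  )
  t0 <- rep(50L, nrow(pool))
  mat <- cbind(T0 = t0, s1 = t0, s2 = t0)
  rownames(mat) <- pool$barcode
  fit <- run_fitness(count_matrix(mat, sheet), pool, genome = g)
  f <- tidy(fit)
  expect_equal(f$fitness, rep(0, nrow(f)))
  expect_equal(f$t, rep(0, nrow(f)))
})

test_that("single-strain genes get a finite floor-based t", {
  fitness <- matrix(c(-1, -1.2), nrow = 1)
  variance <- matrix((1 / log(2)^2) * (1 / 31 + 1 / c(11, 16)), nrow = 1)
  res <- t_scores(fitness, variance, t0_component = (1 / log(2)^2) / 31)
  expect_true(is.finite(res$t))
  expect_equal(res$fitness, -1.1)
  R <- 2
  v_expected <- sum(variance) / R^2 + (R - 1) / R * (1 / log(2)^2) / 31
  expect_equal(res$variance, v_expected)  # median moderation is a no-op here
  expect_equal(res$t, -1.1 / sqrt(v_expected))
})

test_that("record count equals scored genes x conditions x timepoints", {
  sim <- mid_sim()
  f <- tidy(sim$fit)
  expect_equal(
    nrow(f),
    length(sim$fit$scored_genes) * length(sim$design$conditions) *
      length(sim$design$timepoints)
  )
  expect_true(all(is.finite(f$t)))
  expect_true(all(f$n_strains >= 1))
})

test_that("planted strong effects are recovered and the null is calibrated", {
  sim <- mid_sim()
  f <- tidy(sim$fit)
  day1 <- f[f$timepoint == "day1" & f$condition == "alone", ]
  planted <- unique(sim$truth$locus_tag[sim$truth$category == "conserved"])
  est <- day1$fitness[day1$locus_tag %in% planted]
  expect_gt(length(est), 0)
  expect_lt(max(abs(est + 3)), 1)
  # null genes: t roughly standard normal
  neutral <- unique(sim$truth$locus_tag[sim$truth$category == "neutral"])
  tnull <- f$t[f$locus_tag %in% neutral]
  expect_gt(sd(tnull), 0.7)
  expect_lt(sd(tnull), 1.3)
})

test_that("the post-normalisation fitness mode sits near zero", {
  sim <- mid_sim()
  f <- tidy(sim$fit)
  modes <- vapply(
    split(f$fitness, paste(f$condition, f$timepoint)),
    estimate_mode, numeric(1)
  )
  expect_lt(max(abs(modes)), 0.05)
})
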