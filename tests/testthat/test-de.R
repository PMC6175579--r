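test_that("DE thresholds are inclusive on fold change, exclusive on padj", {
  de <- tibble::tibble(
    locus_tag = c("a", "b", "c", "d"),
    contrast = "p1", timepoint = "day1",
    log2FC = c(1.0, 2.0, -1.0, 0.9),
    padj = c(0.005, 0.02, 0.009, 0.001)
  )
  sets <- de_sets(de)
  expect_setequal(sets$locus_tag[sets$direction == "up"], "a")
  expect_setequal(sets$locus_tag[sets$direction == "down"], "c")
  strict <- de_sets(de, strict_gt = TRUE)
  expect_equal(nrow(strict), 0L)
})

test_that("timepoints pool by union and directions stay exclusive", {
  de <- dplyr::bind_rows(
    sim_de_table(sprintf("g%02d", 1:40), planted_up = c("g01", "g02"),
                 planted_down = "g03", timepoint = "day1", seed = 1),
    sim_de_table(sprintf("g%02d", 1:40), planted_up = "g04",
                 planted_down = "g03", timepoint = "day2", seed = 2)
  )
  sets <- de_sets(de)
  expect_setequal(sets$locus_tag[sets$direction == "up"],
                  c("g01", "g02", "g04"))
  expect_setequal(sets$locus_tag[sets$direction == "down"], "g03")
  expect_equal(sets$timepoints[sets$locus_tag == "g03"], "day1,day2")
  both <- intersect(sets$locus_tag[sets$direction == "up"],
                    sets$locus_tag[sets$direction == "down"])
  expect_length(both, 0)
})

test_that("missing padj records are skipped with a warning", {
  de <- tibble::tibble(locus_tag = c("a", "b"), contrast = "p1",
                       timepoint = "day1", log2FC = c(3, 3),
                       padj = c(NA, 1e-5))
  expect_warning(sets <- de_sets(de), "missing padj")
  expect_setequal(sets$locus_tag, "b")
})

test_that("planted DE tables round-trip through classification exactly", {
  genes <- sprintf("g%03d", 1:300)
  up <- sample(genes, 25)
  down <- sample(setdiff(genes, up), 20)
  de <- sim_de_table(genes, planted_up = up, planted_down = down, seed = 5)
  sets <- de_sets(de)
  expect_setequal(sets$locus_tag[sets$direction == "up"], up)
  expect_setequal(sets$locus_tag[sets$direction == "down"], down)
  null_de <- sim_de_table(genes, seed = 6)
  expect_equal(nrow(de_sets(null_de)), 0L)
})

test_that("pairwise/community comparison reproduces the printed arithmetic", {
  # up: conserved 416 + pairwise-specific 549 (|U| = 965), community-specific
  # 49 (|community| = 465); the identities |U| = conserved + specific and
  # |community| = conserved + community-specific hold by construction
  U <- sprintf("u%03d", 1:965)
  community <- c(U[1:416], sprintf("c%03d", 1:49))
  cmp <- compare_de_sets(list(p1 = U), community)
  expect_length(cmp$conserved, 416)
  expect_length(cmp$pairwise_specific, 549)
  expect_length(cmp$community_specific, 49)
  expect_length(community, 465)
  # down: conserved 448 + pairwise-specific 527, community-specific 28
  D <- sprintf("d%03d", 1:975)
  communityd <- c(D[1:448], sprintf("e%03d", 1:28))
  cmpd <- compare_de_sets(list(p1 = D), communityd)
  expect_length(cmpd$pairwise_specific, 527)
  expect_length(cmpd$community_specific, 28)
  expect_length(communityd, 476)
  # identical sets leave nothing specific
  cmp0 <- compare_de_sets(list(p1 = U), U)
  expect_length(cmp0$pairwise_specific, 0)
  expect_length(cmp0$community_specific, 0)
})

test_that("set identities hold for random DE instances", {
  set.seed(80)
  for (i in 1:50) {
    sets <- random_sets(n_sets = 4, p = 0.35)
    cmp <- compare_de_sets(sets[1:3], sets[[4]])
    expect_equal(length(cmp$conserved) + length(cmp$pairwise_specific),
                 length(cmp$pairwise_union))
    expect_equal(length(cmp$conserved) + length(cmp$community_specific),
                 length(unique(sets[[4]])))
  }
})

test_that("amplified genes require both thresholds in the extra contrast", {
  conserved <- c("a", "b", "c")
  contrast <- tibble::tibble(
    locus_tag = c("a", "b", "d"),
    log2FC = c(1.5, 0.4, 3),
    padj = c(0.001, 0.001, 0.001)
  )
  expect_setequal(amplified_genes(conserved, contrast), "a")
  # gene c missing from the table is excluded, d is not conserved
})

test_that("the full DE pipeline recovers a planted fixture", {
  genes <- sprintf("g%03d", 1:400)
  conserved_up <- genes[1:40]
  pairwise_only_up <- genes[41:70]
  community_only_up <- genes[71:80]
  amplified <- conserved_up[1:10]
  de <- dplyr::bind_rows(
    sim_de_table(genes, planted_up = c(conserved_up, pairwise_only_up),
                 contrast = "p1", seed = 7),
    sim_de_table(genes, planted_up = conserved_up[1:20],
                 contrast = "p2", seed = 8),
    sim_de_table(genes, planted_up = c(conserved_up, community_only_up),
                 contrast = "community", seed = 9)
  )
  amp_de <- sim_de_table(genes, planted_up = amplified, seed = 10)[
    , c("locus_tag", "log2FC", "padj")]
  cls <- classify_de(de, pairwise = c("p1", "p2"), community = "community",
                     amplification_de = amp_de)
  expect_setequal(cls$up$conserved, conserved_up)
  expect_setequal(cls$up$pairwise_specific, pairwise_only_up)
  expect_setequal(cls$up$community_specific, community_only_up)
  expect_setequal(cls$amplified_up, amplified)
})

test_that("hypergeometric p-values match an exact summation oracle", {
  exact_upper <- function(k, K, M, n) {
    if (k == 0) return(1)
    i <- k:min(n, K)
    sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
  }
  # hand cases
  expect_equal(exact_upper(10, 20, 100, 10), choose(20, 10) / choose(100, 10))
  cats <- tibble::tibble(
    locus_tag = sprintf("g%03d", 1:100),
    category = rep(c("hit", "rest"), c(20, 80))
  )
  universe <- sprintf("g%03d", 1:100)
  res_full <- hypergeometric_enrichment(sprintf("g%03d", 1:10), universe,
                                        cats)
  p_full <- res_full$p[res_full$category == "hit"]
  expect_equal(p_full, exact_upper(10, 20, 100, 10), tolerance = 1e-10)
  expect_lt(p_full, 1.1e-8)
  expect_true(res_full$enriched[res_full$category == "hit"])
  # overlap at expectation is not enriched
  query2 <- c(sprintf("g%03d", 1:2), sprintf("g%03d", 21:28))
  res2 <- hypergeometric_enrichment(query2, universe, cats)
  p2 <- res2$p[res2$category == "hit"]
  expect_equal(p2, exact_upper(2, 20, 100, 10), tolerance = 1e-10)
  expect_gt(p2, 0.5)
  expect_false(res2$enriched[res2$category == "hit"])
  # zero overlap has p = 1 by the upper-tail convention
  res3 <- hypergeometric_enrichment(sprintf("g%03d", 21:30), universe, cats)
  expect_equal(res3$p[res3$category == "hit"], 1)
})

test_that("hypergeometric enrichment matches the oracle on random cases", {
  exact_upper <- function(k, K, M, n) {
    if (k == 0) return(1)
    i <- k:min(n, K)
    sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
  }
  set.seed(81)
  for (i in 1:40) {
    M <- sample(30:200, 1)
    universe <- sprintf("u%03d", seq_len(M))
    K <- sample(5:(M - 5), 1)
    cats <- tibble::tibble(locus_tag = universe,
                           category = rep(c("k", "o"), c(K, M - K)))
    n <- sample(3:(M - 3), 1)
    query <- sample(universe, n)
    res <- hypergeometric_enrichment(query, universe, cats)
    k <- sum(query %in% universe[1:K])
    expect_equal(res$p[res$category == "k"], exact_upper(k, K, M, n),
                 tolerance = 1e-10)
  }
})

test_that("enrichment validates its inputs", {
  cats <- tibble::tibble(locus_tag = "a", category = "x")
  expect_error(hypergeometric_enrichment(character(0), "a", cats), "empty")
  expect_error(hypergeometric_enrichment("z", "a", cats), "universe")
})
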