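test_that("significance keeps |t| >= 3 (inclusive) with negative fitness", {
  f <- tibble::tibble(
    locus_tag = c("a", "b", "c", "d", "e"),
    condition = "alone", timepoint = "day1",
    fitness = c(-1.2, -0.5, 0.8, -0.4, -1.0),
    t = c(-4.0, -2.9, 4.2, -3.0, 3.5)
  )
  sig <- significant_sets(f, t_threshold = 3)
  # d is at the boundary (|t| = 3, inclusive); e has |t|>3 but via positive t
  # and negative fitness, which still passes both rules
  expect_setequal(sig$locus_tag, c("a", "d", "e"))
})

test_that("timepoint pooling is a union with provenance", {
  f <- tibble::tibble(
    locus_tag = c("a", "b", "b", "c"),
    condition = "alone",
    timepoint = c("day1", "day1", "day2", "day2"),
    fitness = -1, t = -5
  )
  sig <- significant_sets(f)
  expect_setequal(sig$locus_tag, c("a", "b", "c"))
  expect_equal(sig$timepoints[sig$locus_tag == "b"], "day1,day2")
  # pooling is monotone: adding a timepoint never shrinks the set
  f2 <- f[f$timepoint == "day1", ]
  expect_true(all(significant_sets(f2)$locus_tag %in% sig$locus_tag))
})

test_that("community comparison reproduces the printed arithmetic", {
  # construct sets with |A| = 160, |C| = 126, |A & C| = 89
  A <- sprintf("g%03d", 1:160)
  C <- c(sprintf("g%03d", 1:89), sprintf("h%03d", 1:37))
  cls <- classify_vs_alone(A, list(community = C))
  expect_length(cls$conserved, 89)
  expect_length(cls$induced, 37)
  expect_length(cls$alleviated, 71)
})

test_that("set identities hold against a brute-force oracle", {
  set.seed(77)
  for (i in 1:100) {
    sets <- random_sets(n_sets = 4)
    A <- sets[[1]]
    ctx <- sets[2:4]
    for (rule in c("all", "any")) {
      cls <- classify_vs_alone(A, ctx, rule = rule)
      # brute force per gene
      all_genes <- unique(c(A, unlist(ctx)))
      for (gset in list(cls$conserved, cls$induced, cls$alleviated)) {
        expect_true(all(gset %in% all_genes))
      }
      in_ctx <- vapply(all_genes, function(g) {
        hits <- vapply(ctx, function(s) g %in% s, logical(1))
        if (rule == "all") all(hits) else any(hits)
      }, logical(1))
      bf_conserved <- all_genes[all_genes %in% A & in_ctx]
      bf_alleviated <- all_genes[all_genes %in% A & !in_ctx]
      bf_induced <- all_genes[!(all_genes %in% A) &
                                vapply(all_genes, function(g)
                                  any(vapply(ctx, function(s) g %in% s,
                                             logical(1))), logical(1))]
      expect_setequal(cls$conserved, bf_conserved)
      expect_setequal(cls$alleviated, bf_alleviated)
      expect_setequal(cls$induced, bf_induced)
      expect_equal(length(cls$conserved) + length(cls$alleviated), length(A))
    }
  }
})

test_that("disjoint contexts make everything alleviated or induced", {
  A <- c("a", "b")
  ctx <- list(p = c("x", "y"), q = "z")
  cls <- classify_vs_alone(A, ctx)
  expect_length(cls$conserved, 0)
  expect_setequal(cls$alleviated, A)
  expect_setequal(cls$induced, c("x", "y", "z"))
})

test_that("partner breakdown counts sum to the family size", {
  set.seed(78)
  for (i in 1:25) {
    sets <- random_sets(n_sets = 4, p = 0.4)
    A <- sets[[1]]
    partners <- setNames(sets[2:4], c("p1", "p2", "p3"))
    for (family in c("induced", "alleviated")) {
      bd <- partner_breakdown(family, A, partners)
      fam <- classify_vs_alone(A, partners, rule = "all")[[family]]
      expect_equal(nrow(bd), length(fam))
      expect_true(all(bd$pattern %in%
                        c("all", paste0("specific:", names(partners)),
                          "other")))
    }
  }
})

test_that("partner-specific patterns are identified", {
  A <- c("a", "b", "c")
  partners <- list(p1 = c("b", "c"), p2 = c("a", "c"), p3 = c("a", "b"))
  bd <- partner_breakdown("alleviated", A, partners)
  expect_equal(bd$pattern[bd$locus_tag == "a"], "specific:p1")
  bd2 <- partner_breakdown("alleviated", c("z"), partners)
  expect_equal(bd2$pattern, "all")
})

test_that("cross-classification reproduces the printed arithmetic", {
  # induced: |P| = 75, |C| = 37, overlap 29
  P <- c(sprintf("i%02d", 1:29), sprintf("p%02d", 1:46))
  C <- c(sprintf("i%02d", 1:29), sprintf("c%02d", 1:8))
  cc <- cross_classify(P, C)
  expect_length(cc$conserved_interaction, 29)
  expect_length(cc$pairwise_specific, 46)
  expect_length(cc$community_specific, 8)
  # alleviated: 82 / 71 with overlap 68
  P2 <- c(sprintf("i%02d", 1:68), sprintf("p%02d", 1:14))
  C2 <- c(sprintf("i%02d", 1:68), sprintf("c%02d", 1:3))
  cc2 <- cross_classify(P2, C2)
  expect_length(cc2$pairwise_specific, 14)
  expect_length(cc2$community_specific, 3)
  # degenerate: identical families
  cc3 <- cross_classify(P, P)
  expect_length(cc3$pairwise_specific, 0)
  expect_length(cc3$community_specific, 0)
})

test_that("the core set is the intersection of all condition sets", {
  sets <- list(a = c("x", "y", "z"), b = c("x", "z"), c = c("z", "x", "w"))
  expect_setequal(core_set(sets), c("x", "z"))
  expect_setequal(core_set(list(a = c("x"), b = c("x"))), "x")
  expect_error(core_set(list(a = "x")), "at least 2")
  set.seed(79)
  rs <- random_sets(n_sets = 5)
  expect_setequal(core_set(rs), Reduce(intersect, rs))
})

test_that("the higher-order decomposition recovers the printed percentages", {
  ho <- higher_order_summary(
    list(conserved_interaction = 29, pairwise_specific = 46,
         community_specific = 8),
    list(conserved_interaction = 68, pairwise_specific = 14,
         community_specific = 3)
  )
  expect_equal(ho$pairwise_derived, 97)
  expect_equal(ho$higher_order, 71)
  expect_equal(ho$fraction_pairwise_pct, 58)
  expect_equal(ho$fraction_higher_pct, 42)
})

test_that("degenerate higher-order summaries are explicit", {
  empty_specific <- list(conserved_interaction = c("a"),
                         pairwise_specific = character(0),
                         community_specific = character(0))
  ho <- higher_order_summary(empty_specific, empty_specific)
  expect_equal(ho$fraction_pairwise_pct, 100)
  expect_equal(ho$fraction_higher_pct, 0)
  none <- list(conserved_interaction = character(0),
               pairwise_specific = character(0),
               community_specific = character(0))
  ho0 <- higher_order_summary(none, none)
  expect_true(is.na(ho0$fraction_pairwise_pct))
})
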