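test_that("CFU arithmetic and validation behave", {
  res <- cfu_per_ml(100, 1e-3, 100)
  expect_equal(res$cfu_per_ml, 1e6)
  expect_false(res$below_detection)
  zero <- cfu_per_ml(0, 1e-2, 50)
  expect_equal(zero$cfu_per_ml, 0)
  expect_true(zero$below_detection)
  expect_error(cfu_per_ml(-1, 1e-3, 100), "colonies")
  expect_error(cfu_per_ml(10, 0, 100), "dilution")
  expect_error(cfu_per_ml(10, 1e-3, 0), "volume")
})

test_that("competition fitness is the log2 fraction ratio", {
  expect_equal(competition_fitness(0.5, 0.5), 0)
  expect_equal(competition_fitness(0.5, 0.125), -2)
  expect_equal(competition_fitness(0.25, 0.5), 1)
  expect_equal(competition_fitness(0.5, 0), -Inf)
  expect_error(competition_fitness(0, 0.5), "p0")
})

test_that("swapping mutant and reference negates the fitness", {
  set.seed(82)
  p0 <- runif(50, 0.05, 0.95)
  p1 <- runif(50, 0.05, 0.95)
  expect_equal(competition_fitness(p0, p1),
               -competition_fitness(p1, p0))
})

test_that("z-scores match hand arithmetic and the significance rule", {
  res <- z_confidence(c(-1.0, -1.2, -0.8))
  expect_equal(res$mean, -1)
  expect_equal(res$sd, 0.2)
  expect_equal(res$z, -1 / (0.2 / sqrt(3)))
  expect_equal(round(res$z, 2), -8.66)
  expect_true(res$significant)

  res2 <- z_confidence(c(0.1, -0.1))
  expect_equal(res2$mean, 0)
  expect_equal(res2$z, 0)
  expect_false(res2$significant)

  res3 <- z_confidence(c(-0.5, 0.6, -0.4))
  expect_lt(abs(res3$z), 1.645)
  expect_false(res3$significant)
})

test_that("degenerate replicate sets are handled explicitly", {
  one <- z_confidence(-2)
  expect_true(is.na(one$z))
  expect_false(one$significant)
  tied <- z_confidence(c(-0.8, -0.8, -0.8))
  expect_identical(tied$z, -Inf)
  expect_true(tied$significant)
})

test_that("the Student-t option holds the one-sided 5% level at R = 3", {
  set.seed(83)
  n_sim <- 4000
  fp_t <- mean(replicate(n_sim, {
    z_confidence(rnorm(3, 0, 0.3), test = "t")$significant
  }))
  expect_lte(fp_t, 0.07)
})

test_that("plate-count scoring is scale invariant and pairs plates", {
  plates <- tidyr::expand_grid(
    mutant = "dx", replicate = 1:3, timepoint = c("T0", "day1"),
    selective = c(TRUE, FALSE)
  )
  plates$dilution <- 1e-3
  plates$volume_ul <- 100
  # mutant fraction 0.5 at T0, 0.125 at day1 -> fitness -2 in every replicate
  plates$colonies <- ifelse(plates$timepoint == "T0",
                            ifelse(plates$selective, 100, 200),
                            ifelse(plates$selective, 50, 400))
  res <- run_competition(plates)
  expect_equal(res$mean, -2)
  expect_identical(res$z, -Inf)
  expect_true(res$significant)
  scaled <- plates
  scaled$colonies <- plates$colonies * 13
  expect_equal(run_competition(scaled)$mean, res$mean)
})

test_that("incomplete plate pairings are rejected", {
  plates <- tibble::tibble(
    mutant = "dx", replicate = 1L, timepoint = "T0",
    colonies = 10, dilution = 1e-2, volume_ul = 100, selective = TRUE
  )
  expect_error(run_competition(plates), "positive")
})
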