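#' CFU concentration from a plate count
#'
#' `CFU/mL = colonies / (dilution * volume_uL / 1000)`.
#'
#' @param colonies Colony count (>= 0).
#' @param dilution Dilution factor in (0, 1] (e.g. `1e-3`).
#' @param volume_ul Plated volume in microlitres (> 0).
#' @return Tibble: `cfu_per_ml`, `below_detection` (`TRUE` when zero
#'   colonies were observed).
#' @examples
#' cfu_per_ml(100, 1e-3, 100)  # 1e6 CFU/mL
#' @export
cfu_per_ml <- function(colonies, dilution, volume_ul) {
  if (any(colonies < 0)) abort("`colonies` must be >= 0.")
  if (any(dilution <= 0 | dilution > 1)) {
    abort("`dilution` must be in (0, 1].")
  }
  if (any(volume_ul <= 0)) abort("`volume_ul` must be > 0.")
  tibble(
    cfu_per_ml = colonies / (dilution * volume_ul / 1000),
    below_detection = colonies == 0
  )
}

#' Competitive fitness from mutant fractions
#'
#' `f = log2(p1 / p0)`, the log2 change of the mutant's share of the
#' population (mutant CFU / total CFU) between T0 and the endpoint. A zero
#' endpoint fraction yields `-Inf` (below detection); a zero T0 fraction is
#' an input error.
#'
#' @param p0 Mutant fraction at T0, in (0, 1].
#' @param p1 Mutant fraction at the endpoint, in \[0, 1\].
#' @return Numeric vector of fitness values (log2 units; `-Inf` flags a
#'   below-detection endpoint).
#' @examples
#' competition_fitness(0.5, 0.125)  # -2
#' @export
competition_fitness <- function(p0, p1) {
  if (any(p0 <= 0 | p0 > 1)) abort("`p0` must be in (0, 1].")
  if (any(p1 < 0 | p1 > 1)) abort("`p1` must be in [0, 1].")
  log2(p1 / p0)
}

#' Confidence z-score for replicate competition fitness
#'
#' `z = mean(f) / (sd(f) / sqrt(R))` with the sample standard deviation;
#' the mutant is called significantly less fit than wild type when the
#' fitness is below 0 with at least 95% one-sided confidence
#' (`z <= -1.645`, or the Student-t critical value at `R - 1` df when
#' `test = "t"`). With a single replicate z is undefined and the call is not
#' significant; with zero spread and nonzero mean z is `+/-Inf` and the call
#' follows the sign.
#'
#' @param f Numeric vector of replicate fitness values.
#' @param test `"z"` (default, normal critical value 1.645) or `"t"`.
#' @return One-row tibble: `mean`, `sd`, `z`, `n`, `significant`.
#' @examples
#' z_confidence(c(-1.0, -1.2, -0.8))
#' @export
z_confidence <- function(f, test = c("z", "t")) {
  test <- match.arg(test)
  f <- f[is.finite(f)]
  R <- length(f)
  if (R < 1) {
    return(tibble(mean = NA_real_, sd = NA_real_, z = NA_real_, n = 0L,
                  significant = FALSE))
  }
  m <- mean(f)
  if (R == 1) {
    return(tibble(mean = m, sd = NA_real_, z = NA_real_, n = 1L,
                  significant = FALSE))
  }
  s <- sd(f)
  z <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(R))
  }
  crit <- if (test == "z") qnorm(0.95) else qt(0.95, df = R - 1)
  tibble(mean = m, sd = s, z = z, n = as.integer(R),
         significant = z <= -crit)
}

#' Score knockout-versus-wild-type competition assays from plate counts
#'
#' For each mutant and replicate, computes the mutant fraction at T0 and at
#' the endpoint from paired selective (mutant-only) and non-selective
#' (total) plate counts, converts them to per-replicate fitness
#' `log2(p1 / p0)`, and summarises replicates with [z_confidence()].
#'
#' @param plates Tibble of plate counts: `mutant`, `replicate`, `timepoint`
#'   (`"T0"` or an endpoint label), `colonies`, `dilution`, `volume_ul`,
#'   `selective` (`TRUE` = mutant-selective plate, `FALSE` = total).
#' @param test Passed to [z_confidence()].
#' @return A `competition_result` tibble, one row per mutant: `mutant`,
#'   `mean`, `sd`, `z`, `n`, `significant`, plus a `replicates` list-column
#'   of per-replicate fitness.
#' @export
run_competition <- function(plates, test = c("z", "t")) {
  test <- match.arg(test)
  assert_columns(plates, c("mutant", "replicate", "timepoint", "colonies",
                           "dilution", "volume_ul", "selective"), "plates")
  cfu <- cfu_per_ml(plates$colonies, plates$dilution, plates$volume_ul)
  plates$cfu <- cfu$cfu_per_ml

  fractions <- plates |>
    group_by(.data$mutant, .data$replicate, .data$timepoint) |>
    summarise(
      mutant_cfu = sum(.data$cfu[.data$selective]),
      total_cfu = sum(.data$cfu[!.data$selective]),
      .groups = "drop"
    )
  if (any(fractions$total_cfu <= 0)) {
    abort("total (non-selective) CFU must be positive for every sample.")
  }
  fractions$p <- fractions$mutant_cfu / fractions$total_cfu

  wide <- fractions |>
    mutate(when = ifelse(.data$timepoint == "T0", "p0", "p1")) |>
    select("mutant", "replicate", "when", "p") |>
    tidyr::pivot_wider(names_from = "when", values_from = "p")
  if (anyNA(wide$p0) || anyNA(wide$p1)) {
    abort("each mutant x replicate needs both a T0 and an endpoint sample.")
  }
  wide$fitness <- competition_fitness(wide$p0, wide$p1)

  out <- wide |>
    group_by(mutant = .data$mutant) |>
    summarise(replicates = list(.data$fitness), .groups = "drop")
  stats <- bind_rows(lapply(out$replicates, z_confidence, test = test))
  res <- bind_cols(out["mutant"], stats, out["replicates"])
  class(res) <- c("competition_result", class(res))
  res
}

#' @importFrom stats qnorm
NULL
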