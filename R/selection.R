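#' Ordinary least-squares slope of a frequency trajectory
#'
#' Slope of haplotype frequency on calendar year (frequency change per year).
#' Years with undefined frequencies (`NA`) are dropped pairwise, never
#' interpolated.
#'
#' @param years Calendar years.
#' @param freqs Frequencies, same length as `years`.
#' @return The OLS slope.
#' @export
#' @examples
#' slope_statistic(c(1, 2, 3), c(0.1, 0.2, 0.3)) # 0.1
slope_statistic <- function(years, freqs) {
  keep <- !is.na(freqs) & !is.na(years)
  years <- years[keep]
  freqs <- freqs[keep]
  if (length(years) < 2) abort("Need at least 2 defined (year, frequency) points.")
  yc <- years - mean(years)
  sum(yc * freqs) / sum(yc^2)
}

#' Cumulative absolute year-to-year frequency change
#'
#' The sum of absolute differences in frequency between consecutive years.
#' Pairs in which either year's frequency is undefined are dropped.
#'
#' @param freqs Frequencies ordered by year.
#' @return Non-negative cumulative change.
#' @export
#' @examples
#' cumulative_change_statistic(c(0.1, 0.3, 0.2)) # 0.3
cumulative_change_statistic <- function(freqs) {
  if (length(freqs) < 2) abort("Need at least 2 consecutive frequencies.")
  d <- abs(diff(freqs))
  d <- d[!is.na(d)]
  if (length(d) == 0) abort("No consecutive pair of defined frequencies.")
  sum(d)
}

#' Empirical tail probabilities against a simulated null
#'
#' Default estimator: `p_upper = #{null >= observed} / n`,
#' `p_lower = #{null <= observed} / n`; ties count in both tails, so
#' `p_lower + p_upper = 1 + ties/n` exactly. The `"bias_corrected"` variant
#' uses `(k + 1) / (n + 1)`, which never returns an exact zero. An exact zero
#' under the default estimator only means "more extreme than every null
#' value"; [format_empirical_p()] renders it as `< 1/n`.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Simulated null statistics.
#' @param method `"raw"` (default) or `"bias_corrected"`.
#' @return Named numeric vector `c(p_lower, p_upper)`.
#' @export
#' @examples
#' empirical_tail_probabilities(1.5, c(1, 2, 3, 4))
empirical_tail_probabilities <- function(observed, null_values,
                                         method = c("raw", "bias_corrected")) {
  method <- match.arg(method)
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  if (n == 0) abort("Empty null distribution.")
  k_up <- sum(null_values >= observed)
  k_lo <- sum(null_values <= observed)
  if (method == "raw") {
    c(p_lower = k_lo / n, p_upper = k_up / n)
  } else {
    c(p_lower = (k_lo + 1) / (n + 1), p_upper = (k_up + 1) / (n + 1))
  }
}

selection_labels <- c("directional_positive", "directional_negative",
                      "fluctuating", "balancing")

#' Classify a haplotype's trajectory against the gene-drop null
#'
#' Applies the per-tail 2.5% rules: an observed slope in the upper (lower)
#' tail of the simulated slopes indicates positive (negative) directional
#' selection; an observed cumulative change in the upper tail indicates
#' fluctuating selection, and in the lower tail selection maintaining the
#' haplotype near an equilibrium frequency (balancing). Several labels can
#' co-occur and are all reported, joined by `"+"`; with no tail at or below
#' `alpha_per_tail` the haplotype is `consistent_with_drift`.
#'
#' @param p_slope_lower,p_slope_upper Tail probabilities of the slope.
#' @param p_cum_lower,p_cum_upper Tail probabilities of the cumulative change.
#' @param alpha_per_tail Per-tail significance level (default 0.025). The tail
#'   rule is closed (`<= alpha`).
#' @return Character vector of classifications.
#' @export
classify_haplotype <- function(p_slope_lower, p_slope_upper,
                               p_cum_lower, p_cum_upper,
                               alpha_per_tail = 0.025) {
  n <- max(lengths(list(p_slope_lower, p_slope_upper, p_cum_lower, p_cum_upper)))
  p <- cbind(
    directional_positive = rep_len(p_slope_upper, n),
    directional_negative = rep_len(p_slope_lower, n),
    fluctuating = rep_len(p_cum_upper, n),
    balancing = rep_len(p_cum_lower, n)
  )
  apply(p, 1, function(row) {
    hit <- selection_labels[which(row <= alpha_per_tail)]
    if (length(hit) == 0) "consistent_with_drift" else paste(hit, collapse = "+")
  })
}

#' Gene-drop neutrality test for every haplotype
#'
#' Runs the gene-drop ([run_genedrop()]), then compares the observed slope and
#' cumulative change of each haplotype's standing-population frequency
#' trajectory over `cfg$simulated_years` with their simulated null
#' distributions, and classifies each haplotype.
#'
#' @inheritParams run_genedrop
#' @param alpha_per_tail Per-tail significance level (default 0.025).
#' @param tail_method `"raw"` (tail count / n) or `"bias_corrected"`
#'   (`(k+1)/(n+1)`).
#' @param drop A precomputed `genedrop` object, to re-test without re-running
#'   the simulation; overrides `ped`/`diplotypes`/`cfg`.
#' @return A `genedrop_test` object; see [tidy.genedrop_test()].
#' @export
genedrop_test <- function(ped, diplotypes, cfg = genedrop_config(),
                          haplotypes = NULL, alpha_per_tail = 0.025,
                          tail_method = c("raw", "bias_corrected"),
                          drop = NULL) {
  tail_method <- match.arg(tail_method)
  if (is.null(drop)) {
    drop <- run_genedrop(ped, diplotypes, cfg, haplotypes)
  }
  cfg <- drop$config
  test_years <- seq(cfg$simulated_years[1], cfg$simulated_years[2])
  yi <- match(test_years, drop$years)
  K <- length(drop$haplotypes)
  n_sim <- cfg$n_sim

  obs_wide <- tidyr::pivot_wider(drop$observed, names_from = "haplotype",
                                 values_from = "freq", id_cols = "year")
  obs_mat <- as.matrix(obs_wide[match(test_years, obs_wide$year), drop$haplotypes])

  null_slope <- matrix(NA_real_, n_sim, K, dimnames = list(NULL, drop$haplotypes))
  null_cum <- matrix(NA_real_, n_sim, K, dimnames = list(NULL, drop$haplotypes))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    f_obs <- obs_mat[, k]
    obs_slope <- slope_statistic(test_years, f_obs)
    obs_cum <- cumulative_change_statistic(f_obs)
    sim_f <- drop$sim_freq[yi, k, , drop = TRUE] # years x replicates
    if (is.null(dim(sim_f))) sim_f <- matrix(sim_f, ncol = n_sim)
    defined <- !is.na(sim_f[, 1])
    yc <- test_years[defined] - mean(test_years[defined])
    sf <- sim_f[defined, , drop = FALSE]
    null_slope[, k] <- colSums(sf * yc) / sum(yc^2)
    null_cum[, k] <- colSums(abs(sf[-1, , drop = FALSE] - sf[-nrow(sf), , drop = FALSE]))
    ps <- empirical_tail_probabilities(obs_slope, null_slope[, k], tail_method)
    pc <- empirical_tail_probabilities(obs_cum, null_cum[, k], tail_method)
    rows[[k]] <- tibble::tibble(
      haplotype = drop$haplotypes[k],
      obs_slope = obs_slope, obs_cum = obs_cum,
      p_slope_lower = ps[["p_lower"]], p_slope_upper = ps[["p_upper"]],
      p_cum_lower = pc[["p_lower"]], p_cum_upper = pc[["p_upper"]]
    )
  }
  res <- dplyr::bind_rows(rows)
  res$classification <- classify_haplotype(
    res$p_slope_lower, res$p_slope_upper, res$p_cum_lower, res$p_cum_upper,
    alpha_per_tail
  )
  structure(
    list(
      result = res,
      null_slope = null_slope,
      null_cum = null_cum,
      drop = drop,
      alpha_per_tail = alpha_per_tail,
      tail_method = tail_method
    ),
    class = "genedrop_test"
  )
}

#' @export
print.genedrop_test <- function(x, ...) {
  cat(sprintf("# Gene-drop neutrality test (%d replicates, alpha %.3g per tail, %s tails)\n",
              x$drop$config$n_sim, x$alpha_per_tail, x$tail_method))
  out <- x$result
  out$p_slope_upper <- format_empirical_p(out$p_slope_upper, x$drop$config$n_sim)
  out$p_cum_lower <- format_empirical_p(out$p_cum_lower, x$drop$config$n_sim)
  print(out, ...)
  invisible(x)
}

#' Tidy the per-haplotype gene-drop test table
#'
#' @param x A `genedrop_test` object.
#' @param ... Unused.
#' @return Tibble with one row per haplotype: observed slope and cumulative
#'   change, the four empirical tail probabilities, and the classification.
#' @export
tidy.genedrop_test <- function(x, ...) {
  x$result
}

#' One-line summary of a gene-drop test
#'
#' @param x A `genedrop_test` object.
#' @param ... Unused.
#' @return One-row tibble: replicate count, years tested, haplotype count and
#'   how many haplotypes were flagged as inconsistent with drift.
#' @export
glance.genedrop_test <- function(x, ...) {
  cfg <- x$drop$config
  tibble::tibble(
    n_sim = cfg$n_sim,
    first_year = cfg$simulated_years[1],
    last_year = cfg$simulated_years[2],
    n_haplotypes = nrow(x$result),
    n_flagged = sum(x$result$classification != "consistent_with_drift"),
    alpha_per_tail = x$alpha_per_tail,
    tail_method = x$tail_method
  )
}

#' Write the gene-drop test table as TSV
#'
#' @param x A `genedrop_test` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genedrop_test <- function(x, path) {
  readr::write_tsv(tidy(x), path, na = "NA", progress = FALSE)
  invisible(path)
}
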