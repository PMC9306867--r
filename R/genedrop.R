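#' Gene-drop configuration
#'
#' Settings for the gene-drop simulation: which birth cohorts seed the drop
#' with their observed diplotypes (`founder_years`), which cohorts are
#' simulated (`simulated_years`), the number of Monte Carlo replicates, the
#' random seed, and which individuals standing-population frequencies are
#' computed over.
#'
#' `frequency_individuals = "genotyped_only"` (default) computes simulated
#' frequencies over the same individuals as the observed frequencies (those
#' with an observed diplotype), so observed and null trajectories share the
#' same population composition; `"all"` uses every individual alive in a year
#' (every individual carries a simulated diplotype).
#'
#' @param founder_years Inclusive year range of the founder cohorts.
#' @param simulated_years Inclusive year range of the simulated cohorts; must
#'   start after `founder_years` ends.
#' @param n_sim Number of gene-drop replicates.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param frequency_individuals `"genotyped_only"` or `"all"`.
#' @return A `genedrop_config` list.
#' @export
genedrop_config <- function(founder_years = c(1989, 1992),
                            simulated_years = c(1993, 2012),
                            n_sim = 5000,
                            seed = NULL,
                            frequency_individuals = c("genotyped_only", "all")) {
  founder_years <- assert_year_range(founder_years, "founder_years")
  simulated_years <- assert_year_range(simulated_years, "simulated_years")
  if (founder_years[2] >= simulated_years[1]) {
    abort("`founder_years` must end before `simulated_years` begins.")
  }
  assert_scalar_number(n_sim, "n_sim")
  if (n_sim < 1) abort("`n_sim` must be at least 1.")
  if (!is.null(seed)) assert_scalar_number(seed, "seed")
  structure(
    list(
      founder_years = founder_years,
      simulated_years = simulated_years,
      n_sim = as.integer(n_sim),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      frequency_individuals = match.arg(frequency_individuals)
    ),
    class = "genedrop_config"
  )
}

#' Observed per-birth-cohort haplotype frequencies
#'
#' Haplotype frequencies among genotyped individuals of each birth cohort.
#' These are the sampling distributions used for alleles of unknown parents in
#' the gene-drop, and are held fixed across replicates.
#'
#' @param ped A `pedigree`.
#' @param diplotypes Observed diplotype tibble (`id`, `hap1`, `hap2`).
#' @param haplotypes Optional haplotype labels (character or `haplotype_set`);
#'   defaults to the sorted labels present in `diplotypes`.
#' @return Tibble `year`, `haplotype`, `freq`, `n_individuals`; years with no
#'   genotyped individuals have `freq = NA`.
#' @export
cohort_frequencies <- function(ped, diplotypes, haplotypes = NULL) {
  prep <- prepare_genedrop(ped, diplotypes, haplotypes,
                           genedrop_config(seed = 1), resolve = FALSE)
  years <- sort(unique(ped$birth_year))
  rows <- lapply(years, function(y) {
    f <- raw_cohort_freq(prep, y)
    tibble::tibble(
      year = y, haplotype = prep$labels,
      freq = if (is.null(f$freq)) NA_real_ else f$freq,
      n_individuals = f$n
    )
  })
  dplyr::bind_rows(rows)
}

# ---- internal preparation -------------------------------------------------

hap_labels_of <- function(haplotypes, diplotypes) {
  if (is.null(haplotypes)) {
    sort(unique(c(diplotypes$hap1, diplotypes$hap2)))
  } else if (is.character(haplotypes)) {
    haplotypes
  } else {
    haplotypes$haplotype
  }
}

raw_cohort_freq <- function(prep, year) {
  in_cohort <- which(prep$birth_year == year & !is.na(prep$obs1))
  n <- length(in_cohort)
  if (n == 0) return(list(freq = NULL, n = 0L))
  counts <- tabulate(c(prep$obs1[in_cohort], prep$obs2[in_cohort]), nbins = prep$K)
  list(freq = counts / (2 * n), n = n)
}

# Build index structures for the drop. `resolve = TRUE` also resolves, for
# every birth year, the cohort-frequency vector to use for unknown-parent
# draws (with fallback to the nearest cohort that has genotyped individuals,
# preferring earlier years; pre-founder cohorts fall back to the earliest
# cohort with data).
prepare_genedrop <- function(ped, diplotypes, haplotypes, cfg, resolve = TRUE) {
  labels <- hap_labels_of(haplotypes, diplotypes)
  unknown <- setdiff(unique(c(diplotypes$hap1, diplotypes$hap2)), labels)
  if (length(unknown) > 0) {
    abort(paste0("Diplotype table uses unknown haplotype label(s): ",
                 paste(unknown, collapse = ", ")))
  }
  ord_ids <- topological_order(ped)
  ord <- match(ord_ids, ped$id)
  id <- ped$id[ord]
  birth_year <- ped$birth_year[ord]
  sire <- match(ped$sire[ord], id)
  dam <- match(ped$dam[ord], id)
  di <- match(id, diplotypes$id)
  obs1 <- match(diplotypes$hap1[di], labels)
  obs2 <- match(diplotypes$hap2[di], labels)

  prep <- list(
    id = id, birth_year = birth_year, sire = sire, dam = dam,
    obs1 = obs1, obs2 = obs2, labels = labels, K = length(labels),
    n = length(id), cfg = cfg,
    final_year = effective_final_year(new_pedigree(
      tibble::tibble(id = id, sire = NA, dam = NA, sex = NA,
                     birth_year = birth_year,
                     death_year = ped$death_year[ord],
                     final_year = if ("final_year" %in% names(ped)) ped$final_year[ord] else NA_integer_)
    ))
  )

  if (!resolve) return(prep)

  years <- sort(unique(birth_year))
  with_data <- years[vapply(years, function(y) raw_cohort_freq(prep, y)$n > 0, logical(1))]
  if (length(with_data) == 0) {
    abort("No genotyped individuals in any birth cohort; cannot gene-drop.")
  }
  fallbacks <- character(0)
  freq_by_year <- lapply(years, function(y) {
    f <- raw_cohort_freq(prep, y)
    if (f$n > 0) return(f$freq)
    src <- if (y < cfg$founder_years[1]) {
      min(with_data)
    } else {
      cand <- with_data[order(abs(with_data - y), with_data)]
      cand[1]
    }
    fallbacks <<- c(fallbacks,
                    sprintf("cohort %d has no genotyped individuals; using cohort %d frequencies", y, src))
    raw_cohort_freq(prep, src)$freq
  })
  names(freq_by_year) <- as.character(years)
  prep$freq_by_year <- freq_by_year
  prep$freq_earliest <- raw_cohort_freq(prep, min(with_data))$freq
  prep$fallbacks <- fallbacks
  if (length(fallbacks) > 0) {
    inform(paste0("Cohort-frequency fallbacks applied:\n  ",
                  paste(unique(fallbacks), collapse = "\n  ")))
  }

  # Assignment rule per individual (fixed across replicates):
  #   observed          - pre-founder or founder-cohort individual with an
  #                       observed diplotype, assigned verbatim
  #   mendelian         - at least one allele drawn from an assigned parent
  #   frequency_sampled - both alleles drawn from cohort frequencies
  pre_founder <- birth_year < cfg$founder_years[1]
  founder_win <- birth_year >= cfg$founder_years[1] & birth_year <= cfg$founder_years[2]
  genotyped <- !is.na(obs1)
  source <- character(prep$n)
  source[(pre_founder | founder_win) & genotyped] <- "observed"
  todo <- source == ""
  has_parent <- (!is.na(sire) | !is.na(dam)) & !pre_founder
  source[todo & has_parent] <- "mendelian"
  source[todo & !has_parent] <- "frequency_sampled"
  prep$source <- source
  prep$pre_founder <- pre_founder
  prep
}

# Core vectorised drop: one pass down the pedigree for all replicates at once,
# consuming the current RNG stream. Returns N x n_sim integer matrices of
# haplotype indices.
genedrop_assign <- function(prep, n_sim) {
  n <- prep$n
  K <- prep$K
  H1 <- matrix(NA_integer_, n, n_sim)
  H2 <- matrix(NA_integer_, n, n_sim)
  freq_for <- function(i) {
    if (prep$pre_founder[i]) prep$freq_earliest
    else prep$freq_by_year[[as.character(prep$birth_year[i])]]
  }
  draw_parent <- function(pi) {
    take1 <- runif(n_sim) < 0.5
    ifelse(take1, H1[pi, ], H2[pi, ])
  }
  for (i in seq_len(n)) {
    if (prep$source[i] == "observed") {
      H1[i, ] <- prep$obs1[i]
      H2[i, ] <- prep$obs2[i]
      next
    }
    if (prep$pre_founder[i]) {
      f <- freq_for(i)
      H1[i, ] <- sample.int(K, n_sim, replace = TRUE, prob = f)
      H2[i, ] <- sample.int(K, n_sim, replace = TRUE, prob = f)
      next
    }
    H1[i, ] <- if (!is.na(prep$sire[i])) draw_parent(prep$sire[i]) else
      sample.int(K, n_sim, replace = TRUE, prob = freq_for(i))
    H2[i, ] <- if (!is.na(prep$dam[i])) draw_parent(prep$dam[i]) else
      sample.int(K, n_sim, replace = TRUE, prob = freq_for(i))
  }
  list(H1 = H1, H2 = H2)
}

# Individuals counted in the standing population of each year.
counted_sets <- function(prep, years) {
  genotyped <- !is.na(prep$obs1)
  lapply(years, function(y) {
    alive <- prep$birth_year <= y & y <= prep$final_year
    if (prep$cfg$frequency_individuals == "genotyped_only") {
      which(alive & genotyped)
    } else {
      which(alive)
    }
  })
}

# Frequency array [year x haplotype x replicate] from assignment matrices.
standing_freq_array <- function(prep, H, years) {
  sets <- counted_sets(prep, years)
  n_sim <- ncol(H$H1)
  arr <- array(NA_real_, dim = c(length(years), prep$K, n_sim),
               dimnames = list(years, prep$labels, NULL))
  n_counted <- lengths(sets)
  for (yi in seq_along(years)) {
    A <- sets[[yi]]
    if (length(A) == 0) next
    h1 <- H$H1[A, , drop = FALSE]
    h2 <- H$H2[A, , drop = FALSE]
    for (k in seq_len(prep$K)) {
      arr[yi, k, ] <- (.colSums(h1 == k, length(A), n_sim) +
                         .colSums(h2 == k, length(A), n_sim)) / (2 * length(A))
    }
  }
  list(freq = arr, n = n_counted)
}

#' Observed standing-population haplotype frequencies
#'
#' For each year, counts the two haplotype copies of every genotyped
#' individual alive that year (life interval inclusive on both ends). Years in
#' which no genotyped individual is alive are flagged by `n_individuals = 0`
#' and `freq = NA`, never silently zero.
#'
#' @inheritParams cohort_frequencies
#' @param years Integer vector of calendar years.
#' @return Tibble `year`, `haplotype`, `freq`, `n_individuals`.
#' @export
observed_standing_frequencies <- function(ped, diplotypes, years, haplotypes = NULL) {
  cfg <- genedrop_config(
    founder_years = c(min(years) - 2L, min(years) - 1L),
    simulated_years = range(years), seed = 1
  )
  prep <- prepare_genedrop(ped, diplotypes, haplotypes, cfg, resolve = FALSE)
  prep$cfg$frequency_individuals <- "genotyped_only"
  H <- list(H1 = matrix(prep$obs1, ncol = 1), H2 = matrix(prep$obs2, ncol = 1))
  sf <- standing_freq_array(prep, H, years)
  tibble::tibble(
    year = rep(years, each = prep$K),
    haplotype = rep(prep$labels, length(years)),
    freq = as.vector(t(sf$freq[, , 1])),
    n_individuals = rep(sf$n, each = prep$K)
  )
}

#' Run the gene-drop simulation
#'
#' Simulates the neutral (drift-only) distribution of standing-population
#' haplotype-frequency trajectories, given the fixed pedigree. Individuals in
#' pre-founder and founder cohorts keep their observed diplotypes; founder- or
#' pre-founder-cohort individuals without one receive alleles by Mendelian
#' draw from an assigned parent or by draws from their birth cohort's observed
#' haplotype frequencies; every individual born in `simulated_years` is
#' simulated the same way regardless of any observed diplotype.
#'
#' All replicates are generated from one RNG stream seeded with `cfg$seed`,
#' so an identical configuration reproduces bit-identical output.
#'
#' @param ped A `pedigree`.
#' @param diplotypes Observed diplotype tibble (`id`, `hap1`, `hap2`).
#' @param cfg A [genedrop_config()].
#' @param haplotypes Optional haplotype labels or `haplotype_set`.
#' @param keep_assignments If `TRUE`, also keep the full per-replicate
#'   diplotype assignments (two individuals-by-replicates label matrices,
#'   `hap1` and `hap2`). Memory-hungry for large runs; intended for
#'   verification against enumeration oracles.
#' @return A `genedrop` object: observed trajectory tibble, simulated
#'   frequency array `[year, haplotype, replicate]`, per-year counted-set
#'   sizes, per-individual assignment sources, and the configuration.
#' @export
run_genedrop <- function(ped, diplotypes, cfg = genedrop_config(),
                         haplotypes = NULL, keep_assignments = FALSE) {
  prep <- prepare_genedrop(ped, diplotypes, haplotypes, cfg)
  years <- seq(cfg$founder_years[1], cfg$simulated_years[2])
  assignments <- NULL
  sim <- with_seed(cfg$seed, {
    H <- genedrop_assign(prep, cfg$n_sim)
    if (keep_assignments) {
      assignments <- list(
        hap1 = matrix(prep$labels[H$H1], nrow = prep$n,
                      dimnames = list(prep$id, NULL)),
        hap2 = matrix(prep$labels[H$H2], nrow = prep$n,
                      dimnames = list(prep$id, NULL))
      )
    }
    standing_freq_array(prep, H, years)
  })
  obs <- observed_standing_frequencies(ped, diplotypes, years, prep$labels)
  structure(
    list(
      observed = obs,
      sim_freq = sim$freq,
      years = years,
      haplotypes = prep$labels,
      n_counted = setNames(sim$n, years),
      sources = tibble::tibble(id = prep$id, source = prep$source),
      cohort_fallbacks = prep$fallbacks,
      assignments = assignments,
      config = cfg
    ),
    class = "genedrop"
  )
}

#' Single gene-drop replicate
#'
#' One pass of the gene-drop assignment, returning every individual's
#' simulated diplotype and how it was assigned (`observed`, `mendelian`, or
#' `frequency_sampled`).
#'
#' @inheritParams run_genedrop
#' @param seed Optional seed overriding `cfg$seed` for this single replicate.
#' @return Tibble `id`, `hap1`, `hap2`, `source`.
#' @export
drop_once <- function(ped, diplotypes, cfg = genedrop_config(),
                      haplotypes = NULL, seed = cfg$seed) {
  prep <- prepare_genedrop(ped, diplotypes, haplotypes, cfg)
  H <- with_seed(seed, genedrop_assign(prep, 1L))
  tibble::tibble(
    id = prep$id,
    hap1 = prep$labels[H$H1[, 1]],
    hap2 = prep$labels[H$H2[, 1]],
    source = prep$source
  )
}

#' Exact expected haplotype frequencies under the gene-drop
#'
#' Computes, by linear propagation down the pedigree, the exact expectation of
#' each year's standing-population haplotype frequencies under the gene-drop
#' sampling scheme (Mendelian transmission halves each parent's expected
#' dosage; unknown-parent alleles contribute the cohort frequencies). Useful
#' as an independent oracle for the Monte Carlo engine.
#'
#' @inheritParams run_genedrop
#' @return Tibble `year`, `haplotype`, `expected_freq`.
#' @export
genedrop_expectation <- function(ped, diplotypes, cfg = genedrop_config(),
                                 haplotypes = NULL) {
  prep <- prepare_genedrop(ped, diplotypes, haplotypes, cfg)
  n <- prep$n
  K <- prep$K
  E <- matrix(0, n, K) # expected dosage vector per individual (rows sum to 2)
  freq_for <- function(i) {
    if (prep$pre_founder[i]) prep$freq_earliest
    else prep$freq_by_year[[as.character(prep$birth_year[i])]]
  }
  for (i in seq_len(n)) {
    if (prep$source[i] == "observed") {
      E[i, prep$obs1[i]] <- E[i, prep$obs1[i]] + 1
      E[i, prep$obs2[i]] <- E[i, prep$obs2[i]] + 1
      next
    }
    if (prep$pre_founder[i]) {
      E[i, ] <- 2 * freq_for(i)
      next
    }
    c1 <- if (!is.na(prep$sire[i])) E[prep$sire[i], ] / 2 else freq_for(i)
    c2 <- if (!is.na(prep$dam[i])) E[prep$dam[i], ] / 2 else freq_for(i)
    E[i, ] <- c1 + c2
  }
  years <- seq(cfg$founder_years[1], cfg$simulated_years[2])
  sets <- counted_sets(prep, years)
  rows <- lapply(seq_along(years), function(yi) {
    A <- sets[[yi]]
    ef <- if (length(A) == 0) rep(NA_real_, K) else colMeans(E[A, , drop = FALSE]) / 2
    tibble::tibble(year = years[yi], haplotype = prep$labels, expected_freq = ef)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.genedrop <- function(x, ...) {
  cat(sprintf(
    "# Gene-drop: %d replicates, %d haplotypes, years %d-%d (%s)\n",
    x$config$n_sim, length(x$haplotypes), min(x$years), max(x$years),
    x$config$frequency_individuals
  ))
  invisible(x)
}

#' Tidy a gene-drop result into a long trajectory table
#'
#' @param x A `genedrop` object.
#' @param replicates Which simulated replicates to include (default all);
#'   the observed trajectory is always included with `replicate = "observed"`.
#' @param ... Unused.
#' @return Tibble `replicate`, `year`, `haplotype`, `freq`, `n_individuals`.
#' @export
tidy.genedrop <- function(x, replicates = seq_len(x$config$n_sim), ...) {
  obs <- dplyr::mutate(x$observed, replicate = "observed", .before = 1)
  Y <- length(x$years)
  K <- length(x$haplotypes)
  sims <- lapply(replicates, function(r) {
    tibble::tibble(
      replicate = as.character(r),
      year = rep(x$years, each = K),
      haplotype = rep(x$haplotypes, Y),
      freq = as.vector(t(x$sim_freq[, , r])),
      n_individuals = rep(unname(x$n_counted), each = K)
    )
  })
  dplyr::bind_rows(c(list(obs), sims))
}

#' Write gene-drop trajectories as long-format TSV
#'
#' Columns `replicate` (with `"observed"` for the observed trajectory),
#' `year`, `haplotype`, `freq`, `n_individuals`.
#'
#' @param x A `genedrop` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genedrop <- function(x, path) {
  readr::write_tsv(tidy(x), path, na = "NA", progress = FALSE)
  invisible(path)
}
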