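#' Configuration for the synthetic population generator
#'
#' Defaults emulate a closed, intensively monitored ungulate population with
#' overlapping generations: ~24 birth cohorts, eight segregating MHC
#' haplotypes with the rarest near 3%, polygynous males (annual breeding
#' success ranging up to the twenties) against females capped at three
#' offspring per year, high juvenile mortality, and incomplete genotyping.
#'
#' @param n_founders Number of individuals alive in the first year.
#' @param founder_hap_freqs Named haplotype frequency vector (must sum to 1).
#' @param years Inclusive calendar-year range of the study.
#' @param founder_max_age Maximum age (years) of initial individuals.
#' @param juvenile_survival Baseline probability a newborn survives to age 1.
#' @param adult_survival Annual survival probability of adults below
#'   `max_age`.
#' @param max_age Age at which death is certain.
#' @param litter_probs Probabilities of a breeding female producing 0-3
#'   offspring in a year.
#' @param male_skew Gamma shape of annual male siring weights; smaller values
#'   give stronger polygyny.
#' @param selection_juvenile Named vector of per-copy multiplicative effects
#'   on juvenile survival, e.g. `c(D = 0.5)` multiplies survival by
#'   `(1 + 0.5)^dosage` (clamped to `[0, 1]`).
#' @param selection_male_breeding Named vector of per-copy multiplicative
#'   effects on male siring weight.
#' @param genotyping_missingness Probability an individual's diplotype is
#'   unobserved.
#' @param sequence_length Length of the generated amino-acid alignment.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_founders = 220,
                         founder_hap_freqs = c(A = 0.25, B = 0.20, C = 0.15,
                                               D = 0.03, E = 0.12, F = 0.10,
                                               G = 0.08, H = 0.07),
                         years = c(1989, 2012),
                         founder_max_age = 6,
                         juvenile_survival = 0.50,
                         adult_survival = 0.80,
                         max_age = 12,
                         litter_probs = c(0.25, 0.57, 0.16, 0.02),
                         male_skew = 0.4,
                         selection_juvenile = numeric(0),
                         selection_male_breeding = numeric(0),
                         genotyping_missingness = 0.28,
                         sequence_length = 120,
                         seed = NULL) {
  if (is.null(names(founder_hap_freqs)) || anyDuplicated(names(founder_hap_freqs))) {
    abort("`founder_hap_freqs` must be a uniquely named vector.")
  }
  if (any(founder_hap_freqs < 0 | founder_hap_freqs > 1)) {
    abort("`founder_hap_freqs` entries must be probabilities.")
  }
  if (abs(sum(founder_hap_freqs) - 1) > 1e-9) {
    abort("`founder_hap_freqs` must sum to 1 (within 1e-9).")
  }
  years <- assert_year_range(years, "years")
  if (length(litter_probs) != 4 || any(litter_probs < 0) ||
      abs(sum(litter_probs) - 1) > 1e-9) {
    abort("`litter_probs` must be 4 probabilities (0-3 offspring) summing to 1.")
  }
  for (nm in c("selection_juvenile", "selection_male_breeding")) {
    sel <- get(nm)
    if (length(sel) > 0 &&
        (is.null(names(sel)) || !all(names(sel) %in% names(founder_hap_freqs)))) {
      abort(sprintf("`%s` must be named by haplotype labels.", nm))
    }
  }
  if (genotyping_missingness < 0 || genotyping_missingness > 1) {
    abort("`genotyping_missingness` must be in [0, 1].")
  }
  structure(
    list(
      n_founders = as.integer(n_founders),
      founder_hap_freqs = founder_hap_freqs,
      years = years,
      founder_max_age = as.integer(founder_max_age),
      juvenile_survival = juvenile_survival,
      adult_survival = adult_survival,
      max_age = as.integer(max_age),
      litter_probs = litter_probs,
      male_skew = male_skew,
      selection_juvenile = selection_juvenile,
      selection_male_breeding = selection_male_breeding,
      genotyping_missingness = genotyping_missingness,
      sequence_length = as.integer(sequence_length),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Per-copy multiplicative selection factor for each individual.
selection_factor <- function(sel, hap1, hap2, labels) {
  f <- rep(1, length(hap1))
  for (h in names(sel)) {
    k <- match(h, labels)
    dosage <- (hap1 == k) + (hap2 == k)
    f <- f * (1 + sel[[h]])^dosage
  }
  f
}

# Random but reproducible divergent amino-acid alignment; the named
# `divergent` haplotype is made the most diverged from the rest.
make_haplotype_sequences <- function(labels, len, divergent = "D") {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- sample(aa, len, replace = TRUE)
  mutate_at <- function(rate) {
    s <- base
    pos <- which(runif(len) < rate)
    s[pos] <- sample(aa, length(pos), replace = TRUE)
    paste(s, collapse = "")
  }
  seqs <- vapply(labels, function(h) {
    mutate_at(if (identical(h, divergent)) 0.30 else 0.12)
  }, character(1))
  seqs
}

#' Simulate a pedigreed population with MHC haplotypes and fitness records
#'
#' Forward-in-time individual-based simulation. Initial individuals receive
#' Hardy-Weinberg diplotypes at `founder_hap_freqs` and a stable age
#' structure. Each subsequent year, adult mortality is applied, surviving
#' females aged 1+ produce 0-3 offspring, sires aged 1+ are drawn with
#' gamma-skewed (polygynous) weights, offspring inherit one haplotype from
#' each parent, and juvenile survival is Bernoulli with optional per-copy
#' viability selection. Fitness records follow the standard six definitions
#' (total fitness as lifetime breeding success of all individuals born;
#' juvenile survival; adult annual survival; adult life span; adult annual
#' and lifetime breeding success), with measures censored for individuals
#' still alive in the final year.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_population` list: `pedigree`, `diplotypes` (complete),
#'   `diplotypes_observed` (after genotyping missingness), `haplotypes`
#'   (a `haplotype_set` with generated sequences), `fitness`,
#'   `fitness_annual`, and `truth` (every generating parameter plus realised
#'   founder frequencies).
#' @export
simulate_population <- function(cfg = synth_config()) {
  with_seed(cfg$seed, simulate_population_impl(cfg))
}

simulate_population_impl <- function(cfg) {
  labels <- names(cfg$founder_hap_freqs)
  K <- length(labels)
  y0 <- cfg$years[1]
  y_end <- cfg$years[2]

  # Stable-ish founder age structure from the survivorship curve.
  ages <- 0:cfg$founder_max_age
  w_age <- c(1, cfg$juvenile_survival * cfg$adult_survival^(ages[-1] - 1))
  n0 <- cfg$n_founders
  cap <- max(1000, 50 * n0 * (y_end - y0))
  id <- character(cap); sire <- character(cap); dam <- character(cap)
  sex <- character(cap); birth <- integer(cap); death <- integer(cap)
  h1 <- integer(cap); h2 <- integer(cap)
  n <- 0L
  new_ids <- function(k) sprintf("I%05d", n + seq_len(k))

  add <- function(k, sire_, dam_, sex_, birth_, h1_, h2_) {
    idx <- n + seq_len(k)
    id[idx] <<- new_ids(k)
    sire[idx] <<- sire_; dam[idx] <<- dam_
    sex[idx] <<- sex_; birth[idx] <<- birth_
    death[idx] <<- NA_integer_
    h1[idx] <<- h1_; h2[idx] <<- h2_
    n <<- n + k
    idx
  }

  founder_age <- sample(ages, n0, replace = TRUE, prob = w_age)
  add(n0, NA_character_, NA_character_,
      ifelse(runif(n0) < 0.5, "male", "female"), y0 - founder_age,
      sample.int(K, n0, replace = TRUE, prob = cfg$founder_hap_freqs),
      sample.int(K, n0, replace = TRUE, prob = cfg$founder_hap_freqs))
  alive <- rep(TRUE, n)

  for (y in seq(y0 + 1L, y_end)) {
    live <- which(alive[seq_len(n)])
    if (length(live) == 0) {
      abort("Population went extinct; increase survival or n_founders.")
    }
    # Adult mortality on the transition into year y.
    age_prev <- (y - 1L) - birth[live]
    adults <- live[age_prev >= 1L]
    if (length(adults) > 0) {
      p_surv <- ifelse((y - birth[adults]) > cfg$max_age, 0, cfg$adult_survival)
      dies <- runif(length(adults)) >= p_surv
      if (any(dies)) {
        death[adults[dies]] <- y - 1L
        alive[adults[dies]] <- FALSE
      }
    }
    live <- which(alive[seq_len(n)])
    age_now <- y - birth[live]
    mothers <- live[sex[live] == "female" & age_now >= 1L]
    fathers <- live[sex[live] == "male" & age_now >= 1L]
    if (length(mothers) == 0 || length(fathers) == 0) {
      abort("No breeding adults of one sex left; increase survival or n_founders.")
    }
    n_off_per_mother <- sample(0:3, length(mothers), replace = TRUE,
                               prob = cfg$litter_probs)
    total <- sum(n_off_per_mother)
    if (total == 0) next
    mo <- rep(mothers, n_off_per_mother)
    w_sire <- rgamma(length(fathers), shape = cfg$male_skew, rate = 1) + 1e-9
    w_sire <- w_sire * selection_factor(cfg$selection_male_breeding,
                                        h1[fathers], h2[fathers], labels)
    fa <- fathers[sample.int(length(fathers), total, replace = TRUE,
                             prob = w_sire)]
    a_mat <- ifelse(runif(total) < 0.5, h1[mo], h2[mo])
    a_pat <- ifelse(runif(total) < 0.5, h1[fa], h2[fa])
    kid_sex <- ifelse(runif(total) < 0.5, "male", "female")
    idx <- add(total, id[fa], id[mo], kid_sex, y, a_pat, a_mat)
    p_juv <- pmin(pmax(cfg$juvenile_survival *
                         selection_factor(cfg$selection_juvenile,
                                          a_pat, a_mat, labels), 0), 1)
    survives <- runif(total) < p_juv
    alive[idx] <- survives
    death[idx[!survives]] <- y
  }

  idx_all <- seq_len(n)
  censored <- alive[idx_all]
  death_final <- death[idx_all]
  death_final[censored] <- y_end

  ped <- as_pedigree(tibble::tibble(
    id = id[idx_all], sire = sire[idx_all], dam = dam[idx_all],
    sex = sex[idx_all], birth_year = birth[idx_all], death_year = death_final
  ))
  diplotypes <- tibble::tibble(
    id = id[idx_all],
    hap1 = labels[pmin(h1[idx_all], h2[idx_all])],
    hap2 = labels[pmax(h1[idx_all], h2[idx_all])]
  )
  hs <- haplotype_set(labels,
                      make_haplotype_sequences(labels, cfg$sequence_length))
  observed <- apply_missingness(diplotypes, cfg$genotyping_missingness)

  fit <- derive_fitness(ped, censored, y_end)

  founder_cohorts <- which(birth[idx_all] <= y0 + 3L)
  realised <- tabulate(c(h1[founder_cohorts], h2[founder_cohorts]), nbins = K) /
    (2 * length(founder_cohorts))
  truth <- c(unclass(cfg), list(
    n_individuals = n,
    realised_founder_freqs = setNames(realised, labels)
  ))

  structure(
    list(pedigree = ped, diplotypes = diplotypes,
         diplotypes_observed = observed, haplotypes = hs,
         fitness = fit$fitness, fitness_annual = fit$annual,
         truth = truth, config = cfg),
    class = "synth_population"
  )
}

# Fitness measures from the realised life histories.
derive_fitness <- function(ped, censored, y_end) {
  off_by_parent_year <- dplyr::bind_rows(
    tibble::tibble(parent = ped$sire, year = ped$birth_year),
    tibble::tibble(parent = ped$dam, year = ped$birth_year)
  )
  off_by_parent_year <- dplyr::count(
    dplyr::filter(off_by_parent_year, !is.na(.data$parent)),
    .data$parent, .data$year, name = "n_off"
  )
  totals <- dplyr::summarise(dplyr::group_by(off_by_parent_year, .data$parent),
                             total = sum(.data$n_off), .groups = "drop")
  total_fitness <- setNames(rep(0L, nrow(ped)), ped$id)
  total_fitness[totals$parent] <- totals$total

  is_adult <- ped$death_year > ped$birth_year
  juvenile_survival <- ifelse(ped$birth_year == y_end & censored, NA_integer_,
                              as.integer(is_adult))
  adult_lifespan <- ifelse(is_adult & !censored,
                           ped$death_year - ped$birth_year, NA_integer_)

  fitness <- tibble::tibble(
    id = ped$id, sex = ped$sex, birth_year = ped$birth_year,
    censored = censored,
    total_fitness = as.integer(unname(total_fitness)),
    juvenile_survival = juvenile_survival,
    adult_lifespan = adult_lifespan,
    adult_lifetime_breeding = ifelse(is_adult, as.integer(unname(total_fitness)),
                                     NA_integer_)
  )

  adults <- which(is_adult)
  len <- ped$death_year[adults] - ped$birth_year[adults]
  annual <- tibble::tibble(
    id = rep(ped$id[adults], len),
    year = sequence(len) + rep(ped$birth_year[adults], len)
  )
  annual$age <- annual$year - rep(ped$birth_year[adults], len)
  annual <- dplyr::left_join(
    annual,
    dplyr::rename(off_by_parent_year, id = "parent"),
    by = c("id", "year")
  )
  annual$annual_breeding <- dplyr::coalesce(annual$n_off, 0L)
  annual$n_off <- NULL
  last_year_of <- setNames(ped$death_year, ped$id)
  cens_of <- setNames(censored, ped$id)
  annual$annual_survival <- ifelse(
    annual$year < last_year_of[annual$id], 1L,
    ifelse(cens_of[annual$id], NA_integer_, 0L)
  )
  list(fitness = fitness, annual = annual)
}

#' Randomly drop diplotypes to emulate incomplete genotyping
#'
#' @param diplotypes Tibble `id`, `hap1`, `hap2`.
#' @param rate Per-individual probability of being unobserved.
#' @param seed Optional seed (default: current RNG stream).
#' @return The diplotype tibble with dropped rows removed.
#' @export
apply_missingness <- function(diplotypes, rate, seed = NULL) {
  if (rate < 0 || rate > 1) abort("`rate` must be in [0, 1].")
  with_seed(seed, diplotypes[runif(nrow(diplotypes)) >= rate, , drop = FALSE])
}

#' Write a complete fixture set to a directory
#'
#' Writes `pedigree.tsv`, `diplotypes.tsv` (the observed, incomplete table),
#' `haplotypes.fasta`, `fitness.tsv` and `manifest.yaml` (every generating
#' parameter, including the seed). All files round-trip through the package
#' readers.
#'
#' @param pop A `synth_population` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_fixture_set <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.tsv"),
    diplotypes = file.path(dir, "diplotypes.tsv"),
    haplotypes = file.path(dir, "haplotypes.fasta"),
    fitness = file.path(dir, "fitness.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_pedigree(pop$pedigree, paths[["pedigree"]])
  write_diplotypes(pop$diplotypes_observed, paths[["diplotypes"]])
  write_haplotype_fasta(pop$haplotypes, paths[["haplotypes"]])
  readr::write_tsv(pop$fitness, paths[["fitness"]], na = "NA", progress = FALSE)
  manifest <- pop$truth
  manifest$founder_hap_freqs <- as.list(manifest$founder_hap_freqs)
  manifest$realised_founder_freqs <- as.list(manifest$realised_founder_freqs)
  manifest$selection_juvenile <- as.list(manifest$selection_juvenile)
  manifest$selection_male_breeding <- as.list(manifest$selection_male_breeding)
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

#' @export
print.synth_population <- function(x, ...) {
  cat(sprintf(
    "# Synthetic population: %d individuals, years %d-%d, %d haplotypes (%d genotyped)\n",
    nrow(x$pedigree), x$config$years[1], x$config$years[2],
    nrow(x$haplotypes), nrow(x$diplotypes_observed)
  ))
  invisible(x)
}
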