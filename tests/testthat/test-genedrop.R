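# Shared toy: founders born 1989-1990 (founder window 1989-1992),
# offspring born 1993+ are simulated.
toy_cfg <- function(n_sim, seed, last = 1996, freq = "genotyped_only") {
  genedrop_config(founder_years = c(1989, 1992), simulated_years = c(1993, last),
                  n_sim = n_sim, seed = seed, frequency_individuals = freq)
}

test_that("configuration invariants are enforced", {
  expect_error(genedrop_config(founder_years = c(1989, 1994),
                               simulated_years = c(1993, 2012)),
               "must end before")
  expect_error(genedrop_config(n_sim = 0), "at least 1")
  expect_error(genedrop_config(founder_years = c(1992, 1989)), "increasing")
})

test_that("founder-cohort individuals keep observed diplotypes in every replicate", {
  ped <- mk_ped(c("F1", "F2", "K1"), sire = c(NA, NA, "F1"),
                dam = c(NA, NA, "F2"), sex = c("male", "female", NA),
                birth = c(1989, 1989, 1993), death = c(1996, 1996, 1996))
  dip <- mk_dip(c("F1", "F2", "K1"), c("C", "A", "A"), c("D", "B", "C"))
  drop <- run_genedrop(ped, dip, toy_cfg(200, seed = 11), keep_assignments = TRUE)
  src <- setNames(drop$sources$source, drop$sources$id)
  expect_equal(src[["F1"]], "observed")
  expect_equal(unique(drop$assignments$hap1["F1", ]), "C")
  expect_equal(unique(drop$assignments$hap2["F1", ]), "D")
  # post-founder individual with an observed diplotype is never copied
  expect_equal(src[["K1"]], "mendelian")
  expect_gt(length(unique(paste(drop$assignments$hap1["K1", ],
                                drop$assignments$hap2["K1", ]))), 1)
})

test_that("half-known parents mix a Mendelian and a cohort-frequency draw", {
  # F3 has no observed diplotype: allele 1 Mendelian from F1 (A,B),
  # allele 2 from the 1990 cohort frequencies, which are degenerate at C.
  ped <- mk_ped(c("F1", "F2", "F3"), sire = c(NA, NA, "F1"),
                dam = c(NA, NA, NA), sex = c("male", "female", NA),
                birth = c(1989, 1990, 1990), death = 1996)
  dip <- mk_dip(c("F1", "F2"), c("A", "C"), c("B", "C"))
  labels <- c("A", "B", "C")
  n_sim <- 4000
  drop <- run_genedrop(ped, dip, toy_cfg(n_sim, seed = 5), haplotypes = labels,
                       keep_assignments = TRUE)
  expect_equal(drop$sources$source[drop$sources$id == "F3"], "mendelian")
  sim <- simulated_pair_freqs(drop, "F3", labels)
  exp_u <- enum_pair_probs(enum_drop_dist(ped, dip, c(1989, 1992), labels)[["F3"]],
                           labels)
  expect_equal(unname(exp_u[["A/C"]]), 0.5)
  expect_equal(unname(exp_u[["B/C"]]), 0.5)
  for (pair in names(exp_u)) {
    se <- sqrt(exp_u[[pair]] * (1 - exp_u[[pair]]) / n_sim)
    expect_lt(abs(sim[[pair]] - exp_u[[pair]]), max(3 * se, 1e-12))
  }
})

test_that("homozygous parents transmit their single allele always", {
  ped <- mk_ped(c("F1", "F2", "K"), sire = c(NA, NA, "F1"), dam = c(NA, NA, "F2"),
                birth = c(1989, 1989, 1993), death = 1996)
  dip <- mk_dip(c("F1", "F2"), c("A", "B"), c("A", "B"))
  drop <- run_genedrop(ped, dip, toy_cfg(500, seed = 3), keep_assignments = TRUE)
  expect_equal(unique(drop$assignments$hap1["K", ]), "A")
  expect_equal(unique(drop$assignments$hap2["K", ]), "B")
})

test_that("three-generation dosage distribution matches exact enumeration", {
  # founders (A,A) x (B,B) -> child always (A,B); grandchild via second (B,B)
  # mate has B-dosage distribution {1: 0.5, 2: 0.5}
  ped <- mk_ped(c("G1", "G2", "G3", "C1", "K"),
                sire = c(NA, NA, NA, "G1", "C1"),
                dam = c(NA, NA, NA, "G2", "G3"),
                sex = c("male", "female", "female", "male", NA),
                birth = c(1989, 1989, 1989, 1993, 1995), death = 1996)
  dip <- mk_dip(c("G1", "G2", "G3"), c("A", "B", "B"), c("A", "B", "B"))
  n_sim <- 10000
  drop <- run_genedrop(ped, dip, toy_cfg(n_sim, seed = 9), keep_assignments = TRUE)
  expect_equal(unique(drop$assignments$hap1["C1", ]), "A")
  expect_equal(unique(drop$assignments$hap2["C1", ]), "B")
  b_dosage <- (drop$assignments$hap1["K", ] == "B") +
    (drop$assignments$hap2["K", ] == "B")
  expect_setequal(unique(b_dosage), c(1, 2))
  se <- sqrt(0.25 / n_sim)
  expect_lt(abs(mean(b_dosage == 2) - 0.5), 3 * se)
  # and the full diplotype distribution matches the enumeration oracle
  exp_u <- enum_pair_probs(enum_drop_dist(ped, dip, c(1989, 1992), c("A", "B"))[["K"]],
                           c("A", "B"))
  sim <- simulated_pair_freqs(drop, "K", c("A", "B"))
  for (pair in names(exp_u)) {
    se <- sqrt(exp_u[[pair]] * (1 - exp_u[[pair]]) / n_sim)
    expect_lt(abs(sim[[pair]] - exp_u[[pair]]), max(3 * se, 1e-12))
  }
})

test_that("identical seeds give bit-identical output, different seeds differ", {
  pop <- simulate_population(synth_config(n_founders = 50, years = c(1989, 1998),
                                          seed = 77))
  cfg <- toy_cfg(50, seed = 123, last = 1998)
  d1 <- run_genedrop(pop$pedigree, pop$diplotypes_observed, cfg)
  d2 <- run_genedrop(pop$pedigree, pop$diplotypes_observed, cfg)
  expect_identical(d1$sim_freq, d2$sim_freq)
  d3 <- run_genedrop(pop$pedigree, pop$diplotypes_observed,
                     toy_cfg(50, seed = 124, last = 1998))
  expect_false(identical(d1$sim_freq, d3$sim_freq))
  # drop_once agrees with itself under a fixed seed
  expect_identical(drop_once(pop$pedigree, pop$diplotypes_observed, cfg),
                   drop_once(pop$pedigree, pop$diplotypes_observed, cfg))
})

test_that("defined frequency rows sum to one and undefined years are flagged", {
  pop <- simulate_population(synth_config(n_founders = 50, years = c(1989, 1998),
                                          seed = 78))
  drop <- run_genedrop(pop$pedigree, pop$diplotypes_observed,
                       toy_cfg(40, seed = 2, last = 1998))
  sums <- apply(drop$sim_freq, c(1, 3), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  obs_sums <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(drop$observed, !is.na(freq)), year),
    s = sum(freq)
  )$s
  expect_true(all(abs(obs_sums - 1) < 1e-12))

  # a year in which no genotyped individual is alive is NA, not zero
  ped <- mk_ped(c("F1", "K"), sire = c(NA, "F1"), birth = c(1989, 1994),
                death = c(1991, 1995))
  dip <- mk_dip("F1", "A", "B")
  obs <- observed_standing_frequencies(ped, dip, 1989:1995)
  expect_true(all(is.na(obs$freq[obs$year %in% 1992:1995])))
  expect_true(all(obs$n_individuals[obs$year %in% 1992:1995] == 0))
})

test_that("a founders-only pedigree reproduces the observed diplotypes", {
  ped <- mk_ped(c("F1", "F2", "F3"), birth = c(1989, 1990, 1991), death = 1995)
  dip <- mk_dip(c("F1", "F2", "F3"), c("A", "B", "A"), c("B", "B", "C"))
  one <- drop_once(ped, dip, toy_cfg(1, seed = 4))
  expect_equal(one$hap1, dip$hap1[match(one$id, dip$id)])
  expect_equal(one$hap2, dip$hap2[match(one$id, dip$id)])
  expect_true(all(one$source == "observed"))
})

test_that("cohort-frequency fallback is applied and reported", {
  # the 1994 cohort has no genotyped individuals, so its unknown-parent
  # draws borrow the nearest cohort's frequencies
  ped <- mk_ped(c("F1", "X", "Y"), birth = c(1989, 1994, 1994), death = 1996)
  dip <- mk_dip("F1", "A", "B")
  expect_message(
    drop <- run_genedrop(ped, dip, toy_cfg(100, seed = 6)),
    "fallback"
  )
  expect_match(drop$cohort_fallbacks, "1994")
  # the fallback keeps the drop well-defined
  expect_false(any(is.na(drop$sim_freq[, , 1])))
})

test_that("Monte Carlo means match the exact propagation oracle", {
  pop <- simulate_population(synth_config(n_founders = 60, years = c(1989, 1999),
                                          seed = 15))
  cfg <- toy_cfg(2000, seed = 21, last = 1999)
  drop <- run_genedrop(pop$pedigree, pop$diplotypes_observed, cfg)
  ex <- genedrop_expectation(pop$pedigree, pop$diplotypes_observed, cfg)
  fin <- drop$sim_freq[dim(drop$sim_freq)[1], , ]
  mu <- rowMeans(fin)
  se <- apply(fin, 1, sd) / sqrt(ncol(fin))
  exp_f <- dplyr::filter(ex, year == max(year))
  exp_f <- setNames(exp_f$expected_freq, exp_f$haplotype)[names(mu)]
  expect_true(all(abs(mu - exp_f) < 3 * pmax(se, 1e-6)))
})
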