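eight_haps <- LETTERS[1:8]

test_that("design matrix codes dosages relative to the reference haplotype", {
  dip <- mk_dip(c("i1", "i2", "i3"), c("H", "H", "A"), c("H", "C", "B"))
  X <- build_design(dip, eight_haps, reference = "H")
  expect_equal(colnames(X),
               c("(Intercept)", paste0("dosage_", LETTERS[1:7])))
  expect_length(attr(X, "haplotype_terms"), 7) # seven degrees of freedom
  expect_equal(unname(X["i1" == dip$id, -1]), rep(0, 7)) # (H,H) all zero
  expect_equal(unname(X[2, "dosage_C"]), 1)
  expect_equal(sum(X[2, -1]), 1)
  expect_error(build_design(dip, eight_haps, reference = "Z"), "Z")

  hs <- toy_hapset()
  dip2 <- mk_dip(c("i1", "i2"), c("A", "A"), c("A", "B"))
  X2 <- build_design(dip2, hs, reference = "A",
                     heterozygosity = TRUE, divergence = TRUE)
  expect_equal(unname(X2[, "heterozygosity"]), c(0, 1))
  expect_equal(unname(X2[, "divergence"]), c(0, 0.1))
})

test_that("Wald statistic behaves as a chi-square quadratic form", {
  labs <- paste0("dosage_", LETTERS[1:7])
  z <- coef_summary(setNames(rep(0, 7), labs), diag(7))
  w0 <- wald_test(z)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$df, 7)

  b <- coef_summary(setNames(c(2, rep(0, 6)), labs), diag(7))
  w <- wald_test(b)
  expect_equal(w$statistic, 4)
  expect_equal(w$p_value, pchisq(4, 7, lower.tail = FALSE))

  # invariant to joint rescaling b -> 2b, V -> 4V and to label order
  b2 <- coef_summary(setNames(c(4, rep(0, 6)), labs), 4 * diag(7))
  expect_equal(wald_test(b2)$statistic, w$statistic)
  expect_equal(wald_test(b, rev(labs))$statistic, w$statistic)

  expect_error(wald_test(b, c(labs, "nope")), "nope")
  sing <- coef_summary(setNames(c(1, 1), c("a", "b")),
                       matrix(1, 2, 2))
  expect_warning(wald_test(sing, c("a", "b")), "pseudo-inverse")
})

test_that("haplotype-vs-rest contrasts follow the arithmetic definition", {
  # all haplotype effects identical (equal to the reference's 0 in every
  # draw): every contrast 0, none flagged
  flat <- as.data.frame(matrix(0, 50, 7,
                               dimnames = list(NULL, paste0("dosage_", LETTERS[1:7]))))
  ctr <- haplotype_vs_rest_contrasts(flat, eight_haps, reference = "H")
  expect_equal(ctr$estimate[ctr$haplotype != "H"], rep(0, 7))
  expect_false(any(ctr$flagged[ctr$haplotype != "H"]))

  # b_D == 1, others 0 -> c_D = 1, all others -1/7
  d1 <- as.data.frame(matrix(0, 40, 7,
                             dimnames = list(NULL, paste0("dosage_", LETTERS[1:7]))))
  d1$dosage_D <- 1
  ctr2 <- haplotype_vs_rest_contrasts(d1, eight_haps, reference = "H")
  expect_equal(ctr2$estimate[ctr2$haplotype == "D"], 1)
  expect_equal(ctr2$estimate[ctr2$haplotype != "D"], rep(-1 / 7, 7))

  # permuting labels permutes the contrasts identically
  set.seed(5)
  dr <- as.data.frame(matrix(rnorm(200 * 7), 200, 7,
                             dimnames = list(NULL, paste0("dosage_", LETTERS[1:7]))))
  c_orig <- haplotype_vs_rest_contrasts(dr, eight_haps, reference = "H")
  perm <- c("C", "A", "B", "E", "D", "G", "F", "H")
  c_perm <- haplotype_vs_rest_contrasts(dr, perm, reference = "H")
  expect_equal(
    c_perm$estimate[match(eight_haps, c_perm$haplotype)],
    c_orig$estimate
  )

  expect_error(haplotype_vs_rest_contrasts(dr, "H", reference = "H"), "at least 2")
})

test_that("contrasts do not depend on the choice of reference haplotype", {
  set.seed(11)
  dr <- matrix(rnorm(300 * 7, sd = 0.5), 300, 7,
               dimnames = list(NULL, paste0("dosage_", LETTERS[1:7])))
  c_refH <- haplotype_vs_rest_contrasts(as.data.frame(dr), eight_haps, "H")
  # re-express the same posterior relative to haplotype A
  recentred <- dr - dr[, "dosage_A"]
  recentred <- cbind(recentred[, paste0("dosage_", c("B", "C", "D", "E", "F", "G"))],
                     dosage_H = -dr[, "dosage_A"])
  c_refA <- haplotype_vs_rest_contrasts(as.data.frame(recentred), eight_haps, "A")
  expect_equal(
    c_refA$estimate[match(eight_haps, c_refA$haplotype)],
    c_refH$estimate[match(eight_haps, c_refH$haplotype)],
    tolerance = 1e-10
  )
})

test_that("posterior draw IO and summaries validate their inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dr <- tibble::tibble(dosage_A = c(0.1, 0.2, 0.3), dosage_B = c(-1, 0, 1))
  readr::write_tsv(dr, path)
  back <- read_posterior_draws(path)
  expect_equal(as.data.frame(back), as.data.frame(dr))
  s <- summarise_draws(back)
  expect_equal(unname(s$mean), c(0.2, 0))
  expect_equal(s$vcov, stats::cov(as.matrix(dr)), ignore_attr = TRUE)
  writeLines("dosage_A\tdosage_B\n0.1\t0.2", path)
  expect_error(read_posterior_draws(path), "at least 2")
  expect_error(summarise_draws(dr[1, ]), "at least 2")
})

test_that("fitters recover closed-form maximum-likelihood solutions", {
  X1 <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f_pois <- fit_glm(c(1, 2, 3), X1, "poisson_log")
  expect_equal(unname(f_pois$coef), log(2), tolerance = 1e-6)

  X2 <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  f_probit <- fit_glm(c(1, 1, 0, 0), X2, "binomial_probit")
  expect_equal(unname(f_probit$coef), 0, tolerance = 1e-6)

  # zero inflation fixed at zero nests the plain Poisson fit
  set.seed(3)
  X <- cbind(`(Intercept)` = 1, x = rnorm(200))
  y <- rpois(200, exp(0.4 + 0.3 * X[, "x"]))
  f_zip0 <- fit_glm(y, X, "zero_inflated_poisson", fix_zero_inflation = 0)
  f_p <- fit_glm(y, X, "poisson_log")
  expect_equal(f_zip0$coef, f_p$coef, tolerance = 1e-5)
  expect_equal(f_zip0$loglik, f_p$loglik, tolerance = 1e-6)

  expect_error(fit_glm(y, cbind(X, x2 = X[, "x"]), "poisson_log"),
               "rank deficient")
  expect_error(fit_glm(y[1:10], X, "poisson_log"), "length")
})

test_that("the zero-inflated Poisson fitter agrees with an independent implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(21)
  n <- 800
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  lam <- exp(0.6 + 0.4 * X[, "x"])
  y <- ifelse(runif(n) < 0.25, 0L, rpois(n, lam))
  ours <- fit_glm(y, X, "zero_inflated_poisson")
  ref <- glmmTMB::glmmTMB(y ~ x, data = data.frame(y = y, x = X[, "x"]),
                          ziformula = ~1, family = stats::poisson())
  ref_coef <- glmmTMB::fixef(ref)
  expect_equal(unname(ours$coef[c("(Intercept)", "x")]),
               unname(ref_coef$cond), tolerance = 1e-3)
  expect_equal(unname(ours$coef["zi_logit"]), unname(ref_coef$zi),
               tolerance = 1e-3)
})

test_that("ordinal probit absorbs the intercept into thresholds and recovers effects", {
  set.seed(9)
  n <- 1500
  x <- rnorm(n)
  latent <- 0.8 * x + rnorm(n)
  y <- cut(latent, c(-Inf, -0.7, 0.7, Inf), labels = FALSE) - 1
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- fit_glm(y, X, "ordinal_probit")
  expect_false("(Intercept)" %in% names(f$coef))
  expect_lt(abs(f$coef[["x"]] - 0.8), 3 * sqrt(f$vcov["x", "x"]) + 0.05)
  expect_true(any(grepl("threshold", names(f$coef))))

  td <- tidy(f)
  expect_setequal(names(td),
                  c("term", "estimate", "std.error", "statistic", "p.value"))
  g <- glance(f)
  expect_equal(g$n, n)
  expect_true(g$converged)
})

test_that("coefficient summaries validate their covariance", {
  expect_error(coef_summary(c(a = 1), matrix(c(1, 2), 1)), "dimensions")
  expect_error(coef_summary(setNames(1:2, c("a", "b")),
                            matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
  expect_error(coef_summary(setNames(1:2, c("a", "b")),
                            matrix(c(1, 2, 2, 1), 2)), "semi-definite")
  expect_error(coef_summary(1:2, diag(2)), "named")
})
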