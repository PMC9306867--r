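#' Coefficient summary (posterior or ML mean and covariance)
#'
#' A light container for a coefficient vector and its covariance matrix, the
#' two ingredients of the Wald test. Posterior draws from an external
#' mixed-model fit are summarised the same way (posterior mean and posterior
#' covariance).
#'
#' @param mean Named numeric coefficient vector.
#' @param vcov Covariance matrix (symmetric, positive semi-definite within
#'   1e-8), dimensions matching `mean`.
#' @return A `coef_summary` object.
#' @export
coef_summary <- function(mean, vcov) {
  if (is.null(names(mean))) abort("`mean` must be a named vector.")
  vcov <- as.matrix(vcov)
  if (!all(dim(vcov) == length(mean))) {
    abort("`vcov` dimensions must match the length of `mean`.")
  }
  if (max(abs(vcov - t(vcov))) > 1e-8) abort("`vcov` must be symmetric.")
  ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("`vcov` must be positive semi-definite.")
  }
  dimnames(vcov) <- list(names(mean), names(mean))
  structure(list(mean = mean, vcov = vcov, labels = names(mean)),
            class = "coef_summary")
}

as_coef_summary <- function(x) {
  if (inherits(x, "coef_summary")) return(x)
  if (inherits(x, "fitness_fit")) return(coef_summary(x$coef, x$vcov))
  abort("Expected a `coef_summary` or `fitness_fit`.")
}

#' Summarise posterior draws into a coefficient summary
#'
#' @param draws Data frame or matrix of posterior draws (rows = samples,
#'   columns = coefficients).
#' @return A `coef_summary` with the posterior mean and covariance.
#' @export
summarise_draws <- function(draws) {
  m <- as.matrix(draws)
  if (nrow(m) < 2) abort("Need at least 2 posterior draws.")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m))) {
    abort("Draw columns must carry unique coefficient labels.")
  }
  coef_summary(colMeans(m), stats::cov(m))
}

#' Read posterior coefficient draws from TSV/CSV
#'
#' Columns are coefficient labels, rows are draws. The delimiter is taken from
#' the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path Path to the draw file.
#' @return Tibble of draws.
#' @export
read_posterior_draws <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = readr::cols(.default = readr::col_double()),
               progress = FALSE)
  if (nrow(df) < 2) abort("Need at least 2 posterior draws.")
  if (any(vapply(df, function(x) all(is.na(x)), logical(1)))) {
    abort("Posterior draw file contains non-numeric or empty columns.")
  }
  df
}

#' Build a fixed-effects design matrix with haplotype dosages
#'
#' Dosage (0/1/2) columns for every haplotype except the reference, so that
#' with `K` haplotypes the haplotype block has `K - 1` degrees of freedom and
#' individual effects are relative to the reference. Optional heterozygosity
#' and sequence-divergence columns, plus generic covariate pass-through.
#'
#' @param diplotypes Tibble `id`, `hap1`, `hap2`.
#' @param hs A `haplotype_set` (sequences needed only for `divergence`).
#' @param reference Reference haplotype label (default `"H"`).
#' @param heterozygosity,divergence Logical; include those columns.
#' @param covariates Optional data frame of extra columns (same row order).
#' @return Numeric matrix with an `(Intercept)` column; haplotype dosage
#'   columns are named `dosage_<label>` and listed in the
#'   `"haplotype_terms"` attribute.
#' @export
build_design <- function(diplotypes, hs, reference = "H",
                         heterozygosity = FALSE, divergence = FALSE,
                         covariates = NULL) {
  labels <- if (is.character(hs)) hs else hs$haplotype
  if (!reference %in% labels) {
    abort(paste0("Reference haplotype '", reference, "' is not in the haplotype set."))
  }
  dos <- dosage_matrix(diplotypes, labels)
  keep <- setdiff(labels, reference)
  X <- cbind(`(Intercept)` = 1, as.matrix(dos[keep]))
  colnames(X) <- c("(Intercept)", paste0("dosage_", keep))
  if (heterozygosity) {
    X <- cbind(X, heterozygosity = heterozygosity(diplotypes$hap1, diplotypes$hap2))
  }
  if (divergence) {
    X <- cbind(X, divergence = diplotype_divergence(diplotypes$hap1, diplotypes$hap2, hs))
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(tibble::as_tibble(covariates))
    X <- cbind(X, cv)
  }
  attr(X, "haplotype_terms") <- paste0("dosage_", keep)
  attr(X, "reference") <- reference
  X
}

#' Wald test on a coefficient subset
#'
#' Quadratic-form test `W = b' V^-1 b` of whether a subset of coefficients is
#' jointly zero, with `W ~ chi-square(df = length(subset))` under the null.
#' With the 7 non-reference haplotype dosage terms of an 8-haplotype system
#' this is the 7-d.f. test of whether haplotypes explain variation in fitness.
#'
#' @param x A `coef_summary` or `fitness_fit`.
#' @param terms Coefficient labels to test jointly; defaults to the
#'   haplotype dosage terms (`dosage_*`) if present, else all non-intercept
#'   terms.
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(x, terms = NULL) {
  s <- as_coef_summary(x)
  if (is.null(terms)) {
    terms <- grep("^dosage_", s$labels, value = TRUE)
    if (length(terms) == 0) terms <- setdiff(s$labels, "(Intercept)")
  }
  missing <- setdiff(terms, s$labels)
  if (length(missing) > 0) {
    abort(paste0("Unknown coefficient label(s): ", paste(missing, collapse = ", ")))
  }
  b <- s$mean[terms]
  V <- s$vcov[terms, terms, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e) {
    warn("Sub-covariance is singular; using the Moore-Penrose pseudo-inverse.")
    MASS::ginv(V)
  })
  W <- drop(t(b) %*% Vi %*% b)
  df <- length(terms)
  tibble::tibble(statistic = W, df = df, p_value = pchisq(W, df, lower.tail = FALSE))
}

#' Haplotype-versus-rest contrasts from posterior draws
#'
#' For each haplotype `i`, the contrast `c_i = b_i - mean_{j != i}(b_j)` is
#' computed per posterior draw, with the reference haplotype's effect fixed at
#' zero and included in the means. A haplotype is flagged when the equal-tailed
#' 95% credible interval of its contrast excludes zero. Following the
#' sequential procedure, contrasts are meant to be interpreted only after a
#' significant Wald test; the caller enforces that.
#'
#' @param draws Data frame or matrix of posterior draws whose columns include
#'   the non-reference haplotype coefficients.
#' @param haplotypes Character vector of all haplotype labels (including the
#'   reference).
#' @param reference Reference haplotype label whose effect is fixed at 0.
#' @param columns Named character vector mapping each non-reference label to
#'   its draw column. Defaults to `dosage_<label>` when present, else the bare
#'   label.
#' @param level Credible level (default 0.95).
#' @return Tibble `haplotype`, `estimate`, `lower`, `upper`, `flagged`.
#' @export
haplotype_vs_rest_contrasts <- function(draws, haplotypes, reference = "H",
                                        columns = NULL, level = 0.95) {
  if (length(haplotypes) < 2) abort("Need at least 2 haplotypes for contrasts.")
  if (!reference %in% haplotypes) {
    abort(paste0("Reference haplotype '", reference, "' is not among the labels."))
  }
  m <- as.matrix(draws)
  others <- setdiff(haplotypes, reference)
  if (is.null(columns)) {
    columns <- ifelse(paste0("dosage_", others) %in% colnames(m),
                      paste0("dosage_", others), others)
    names(columns) <- others
  }
  missing <- setdiff(others, names(columns))
  if (length(missing) > 0) {
    abort(paste0("No draw column mapped for haplotype(s): ",
                 paste(missing, collapse = ", ")))
  }
  absent <- setdiff(unname(columns[others]), colnames(m))
  if (length(absent) > 0) {
    abort(paste0("Draw column(s) not found: ", paste(absent, collapse = ", ")))
  }
  B <- cbind(m[, columns[others], drop = FALSE], 0)
  colnames(B) <- c(others, reference)
  B <- B[, haplotypes, drop = FALSE]
  K <- length(haplotypes)
  tot <- rowSums(B)
  alpha <- (1 - level) / 2
  rows <- lapply(seq_len(K), function(i) {
    ci <- B[, i] - (tot - B[, i]) / (K - 1)
    qs <- quantile(ci, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(
      haplotype = haplotypes[i],
      estimate = mean(ci), lower = qs[1], upper = qs[2],
      flagged = qs[1] > 0 | qs[2] < 0
    )
  })
  dplyr::bind_rows(rows)
}

# ---- simplified fixed-effects fitters -------------------------------------

glm_family_names <- c("binomial_probit", "poisson_log", "zero_inflated_poisson",
                      "ordinal_probit")

#' Fixed-effects fitness-model fitter
#'
#' Maximum-likelihood fixed-effects fits for the error families used with the
#' different fitness measures: probit regression for binary survival,
#' log-link Poisson for life span and breeding counts, zero-inflated Poisson
#' for total fitness (a logit-scale inflation intercept shared across
#' individuals), and ordinal probit for small bounded counts such as female
#' annual breeding success. The covariance is the inverse observed
#' information. This is a deliberately simplified stand-in for mixed ("animal")
#' models, intended for synthetic-data validation of the post-processing; it
#' fits no random effects.
#'
#' @param response Response vector (0/1 for `binomial_probit`, non-negative
#'   counts for the Poisson families, small ordered counts for
#'   `ordinal_probit`).
#' @param design Numeric design matrix (e.g. from [build_design()]),
#'   including its own intercept column. For `ordinal_probit` the intercept
#'   column is dropped (absorbed into the thresholds).
#' @param family One of `"binomial_probit"`, `"poisson_log"`,
#'   `"zero_inflated_poisson"`, `"ordinal_probit"`.
#' @param fix_zero_inflation Optional fixed zero-inflation probability for
#'   `zero_inflated_poisson` (e.g. 0 reduces the model to `poisson_log`).
#' @return A `fitness_fit` object with elements `coef`, `vcov`, `family`,
#'   `converged`, `loglik`, `n`; see [tidy.fitness_fit()].
#' @export
fit_glm <- function(response, design,
                    family = c("binomial_probit", "poisson_log",
                               "zero_inflated_poisson", "ordinal_probit"),
                    fix_zero_inflation = NULL) {
  family <- match.arg(family)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(response)
  if (length(y) != nrow(X)) abort("`response` length must match the design rows.")
  if (qr(X)$rank < ncol(X) && family != "ordinal_probit") {
    abort("Design matrix is rank deficient.")
  }
  switch(family,
    binomial_probit = fit_glm_irls(y, X, binomial(link = "probit"), family),
    poisson_log = fit_glm_irls(y, X, poisson(link = "log"), family),
    zero_inflated_poisson = fit_zip(y, X, fix_zero_inflation),
    ordinal_probit = fit_ordinal_probit(y, X)
  )
}

new_fitness_fit <- function(coef, vcov, family, converged, loglik, n,
                            note = NULL) {
  dimnames(vcov) <- list(names(coef), names(coef))
  structure(
    list(coef = coef, vcov = vcov, family = family, converged = converged,
         loglik = loglik, n = n, note = note),
    class = "fitness_fit"
  )
}

fit_glm_irls <- function(y, X, fam, family_name) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = fam))
  if (!fit$converged) {
    abort(sprintf("%s fit did not converge after %d IRLS iterations.",
                  family_name, fit$iter))
  }
  note <- NULL
  if (family_name == "binomial_probit" && any(abs(fit$coefficients) > 10)) {
    warn("Very large probit coefficients; possible separation. Standard errors are unreliable.")
    note <- "possible separation"
  }
  R <- qr.R(fit$qr)
  V <- chol2inv(R)
  co <- fit$coefficients
  ll <- switch(family_name,
    binomial_probit = sum(stats::dbinom(y, 1, fit$fitted.values, log = TRUE)),
    poisson_log = sum(dpois(y, fit$fitted.values, log = TRUE))
  )
  new_fitness_fit(co, V, family_name, TRUE, ll, length(y), note)
}

zip_negloglik <- function(beta, g0, y, X) {
  eta <- drop(X %*% beta)
  lam <- exp(eta)
  pi0 <- plogis(g0)
  zero <- y == 0
  ll <- numeric(length(y))
  ll[zero] <- log(pi0 + (1 - pi0) * exp(-lam[zero]))
  ll[!zero] <- log1p(-pi0) + y[!zero] * eta[!zero] - lam[!zero] - lgamma(y[!zero] + 1)
  -sum(ll)
}

fit_zip <- function(y, X, fix_zero_inflation = NULL) {
  if (any(y < 0 | y != floor(y))) abort("Zero-inflated Poisson needs non-negative counts.")
  start_pois <- suppressWarnings(stats::glm.fit(X, pmax(y, 0), family = poisson()))$coefficients
  p <- ncol(X)
  if (!is.null(fix_zero_inflation)) {
    pi0 <- fix_zero_inflation
    if (pi0 < 0 || pi0 >= 1) abort("`fix_zero_inflation` must be in [0, 1).")
    g0 <- if (pi0 == 0) -Inf else qlogis(pi0)
    opt <- optim(start_pois, function(b) zip_negloglik(b, g0, y, X),
                 method = "BFGS", hessian = TRUE, control = list(maxit = 500))
    if (opt$convergence != 0) {
      abort(paste0("Zero-inflated Poisson fit did not converge (optim code ",
                   opt$convergence, ")."))
    }
    co <- setNames(opt$par, colnames(X))
    V <- solve(opt$hessian)
    return(new_fitness_fit(co, V, "zero_inflated_poisson", TRUE, -opt$value,
                           length(y), note = sprintf("zero inflation fixed at %g", pi0)))
  }
  p0_obs <- mean(y == 0)
  p0_fit <- mean(dpois(0, exp(drop(X %*% start_pois))))
  excess <- (p0_obs - p0_fit) / max(1 - p0_fit, 1e-6)
  g0_start <- qlogis(min(max(excess, 0.02), 0.95))
  par0 <- c(start_pois, zi_logit = g0_start)
  opt <- optim(par0, function(p_) zip_negloglik(p_[seq_len(p)], p_[p + 1], y, X),
               method = "BFGS", hessian = TRUE, control = list(maxit = 1000))
  if (opt$convergence != 0) {
    abort(paste0("Zero-inflated Poisson fit did not converge (optim code ",
                 opt$convergence, ")."))
  }
  co <- setNames(opt$par, c(colnames(X), "zi_logit"))
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    warn("Observed information is singular; using a ridge-regularised inverse.")
    solve(opt$hessian + diag(1e-6, nrow(opt$hessian)))
  })
  new_fitness_fit(co, V, "zero_inflated_poisson", TRUE, -opt$value, length(y))
}

fit_ordinal_probit <- function(y, X) {
  keep <- setdiff(colnames(X), "(Intercept)")
  if (length(keep) == 0) {
    abort("Ordinal probit needs at least one non-intercept column.")
  }
  df <- as.data.frame(X[, keep, drop = FALSE])
  safe <- make.names(keep, unique = TRUE)
  names(df) <- safe
  df$.y <- factor(y, ordered = TRUE)
  if (nlevels(df$.y) < 2) abort("Ordinal response needs at least 2 observed levels.")
  fit <- MASS::polr(.y ~ ., data = df, method = "probit", Hess = TRUE)
  if (is.null(fit$Hessian)) abort("Ordinal probit fit did not converge.")
  co <- c(fit$coefficients, fit$zeta)
  names(co) <- c(keep, paste0("threshold_", names(fit$zeta)))
  V <- vcov(fit)
  dimnames(V) <- list(names(co), names(co))
  new_fitness_fit(co, V, "ordinal_probit", fit$convergence == 0,
                  -fit$deviance / 2, length(y))
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf("# Fitness-model fit: %s, n = %d, logLik = %.2f%s\n",
              x$family, x$n, x$loglik,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a fitness-model fit
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.fitness_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  z <- x$coef / se
  tibble::tibble(
    term = names(x$coef), estimate = unname(x$coef), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' One-line summary of a fitness-model fit
#'
#' @param x A `fitness_fit`.
#' @param ... Unused.
#' @return One-row tibble `family`, `n`, `logLik`, `df`, `converged`.
#' @export
glance.fitness_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n, logLik = x$loglik,
    df = length(x$coef), converged = x$converged
  )
}
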