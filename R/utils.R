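# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. `seed = NULL` means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a root seed, staying inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483587) + 1L
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_year_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be an increasing pair of years c(first, last).", name))
  }
  as.integer(x)
}

# Format an empirical p for display: exact zeros become "< 1/n_sim".
#' Format an empirical tail probability for reporting
#'
#' Empirical p-values of exactly zero only mean "more extreme than every one of
#' the `n_sim` null values", so they are rendered as an inequality rather than
#' as 0.
#'
#' @param p Numeric vector of empirical tail probabilities.
#' @param n_sim Number of null replicates the probabilities were computed from.
#' @return Character vector, e.g. `"0.0194"` or `"< 0.0002"`.
#' @export
#' @examples
#' format_empirical_p(c(0.0194, 0), n_sim = 5000)
format_empirical_p <- function(p, n_sim) {
  ifelse(p == 0,
    paste0("< ", format(1 / n_sim, scientific = FALSE, trim = TRUE)),
    format(p, scientific = FALSE, trim = TRUE)
  )
}
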