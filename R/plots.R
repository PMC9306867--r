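#' Plot gene-drop trajectories
#'
#' One panel per haplotype: a sample of simulated (drift-only) trajectories in
#' grey with the observed standing-population frequency overlaid in red.
#'
#' @param object A `genedrop` object.
#' @param max_replicates Number of simulated trajectories to draw per panel
#'   (default 200; sampled deterministically as the first replicates).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genedrop <- function(object, max_replicates = 200, ...) {
  reps <- seq_len(min(object$config$n_sim, max_replicates))
  long <- tidy(object, replicates = reps)
  sim <- dplyr::filter(long, .data$replicate != "observed")
  obs <- dplyr::filter(long, .data$replicate == "observed")
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$year, y = .data$freq,
                                    group = .data$replicate)) +
    ggplot2::geom_line(colour = "grey55", alpha = 0.25, linewidth = 0.2,
                       na.rm = TRUE) +
    ggplot2::geom_line(data = obs, colour = "red", linewidth = 0.7,
                       na.rm = TRUE) +
    ggplot2::facet_wrap(~haplotype, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Haplotype frequency (standing population)") +
    ggplot2::theme_minimal()
}

#' Plot a gene-drop test
#'
#' As [autoplot.genedrop()], with each panel labelled by the haplotype's
#' classification against the drift null.
#'
#' @param object A `genedrop_test` object.
#' @inheritParams autoplot.genedrop
#' @return A ggplot object.
#' @export
autoplot.genedrop_test <- function(object, max_replicates = 200, ...) {
  lab <- setNames(
    sprintf("%s (%s)", object$result$haplotype, object$result$classification),
    object$result$haplotype
  )
  autoplot(object$drop, max_replicates = max_replicates) +
    ggplot2::facet_wrap(~haplotype, scales = "free_y",
                        labeller = ggplot2::as_labeller(lab))
}

#' Plot haplotype-versus-rest contrasts
#'
#' Point estimates with credible-interval bars; intervals excluding zero are
#' highlighted.
#'
#' @param contrasts Tibble from [haplotype_vs_rest_contrasts()].
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(x = .data$haplotype, y = .data$estimate,
                               colour = .data$flagged)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "Haplotype", y = "Effect vs mean of other haplotypes") +
    ggplot2::theme_minimal()
}
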