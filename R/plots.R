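# Minimal result figures: a caterpillar plot of per-taxon interaction
# slopes and a replicate-z histogram for the permutation test.

#' @export
autoplot.burden_fit <- function(object, ...) {
  eff <- extract_taxon_effects(object)
  fe <- object$fixed_effects
  b_int <- fe$estimate[fe$term == "sex[male]:color[brown]"]
  eff$taxon_id <- factor(eff$taxon_id, levels = eff$taxon_id)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$total_slope, y = .data$taxon_id)) +
    ggplot2::geom_vline(xintercept = b_int, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, color = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$total_slope - 1.96 * .data$cond_sd,
                                         xmax = .data$total_slope + 1.96 * .data$cond_sd),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sex[male]:color[brown] slope (fixed + taxon deviation)",
                  y = NULL,
                  title = "Per-taxon response to the sex-by-color interaction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  reps <- dplyr::filter(object$replicates, .data$converged)
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * abs(object$observed_z),
                        color = "red", linetype = "dashed") +
    ggplot2::labs(x = "replicate interaction z",
                  y = "count",
                  title = sprintf("Constrained permutation null (%s)",
                                  object$scheme$mode),
                  subtitle = sprintf("observed z = %.2f; proportion at least as extreme = %.3f",
                                     object$observed_z, object$extreme_proportion)) +
    ggplot2::theme_minimal()
}
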