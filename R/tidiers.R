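# broom-style methods for the package's fitted objects

#' @export
tidy.burden_fit <- function(x, effects = c("fixed", "ran_vals"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") return(x$fixed_effects)
  x$taxon_modes
}

#' @export
glance.burden_fit <- function(x, ...) {
  tibble(logLik = x$loglik, theta = x$theta, nobs = x$n_obs,
         n_fish = x$n_fish, n_taxa = x$n_taxa,
         converged = x$converged, boundary = x$boundary)
}

#' @export
tidy.condition_fit <- function(x, ...) x$fixed_effects

#' @export
glance.condition_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n_used, n_excluded = x$n_excluded,
         response = x$response, converged = x$converged)
}

#' @export
tidy.permutation_result <- function(x, ...) x$replicates

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_z = x$observed_z,
         extreme_proportion = x$extreme_proportion,
         observed_more_extreme = x$observed_more_extreme,
         n_replicates = nrow(x$replicates), n_failed = x$n_failed,
         mode = x$scheme$mode)
}

#' @export
tidy.permanova_table <- function(x, ...) as_tibble(x)
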