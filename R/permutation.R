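#' Constrained color-relabelling scheme
#'
#' Defines the two iterations of the constrained permutation test for the
#' sex-by-color interaction.  Under `males_only`, exactly `n_blue_males`
#' males are relabelled blue (the rest brown) and females keep their
#' observed colors; under `both_sexes`, `n_blue_females` females are
#' additionally relabelled blue (the rest brown).  Defaults mirror the
#' observed design: 4 blue males, 11 blue females, 500 replicates.
#'
#' @param mode `"males_only"` or `"both_sexes"`.
#' @param n_blue_males,n_blue_females Constraint counts.
#' @param n_replicates Number of relabelled replicates (>= 1).
#' @param seed Integer seed; each replicate uses a counter-based substream
#'   of it, so replicates are order-independent.
#' @return A `permutation_scheme` list.
#' @export
permutation_scheme <- function(mode = c("males_only", "both_sexes"),
                               n_blue_males = 4, n_blue_females = 11,
                               n_replicates = 500, seed = 1L) {
  mode <- match.arg(mode)
  check_scalar_count(n_blue_males, "n_blue_males")
  if (mode == "both_sexes") check_scalar_count(n_blue_females, "n_blue_females")
  check_scalar_count(n_replicates, "n_replicates")
  structure(list(mode = mode, n_blue_males = as.integer(n_blue_males),
                 n_blue_females = as.integer(n_blue_females),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "permutation_scheme")
}

#' Relabel host colors for one permutation replicate
#'
#' Draws a uniform random subset of males (and, under `both_sexes`, of
#' females) to label blue, holding the configured counts exactly.  The draw
#' is reproducible from `(scheme$seed, replicate_index)` alone, so
#' replicates may run in any order.
#'
#' @param hosts Host tibble.
#' @param scheme A [permutation_scheme()].
#' @param replicate_index Positive integer replicate counter.
#' @return `hosts` with the `color` column relabelled.
#' @export
permute_colors <- function(hosts, scheme, replicate_index) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  check_scalar_count(replicate_index, "replicate_index")
  males <- which(hosts$sex == "male")
  if (length(males) < scheme$n_blue_males)
    abort(sprintf("scheme needs %d males but only %d present",
                  scheme$n_blue_males, length(males)),
          class = "morphburden_scheme_error")
  females <- which(hosts$sex == "female")
  if (scheme$mode == "both_sexes" && length(females) < scheme$n_blue_females)
    abort(sprintf("scheme needs %d females but only %d present",
                  scheme$n_blue_females, length(females)),
          class = "morphburden_scheme_error")
  out <- as_tibble(hosts)
  with_seed(derive_seed(scheme$seed, 10L, replicate_index), {
    blue_m <- sample(males, scheme$n_blue_males)
    out$color[males] <- "brown"
    out$color[blue_m] <- "blue"
    if (scheme$mode == "both_sexes") {
      blue_f <- sample(females, scheme$n_blue_females)
      out$color[females] <- "brown"
      out$color[blue_f] <- "blue"
    }
  })
  out
}

#' Constrained permutation test for the sex-by-color interaction
#'
#' Fits the burden model to the observed data, then refits it to
#' `n_replicates` color-relabelled datasets (see [permute_colors()]) and
#' compares the observed interaction Wald z with the replicate
#' distribution.  Extremeness is two-sided with ties counted as extreme:
#' `extreme_proportion` is the fraction of converged replicates with
#' `|z_rep| >= |z_obs|`, where z values agreeing to 1e-4 count as tied
#' (refits of permutation-equivalent data stop within optimizer noise of
#' one another).  The complementary proportion (observed strictly
#' more extreme than the replicate) is also reported.  Replicates whose fit
#' fails to converge are excluded from the denominator and counted.
#'
#' @param hosts,counts Data tables as for [fit_burden_model()].
#' @param design A [burden_design()]; must include the `sex:color` term.
#' @param scheme A [permutation_scheme()].
#' @param control A [burden_control()]; replicate fits are warm-started
#'   from the observed fit.
#' @param add_one Apply the (extreme + 1) / (n + 1) correction guaranteeing
#'   a positive proportion?  Off by default (plain proportion).
#' @return A `permutation_result`: `observed_z`, `replicates` tibble
#'   (replicate, z, converged), `extreme_proportion`,
#'   `observed_more_extreme`, `n_failed`, `scheme`.
#' @export
run_permutation_test <- function(hosts, counts, design = burden_design(),
                                 scheme = permutation_scheme(),
                                 control = burden_control(),
                                 add_one = FALSE) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  if (!"sex:color" %in% design$fixed)
    abort("design must include the sex:color interaction",
          class = "morphburden_design_error")
  int_term <- "sex[male]:color[brown]"
  # observed and replicate z must be computed identically for the
  # extremeness comparison to be meaningful; the fast conditional SE is
  # used for both (the permutation reference distribution self-calibrates,
  # so only consistency matters, not the SE's absolute scale)
  control$se_method <- "conditional"
  prep <- prep_burden_data(hosts, counts, design)
  observed <- fit_burden_core(prep, control)
  if (!observed$converged)
    abort("observed-data fit did not converge; cannot calibrate against it",
          class = "morphburden_fit_error")
  obs_z <- observed$fixed_effects$z[observed$fixed_effects$term == int_term]
  if (!length(obs_z) || !is.finite(obs_z))
    abort("observed fit has no finite interaction z",
          class = "morphburden_fit_error")

  rep_control <- control
  rep_control$start <- observed$par
  reps <- purrr::map_dfr(seq_len(scheme$n_replicates), function(r) {
    h_r <- permute_colors(hosts, scheme, r)
    prep_r <- update_prep_colors(prep, h_r)
    fit_r <- tryCatch(suppressWarnings(fit_burden_core(prep_r, rep_control)),
                      error = function(e) NULL)
    if (is.null(fit_r)) return(tibble(replicate = r, z = NA_real_, converged = FALSE))
    z_r <- fit_r$fixed_effects$z[fit_r$fixed_effects$term == int_term]
    tibble(replicate = r, z = z_r,
           converged = fit_r$converged && is.finite(z_r))
  })

  ok <- reps$converged
  n_ok <- sum(ok)
  if (n_ok == 0)
    abort("no permutation replicate converged", class = "morphburden_fit_error")
  # ties count as extreme; z values agreeing to 1e-4 are treated as tied so
  # that replicates whose refit differs from the observed fit only by
  # optimizer termination noise still register as ties
  n_extreme <- sum(abs(reps$z[ok]) >= abs(obs_z) - 1e-4)
  extreme <- if (add_one) (n_extreme + 1) / (n_ok + 1) else n_extreme / n_ok

  structure(list(observed_z = obs_z, replicates = reps,
                 extreme_proportion = extreme,
                 observed_more_extreme = sum(abs(reps$z[ok]) < abs(obs_z) - 1e-4) / n_ok,
                 n_failed = sum(!ok), scheme = scheme,
                 observed_fit = observed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> mode = %s, %d replicates (%d failed)\n",
              x$scheme$mode, nrow(x$replicates), x$n_failed))
  cat(sprintf("  observed interaction z = %.3f\n", x$observed_z))
  cat(sprintf("  proportion of replicates at least as extreme: %.4f\n",
              x$extreme_proportion))
  cat(sprintf("  proportion with observed strictly more extreme: %.4f\n",
              x$observed_more_extreme))
  invisible(x)
}
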