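#' Fulton's K condition factor
#'
#' Body condition as mass divided by the cube of length (the bare ratio; no
#' display multiplier is applied by default).  Heavier-for-length fish score
#' higher.
#'
#' @param total_mass Body mass (kg), > 0.
#' @param total_length Total length (cm), > 0.
#' @param multiplier Optional display multiplier (e.g. `1e5`); default 1.
#' @return `multiplier * total_mass / total_length^3` (kg/cm^3).
#' @examples
#' fultons_k(3.43, 70) # 1e-5
#' @export
fultons_k <- function(total_mass, total_length, multiplier = 1) {
  if (any(!is.finite(total_mass) | total_mass <= 0))
    abort("`total_mass` must be positive", class = "morphburden_domain_error")
  if (any(!is.finite(total_length) | total_length <= 0))
    abort("`total_length` must be positive", class = "morphburden_domain_error")
  multiplier * total_mass / total_length^3
}

#' Hepatosomatic index (HSI)
#'
#' Liver mass divided by body mass, a proxy for energy reserves; optionally
#' fourth-root transformed (the transform used to improve normality before
#' model fitting).
#'
#' @param liver_mass Liver mass (kg), >= 0 and < `body_mass`.
#' @param body_mass Body mass (kg), > 0.
#' @param transform Return the fourth root of the ratio?
#' @return The ratio (or its fourth root).
#' @examples
#' hepatosomatic_index(0.05, 1.0, transform = TRUE) # 0.05^0.25
#' @export
hepatosomatic_index <- function(liver_mass, body_mass, transform = FALSE) {
  if (any(!is.finite(body_mass) | body_mass <= 0))
    abort("`body_mass` must be positive", class = "morphburden_domain_error")
  if (any(!is.finite(liver_mass) | liver_mass < 0))
    abort("`liver_mass` must be non-negative", class = "morphburden_domain_error")
  if (any(liver_mass >= body_mass))
    abort("`liver_mass` must be smaller than `body_mass`",
          class = "morphburden_domain_error")
  hsi <- liver_mass / body_mass
  if (isTRUE(transform)) hsi^(1 / 4) else hsi
}

#' Flag implausible body-condition outliers
#'
#' Flags fish whose Fulton's K exceeds `max_k_fold` times the across-fish
#' median K — the signature of a mis-recorded body mass.  Records are
#' flagged, never silently dropped; each exclusion is logged with its
#' fish_id.
#'
#' @param hosts Host tibble with `fish_id`, `total_mass_kg`,
#'   `total_length_cm` (>= 2 rows, so the median is meaningful).
#' @param max_k_fold Multiplier of the median K above which a record is
#'   flagged.
#' @return `hosts` with a logical column `k_outlier`; the log lines are
#'   attached as attribute `"outlier_log"`.
#' @export
flag_condition_outliers <- function(hosts, max_k_fold = 10) {
  if (nrow(hosts) < 2)
    abort("outlier flagging needs at least 2 records",
          class = "morphburden_domain_error")
  k <- fultons_k(hosts$total_mass_kg, hosts$total_length_cm)
  med <- median(k)
  flag <- k > max_k_fold * med
  out <- dplyr::mutate(as_tibble(hosts), k_outlier = flag)
  log_lines <- sprintf("flagged %s: Fulton's K %.3g exceeds %g x median (%.3g)",
                       hosts$fish_id[flag], k[flag], max_k_fold, med)
  for (l in log_lines) inform(l)
  attr(out, "outlier_log") <- log_lines
  out
}

#' Fit a body-condition mixed model
#'
#' Post-hoc Gaussian linear mixed model for Fulton's K or the fourth-root
#' transformed hepatosomatic index: fixed effects depth (standardized with
#' [scale_plus_two()]), sex, color and their interaction (treatment
#' contrasts, reference female/blue), with random intercepts for sampling
#' location nested within sampling region, fitted by maximum likelihood
#' via [lme4::lmer()].  Wald z (estimate / SE) and two-sided normal p are
#' reported per fixed term.  Flagged K outliers (see
#' [flag_condition_outliers()]) are excluded with a logged count.
#'
#' @param hosts Host tibble; needs `liver_mass_kg` when
#'   `response = "hsi"`.
#' @param response `"fultons_k"` or `"hsi"` (fourth-root transformed).
#' @param nesting Random-intercept levels; `NULL` or `character(0)` fits
#'   ordinary least squares (all variance components fixed at zero).
#' @param exclude_outliers Apply [flag_condition_outliers()] first?
#' @param max_k_fold Outlier threshold passed through.
#' @return A `condition_fit` object: `fixed_effects` tibble (term,
#'   estimate, se, z, p on the analysis scale), `variance_components`,
#'   `loglik`, `converged`, `n_used`, `n_excluded`, `scaling`, `response`.
#' @export
fit_condition_model <- function(hosts,
                                response = c("fultons_k", "hsi"),
                                nesting = c("region", "location"),
                                exclude_outliers = TRUE,
                                max_k_fold = 10) {
  response <- match.arg(response)
  hosts <- validate_hosts(hosts)
  if (response == "hsi" && !"liver_mass_kg" %in% names(hosts))
    abort("host table is missing column(s): liver_mass_kg",
          class = "morphburden_schema_error")
  n_excluded <- 0L
  if (exclude_outliers && nrow(hosts) >= 2) {
    flagged <- flag_condition_outliers(hosts, max_k_fold)
    n_excluded <- sum(flagged$k_outlier)
    if (n_excluded > 0)
      inform(sprintf("excluding %d condition outlier(s)", n_excluded))
    hosts <- dplyr::filter(flagged, !.data$k_outlier)
  }
  y <- switch(response,
              fultons_k = fultons_k(hosts$total_mass_kg, hosts$total_length_cm),
              hsi = hepatosomatic_index(hosts$liver_mass_kg, hosts$total_mass_kg,
                                        transform = TRUE))
  depth_s <- scale_plus_two(hosts$depth_m)
  df <- tibble(y = y,
               depth = as.numeric(depth_s),
               sex = factor(hosts$sex, levels = c("female", "male")),
               color = factor(hosts$color, levels = c("blue", "brown")),
               region = factor(hosts$region),
               location = factor(paste(hosts$region, hosts$location, sep = ":")))
  if (nlevels(droplevels(df$sex)) < 2 || nlevels(droplevels(df$color)) < 2)
    abort("need at least 2 observed levels of sex and color",
          class = "morphburden_design_error")

  nesting <- nesting %||% character(0)
  term_names <- c("(Intercept)", "depth", "sex[male]", "color[brown]",
                  "sex[male]:color[brown]")
  if (length(nesting) == 0) {
    fit <- lm(y ~ depth + sex * color, data = df)
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(logLik(fit))
    vc <- tibble(component = character(), sd = numeric())
    conv <- TRUE
  } else {
    re <- if (setequal(nesting, c("region", "location"))) {
      "(1 | region) + (1 | location)"  # location coded within region
    } else if (identical(nesting, "region")) {
      "(1 | region)"
    } else {
      "(1 | location)"
    }
    form <- stats::as.formula(paste("y ~ depth + sex * color +", re))
    fit <- lme4::lmer(form, data = df, REML = FALSE)
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    ll <- as.numeric(logLik(fit))
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    vc <- tibble(component = vcdf$grp, sd = vcdf$sdcor)
    msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
    # a singular (zero-variance) fit is a boundary estimate, not a failure
    conv <- length(setdiff(msgs, grep("boundary", msgs, value = TRUE))) == 0
  }
  z <- est / se
  fixed <- tibble(term = term_names[seq_along(est)], estimate = unname(est),
                  se = unname(se), z = unname(z),
                  p = 2 * pnorm(-abs(unname(z))))

  structure(list(fixed_effects = fixed, variance_components = vc,
                 loglik = ll, converged = conv,
                 n_used = nrow(df), n_excluded = n_excluded,
                 scaling = list(depth_center = attr(depth_s, "center"),
                                depth_scale = attr(depth_s, "scale")),
                 response = response),
            class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat(sprintf("<condition_fit> response = %s, n = %d (%d outlier(s) excluded)\n",
              x$response, x$n_used, x$n_excluded))
  cat(sprintf("  ML logLik = %.3f, converged: %s\n", x$loglik, x$converged))
  print(as.data.frame(x$fixed_effects), digits = 4, row.names = FALSE)
  invisible(x)
}
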