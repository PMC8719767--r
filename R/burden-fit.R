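#' Negative-binomial (NB2) log probability mass
#'
#' Log-mass of the NB2 distribution with mean `mu` and dispersion `theta`
#' (variance `mu + mu^2 / theta`), written in a form stable for large
#' `theta`, where it tends to the Poisson log-mass.
#'
#' @param count Non-negative integer vector.
#' @param mu Mean(s), >= 0.
#' @param theta Dispersion, > 0.
#' @return Log-probabilities, recycled to common length.
#' @examples
#' nb_log_pmf(0, 1, 1) # log(1/2)
#' @export
nb_log_pmf <- function(count, mu, theta) {
  if (any(!is.finite(count) | count < 0 | count != floor(count)))
    abort("`count` must contain non-negative integers",
          class = "morphburden_domain_error")
  if (any(!is.finite(mu) | mu < 0))
    abort("`mu` must be non-negative", class = "morphburden_domain_error")
  if (any(!is.finite(theta) | theta <= 0))
    abort("`theta` must be positive", class = "morphburden_domain_error")
  n <- max(length(count), length(mu), length(theta))
  count <- rep_len(count, n); mu <- rep_len(mu, n); theta <- rep_len(theta, n)
  out <- ifelse(mu == 0, ifelse(count == 0, 0, -Inf),
                lgamma(count + theta) - lgamma(theta) - lgamma(count + 1) +
                  count * (log(mu) - log(theta + mu)) -
                  theta * log1p(mu / theta))
  out
}

#' Wald z statistic
#'
#' @param estimate Point estimate.
#' @param se Standard error, > 0.
#' @return `estimate / se`.
#' @export
wald_z <- function(estimate, se) {
  if (any(!is.finite(se) | se <= 0))
    abort("`se` must be positive", class = "morphburden_domain_error")
  estimate / se
}

#' Variance inflation factors for a fixed-effect design matrix
#'
#' For each column (the intercept, if present, is used only as a regressor),
#' regresses it on all other columns and reports `1 / (1 - R^2)`.  Exact
#' linear dependence is reported as `Inf`.  Values above `threshold` raise a
#' warning, never an error.
#'
#' @param X Numeric design matrix with column names.
#' @param threshold Warning threshold (conventionally 5).
#' @return Named numeric vector of VIFs (intercept excluded).
#' @export
compute_vif <- function(X, threshold = 5) {
  X <- as.matrix(X)
  keep <- colnames(X) != "(Intercept)"
  terms <- colnames(X)[keep]
  if (length(terms) < 2) return(setNames(rep(1, length(terms)), terms))
  vifs <- vapply(terms, function(tm) {
    yj <- X[, tm]
    others <- X[, colnames(X) != tm, drop = FALSE]
    fit <- lm.fit(cbind(`(Intercept)` = 1, others), yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  high <- vifs > threshold
  if (any(high))
    warn(paste0("variance inflation factor above ", threshold, " for: ",
                paste(names(vifs)[high], collapse = ", ")))
  vifs
}

# ---- outer parameter packing -------------------------------------------

par_template <- function(p, s, d) {
  list(p = p, s = s, d = d, n_lower = d * (d - 1L) / 2L,
       length = p + 1L + s + d + d * (d - 1L) / 2L)
}

unpack_par <- function(par, tpl) {
  i <- 0L
  beta <- par[seq_len(tpl$p)]; i <- tpl$p
  theta <- exp(par[i + 1L]); i <- i + 1L
  lambda <- exp(par[i + seq_len(tpl$s)]); i <- i + tpl$s
  Lt <- matrix(0, max(tpl$d, 1), max(tpl$d, 1))
  if (tpl$d > 0) {
    Lt <- matrix(0, tpl$d, tpl$d)
    diag(Lt) <- exp(par[i + seq_len(tpl$d)]); i <- i + tpl$d
    if (tpl$n_lower > 0) {
      Lt[lower.tri(Lt)] <- par[i + seq_len(tpl$n_lower)]
    }
  }
  list(beta = beta, theta = theta, lambda = as.numeric(lambda), Lt = Lt)
}

par_bounds <- function(tpl) {
  lower <- c(rep(-30, tpl$p), -5, rep(-7, tpl$s), rep(-7, tpl$d),
             rep(-5, tpl$n_lower))
  upper <- c(rep(30, tpl$p), 16, rep(3, tpl$s), rep(3, tpl$d),
             rep(5, tpl$n_lower))
  list(lower = lower, upper = upper)
}

#' Fit the parasite-burden negative-binomial mixed model
#'
#' Maximizes the Laplace-approximated marginal likelihood of the NB2 mixed
#' model over the fixed effects, the dispersion `theta` and all variance
#' parameters (optimized on the log scale).  The inner problem — the joint
#' mode of the nested host intercepts and the correlated taxon-level
#' effects — is solved by damped Newton iterations; the outer problem by
#' bounded quasi-Newton ([stats::nlminb()]).  Wald z statistics and
#' two-sided normal p values are reported per fixed term.
#'
#' Variance inflation factors of the fixed-effect matrix are checked before
#' fitting; values above 5 warn but never abort.  Non-convergence is flagged
#' in the result, with parameters still reported.
#'
#' @param hosts Host tibble (one row per fish; see [read_host_table()] for
#'   the column contract).
#' @param counts Long count tibble (`fish_id`, `taxon_id`, `count`); absent
#'   pairs are completed as structural zeros.
#' @param design A [burden_design()].
#' @param control A [burden_control()].
#' @return A `burden_fit` object with elements `fixed_effects` (tibble:
#'   term, estimate, se, z, p on the analysis scale), `theta`,
#'   `variance_components`, `taxon_cov`, `taxon_modes` (conditional modes
#'   and conditional SDs per taxon term), `loglik`, `converged`,
#'   `boundary`, `vif`, `scaling`, and the outer parameter vector `par`
#'   reusable as a warm start.
#' @examples
#' sim <- generate_dataset(generator_config(n_regions = 2, sites_per_region = 2,
#'                                          fish_per_site = 4, n_taxa = 3,
#'                                          seed = 7))
#' fit <- fit_burden_model(sim$hosts, sim$counts,
#'                         design = burden_design(taxon_structure = "reduced"))
#' tidy(fit)
#' @export
fit_burden_model <- function(hosts, counts, design = burden_design(),
                             control = burden_control()) {
  prep <- prep_burden_data(hosts, counts, design)
  fit_burden_core(prep, control)
}

# Fitting engine on an already-prepared dataset; the permutation test calls
# this directly with color-updated copies of one shared preparation.
fit_burden_core <- function(prep, control = burden_control()) {
  dat <- prep$dat
  p <- ncol(dat$X); s <- length(prep$scalar_blocks); d <- dat$d
  tpl <- par_template(p, s, d)

  vif <- compute_vif(dat$X)

  start <- c(log(mean(dat$y) + 0.1) - mean(dat$offset), rep(0, p - 1),
             0, rep(log(0.3), s), rep(log(0.3), d), rep(0, tpl$n_lower))
  user_start <- control$start
  if (inherits(user_start, "burden_fit")) user_start <- user_start$par
  if (is.numeric(user_start) && length(user_start) == tpl$length)
    start <- user_start

  bounds <- par_bounds(tpl)
  ctx <- nbglmm_make_ctx(dat, p, s, d)
  objective <- function(par) {
    nbglmm_ctx_nll(ctx, par, control$inner_tol, control$max_inner)
  }

  opt <- nlminb(start, objective, lower = bounds$lower, upper = bounds$upper,
                control = list(rel.tol = control$outer_tol,
                               iter.max = control$max_outer,
                               eval.max = 20L * control$max_outer))
  par_hat <- opt$par
  th <- unpack_par(par_hat, tpl)
  final <- nbglmm_eval_cpp(th$beta, th$theta, th$lambda, th$Lt, dat,
                           nbglmm_ctx_v(ctx),
                           control$inner_tol, control$max_inner, TRUE)

  v_hat <- as.numeric(final$v)
  converged <- opt$convergence == 0 && isTRUE(final$converged) &&
    is.finite(final$nll)
  boundary <- any(par_hat[p + 1 + seq_len(s + d)] <= -6.9)
  if (boundary)
    warn("one or more variance parameters were fitted at the zero boundary")

  se <- rep(NA_real_, p)
  if (control$compute_se && p > 0) {
    se <- tryCatch(fd_beta_se(par_hat, objective_beta = objective, tpl = tpl,
                              bounds = bounds, method = control$se_method),
                   error = function(e) rep(NA_real_, p))
  }
  est <- th$beta
  z <- ifelse(is.finite(se) & se > 0, est / se, NA_real_)
  fixed <- tibble(term = colnames(dat$X), estimate = est, se = se,
                  z = z, p = 2 * pnorm(-abs(z)))

  vc <- tibble(component = prep$scalar_blocks, sd = th$lambda)
  taxon_cov <- NULL
  taxon_modes <- tibble(taxon_id = character(), term = character(),
                        mode = numeric(), cond_sd = numeric())
  if (d > 0) {
    Lt <- th$Lt
    taxon_cov <- Lt %*% t(Lt)
    dimnames(taxon_cov) <- list(prep$taxon_terms, prep$taxon_terms)
    n_taxa <- dat$n_taxa
    c0 <- dat$q - n_taxa * d
    blocks <- final$taxon_vcov_blocks
    modes <- purrr::map_dfr(seq_len(n_taxa), function(t) {
      vt <- v_hat[c0 + (t - 1L) * d + seq_len(d)]
      ut <- as.numeric(Lt %*% vt)
      Bt <- Lt %*% blocks[, , t] %*% t(Lt)
      tibble(taxon_id = prep$taxon_levels[t], term = prep$taxon_terms,
             mode = ut, cond_sd = sqrt(pmax(diag(Bt), 0)))
    })
    taxon_modes <- modes
    vc <- dplyr::bind_rows(vc,
                           tibble(component = paste0("taxon:", prep$taxon_terms),
                                  sd = sqrt(diag(taxon_cov))))
  }

  structure(
    list(fixed_effects = fixed, theta = th$theta,
         variance_components = vc, taxon_cov = taxon_cov,
         taxon_modes = taxon_modes, loglik = -final$nll,
         converged = converged, boundary = boundary,
         opt_message = opt$message, vif = vif,
         scaling = prep$scaling, par = par_hat,
         n_obs = prep$n_obs, n_fish = prep$n_fish,
         n_taxa = dat$n_taxa, design = prep$design),
    class = "burden_fit")
}

# Wald standard errors from finite-difference curvature of the Laplace
# objective at the optimum.  "full" differentiates over the fixed effects
# plus every interior variance parameter (theta, SDs, covariance factor) and
# takes the fixed-effect block of the inverse — parameters sitting at a box
# bound are held fixed, since curvature is one-sided there.  "conditional"
# differentiates over the fixed effects only (faster; SEs conditional on the
# estimated variance parameters, mildly anti-conservative).
fd_beta_se <- function(par_hat, objective_beta, tpl, bounds = NULL,
                       method = c("full", "conditional")) {
  method <- match.arg(method)
  p <- tpl$p
  idx <- seq_len(p)
  if (method == "full") {
    interior <- seq_along(par_hat)
    if (!is.null(bounds)) {
      at_bound <- par_hat <= bounds$lower + 1e-6 | par_hat >= bounds$upper - 1e-6
      interior <- which(!at_bound | seq_along(par_hat) <= p)
    }
    idx <- union(seq_len(p), interior)
  }
  m <- length(idx)
  h <- 1e-4 * pmax(abs(par_hat[idx]), 1)
  H <- matrix(NA_real_, m, m)
  f0 <- objective_beta(par_hat)
  for (a in seq_len(m)) {
    ei <- replace(numeric(length(par_hat)), idx[a], h[a])
    H[a, a] <- (objective_beta(par_hat + ei) + objective_beta(par_hat - ei) -
                  2 * f0) / h[a]^2
  }
  if (m > 1) {
    for (a in seq_len(m - 1)) {
      for (b in seq((a + 1), m)) {
        ei <- replace(numeric(length(par_hat)), idx[a], h[a])
        ej <- replace(numeric(length(par_hat)), idx[b], h[b])
        H[a, b] <- H[b, a] <-
          (objective_beta(par_hat + ei + ej) - objective_beta(par_hat + ei - ej) -
             objective_beta(par_hat - ei + ej) + objective_beta(par_hat - ei - ej)) /
          (4 * h[a] * h[b])
      }
    }
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if ((is.null(V) || any(diag(V)[seq_len(p)] <= 0)) && method == "full") {
    # fall back to the conditional curvature if the full Hessian is not
    # usable (e.g. a flat variance direction)
    return(fd_beta_se(par_hat, objective_beta, tpl, bounds, "conditional"))
  }
  if (is.null(V)) return(rep(NA_real_, p))
  sqrt(pmax(diag(V)[seq_len(p)], 0))
}

#' Evaluate the Laplace-approximated NB mixed-model log-likelihood
#'
#' Low-level entry point for checking the Laplace approximation itself:
#' evaluates the marginal log-likelihood of an NB2 model with scalar
#' random-intercept blocks at fixed parameter values (no optimization).
#'
#' @param y Count vector.
#' @param X Fixed-effect design matrix (default intercept only).
#' @param offset Offset vector (default zero).
#' @param groups Data frame (or list) of factors, one scalar
#'   random-intercept block per column.
#' @param beta Fixed-effect values, one per column of `X`.
#' @param theta NB2 dispersion.
#' @param re_sd Random-intercept standard deviations, one per group block.
#' @param inner_tol Inner-mode gradient tolerance.
#' @return The Laplace marginal log-likelihood; conditional modes on the
#'   data scale are attached as attribute `"modes"`.
#' @export
laplace_loglik <- function(y, X = NULL, offset = NULL, groups = NULL,
                           beta, theta, re_sd = NULL, inner_tol = 1e-10) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (length(beta) != ncol(X))
    abort("`beta` must have one value per column of `X`",
          class = "morphburden_domain_error")
  if (is.null(offset)) offset <- rep(0, n)
  groups <- lapply(as.list(groups %||% list()), factor)
  s <- length(groups)
  if (length(re_sd %||% numeric(0)) != s)
    abort("`re_sd` must have one value per grouping factor",
          class = "morphburden_domain_error")
  k <- max(s, 1L)
  Zi <- matrix(-2L, n, k); Zv <- matrix(0, n, k); Zl <- matrix(-2L, n, k)
  col0 <- 0L
  for (b in seq_len(s)) {
    f <- groups[[b]]
    Zi[, b] <- col0 + as.integer(f) - 1L
    Zv[, b] <- 1
    Zl[, b] <- b - 1L
    col0 <- col0 + nlevels(f)
  }
  dat <- list(y = as.numeric(y), X = X, offset = as.numeric(offset),
              Zi = Zi, Zv = Zv, Zl = Zl, d = 0L, q = as.integer(col0),
              n_taxa = 0L)
  res <- nbglmm_eval_cpp(as.numeric(beta), theta, as.numeric(re_sd %||% numeric(0)),
                         matrix(0, 1, 1), dat, numeric(0), inner_tol, 100L, FALSE)
  out <- -res$nll
  if (s > 0) {
    u <- as.numeric(res$v)
    sds <- rep(as.numeric(re_sd), vapply(groups, nlevels, integer(1)))
    attr(out, "modes") <- u * sds
  }
  attr(out, "converged") <- res$converged
  out
}

#' Model-implied blue-to-brown burden ratio
#'
#' Converts the fitted color and sex-by-color coefficients (treatment
#' contrasts, reference female/blue) to the multiplicative factor by which a
#' blue fish's expected per-taxon burden exceeds a brown fish's, within one
#' sex: `exp(-(color[brown] + interaction))` for males,
#' `exp(-color[brown])` for females.  Values above 1 mean blue carries more.
#'
#' @param fit A `burden_fit`, or any data frame with `term` and `estimate`
#'   columns holding `color[brown]` and the `sex:color` interaction.
#' @param sex `"male"` or `"female"`.
#' @return The burden ratio (scalar).
#' @examples
#' tab <- tibble::tibble(term = c("color[brown]", "sex[male]:color[brown]"),
#'                       estimate = c(0.07987, -0.71694))
#' blue_to_brown_ratio(tab, "male") # about 1.89
#' @export
blue_to_brown_ratio <- function(fit, sex = c("male", "female")) {
  sex <- match.arg(sex)
  tab <- if (inherits(fit, "burden_fit")) fit$fixed_effects else as_tibble(fit)
  if (!all(c("term", "estimate") %in% names(tab)))
    abort("`fit` must provide `term` and `estimate`",
          class = "morphburden_spec_error")
  grab <- function(pattern) {
    hit <- grepl(pattern, tab$term)
    if (!any(hit))
      abort(paste0("no term matching ", pattern, " in the fit"),
            class = "morphburden_spec_error")
    tab$estimate[which(hit)[1]]
  }
  b_color <- grab("^color\\[brown\\]$|^colorbrown$")
  if (sex == "female") return(exp(-b_color))
  b_int <- grab(":color\\[brown\\]$|^sex\\[male\\]\\*color\\[brown\\]$|sexmale:colorbrown")
  exp(-(b_color + b_int))
}

#' Per-taxon interaction slopes from a burden fit
#'
#' Extracts the conditional mode (BLUP-like) of each taxon's sex-by-color
#' interaction deviation, its conditional SD, and the total slope (fixed
#' interaction + taxon deviation), ordered by total slope for a caterpillar
#' plot.
#'
#' @param fit A `burden_fit` with a taxon random term.
#' @return Tibble: `taxon_id`, `deviation`, `cond_sd`, `total_slope`,
#'   ordered ascending by `total_slope`; attribute `"degenerate"` is `TRUE`
#'   when the taxon interaction variance was fitted at zero (all deviations
#'   exactly 0).
#' @export
extract_taxon_effects <- function(fit) {
  stopifnot(inherits(fit, "burden_fit"))
  if (nrow(fit$taxon_modes) == 0)
    abort("fit has no taxon random term", class = "morphburden_spec_error")
  int_term <- "sex[male]:color[brown]"
  modes <- dplyr::filter(fit$taxon_modes, .data$term == int_term)
  if (nrow(modes) == 0)
    abort("taxon structure lacks an interaction component",
          class = "morphburden_spec_error")
  fe <- fit$fixed_effects
  b_int <- fe$estimate[fe$term == int_term]
  if (length(b_int) == 0) b_int <- 0
  degenerate <- sqrt(fit$taxon_cov[int_term, int_term]) < 5e-3
  if (degenerate) {
    warn("taxon interaction variance fitted at zero; all deviations are 0")
    modes$mode <- 0
  }
  out <- tibble(taxon_id = modes$taxon_id, deviation = modes$mode,
                cond_sd = modes$cond_sd,
                total_slope = b_int + modes$mode)
  out <- dplyr::arrange(out, .data$total_slope)
  attr(out, "degenerate") <- degenerate
  out
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit> NB2 mixed model, Laplace approximation\n")
  cat(sprintf("  n = %d observations (%d fish x %d taxa), logLik = %.3f, theta = %.3f\n",
              x$n_obs, x$n_fish, max(x$n_taxa, 1), x$loglik, x$theta))
  cat(sprintf("  converged: %s%s\n", x$converged,
              if (x$boundary) " (variance at boundary)" else ""))
  print(as.data.frame(x$fixed_effects), digits = 5, row.names = FALSE)
  invisible(x)
}
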