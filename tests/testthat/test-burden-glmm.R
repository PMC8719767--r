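test_that("NB2 log-pmf matches dnbinom and its stated limits", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  expect_equal(nb_log_pmf(0, 0, 5), 0)
  expect_equal(nb_log_pmf(3, 2, 1e8), dpois(3, 2, log = TRUE), tolerance = 1e-4)
  expect_equal(nb_log_pmf(3, 2, 1e8), -1.712402, tolerance = 1e-4)
  # dnbinom as the independent oracle over a grid
  for (y in c(0, 1, 7)) {
    for (mu in c(0.3, 2, 15)) {
      for (th in c(0.4, 1, 9)) {
        expect_equal(nb_log_pmf(y, mu, th),
                     dnbinom(y, size = th, mu = mu, log = TRUE),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(nb_log_pmf(-1, 1, 1), class = "morphburden_domain_error")
  expect_error(nb_log_pmf(1, 1, 0), class = "morphburden_domain_error")
})

test_that("wald_z reproduces printed-table z values at printed precision", {
  expect_equal(round(wald_z(0.94182, 0.17238), 3), 5.464)
  expect_equal(round(wald_z(-0.71694, 0.17404), 3), -4.119)
  expect_equal(wald_z(0, 0.5), 0)
  expect_error(wald_z(1, 0), class = "morphburden_domain_error")
})

test_that("VIF identifies orthogonality, near-collinearity and exact dependence", {
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  expect_equal(unname(compute_vif(X)), c(1, 1, 1))
  # exact correlation 0.9 between two standardized columns
  u <- as.numeric(scale(c(1, 5, 2, 8, 4, 7, 3, 6)))
  w <- withr::with_seed(4, rnorm(8))
  v <- as.numeric(scale(residuals(lm(w ~ u))))
  x2 <- 0.9 * u + sqrt(1 - 0.81) * v
  vifs <- suppressWarnings(compute_vif(cbind(a = u, b = x2)))
  expect_lt(max(abs(vifs - 1 / (1 - 0.81))), 0.01)
  expect_warning(out <- compute_vif(cbind(a = u, b = u)), "inflation")
  expect_true(all(is.infinite(out)))
})

test_that("blue_to_brown_ratio converts coefficients to burden ratios", {
  tab <- tibble::tibble(term = c("color[brown]", "sex[male]:color[brown]"),
                        estimate = c(0.07987, -0.71694))
  expect_equal(signif(blue_to_brown_ratio(tab, "male"), 3), 1.89)
  expect_equal(blue_to_brown_ratio(tab, "female"), exp(-0.07987))
  zero <- tibble::tibble(term = tab$term, estimate = c(0, 0))
  expect_equal(blue_to_brown_ratio(zero, "male"), 1)
  half <- tibble::tibble(term = tab$term, estimate = c(log(2), 0))
  expect_equal(blue_to_brown_ratio(half, "male"), 0.5)
  expect_error(blue_to_brown_ratio(tibble::tibble(term = "depth", estimate = 1),
                                   "male"),
               class = "morphburden_spec_error")
})

test_that("with no random effects or covariates the NB MLE mean is the sample mean", {
  hosts <- tibble::tibble(fish_id = c("F1", "F2", "F3"), region = "R1",
                          location = "S1", depth_m = 10,
                          sex = c("male", "female", "male"),
                          color = c("blue", "brown", "brown"),
                          total_length_cm = 1, total_mass_kg = 1,
                          liver_mass_kg = 0.01)
  counts <- tibble::tibble(fish_id = c("F1", "F2", "F3"), taxon_id = "T01",
                           count = c(2, 4, 6))
  design <- burden_design(fixed = character(0), nesting = character(0),
                          taxon_structure = "none", use_offset = FALSE)
  fit <- fit_burden_model(hosts, counts, design)
  expect_equal(fit$fixed_effects$estimate[1], log(4), tolerance = 1e-4)
})

test_that("Laplace log-likelihood matches the adaptive quadrature oracle on the toy", {
  toy <- read.csv(system.file("extdata", "toy_counts_1re.csv",
                              package = "morphburden"))
  pts <- list(c(beta = 0.8, theta = 1.5, sd = 0.6),
              c(beta = 1.0, theta = 5.0, sd = 0.3),
              c(beta = 0.86, theta = 50, sd = 0.64))
  for (p in pts) {
    la <- as.numeric(laplace_loglik(toy$count, groups = list(g = toy$group),
                                    beta = p["beta"], theta = p["theta"],
                                    re_sd = p["sd"]))
    aq <- agq_nb_loglik(toy$count, toy$group, p["beta"], p["theta"], p["sd"])
    expect_lt(abs(la - aq) / abs(aq), 1e-3)
  }
})

test_that("the full fit agrees with glmmTMB on a moderate synthetic dataset", {
  skip_if_not_installed("glmmTMB")
  sim <- generate_dataset(generator_config(
    n_regions = 2, sites_per_region = 3, fish_per_site = 6, n_taxa = 4,
    taxon_cov = diag(c(0.8, 0.2, 0.2, 0.4)^2), seed = 17,
    cell_probabilities = c(brown_male = 0.4, blue_male = 0.2,
                           brown_female = 0.2, blue_female = 0.2)))
  fit <- suppressWarnings(
    fit_burden_model(sim$hosts, sim$counts,
                     burden_design(nesting = "fish", taxon_structure = "reduced")))
  d <- dplyr::left_join(sim$counts, sim$hosts, by = "fish_id")
  d$male <- as.numeric(d$sex == "male")
  d$brown <- as.numeric(d$color == "brown")
  d$mb <- d$male * d$brown
  hd <- scale_plus_two(sim$hosts$depth_m)
  d$depth_s <- setNames(as.numeric(hd), sim$hosts$fish_id)[d$fish_id]
  g <- suppressWarnings(glmmTMB::glmmTMB(
    count ~ depth_s + male + brown + mb + (1 | fish_id) + (1 + mb | taxon_id) +
      offset(log(total_length_cm)),
    family = glmmTMB::nbinom2, data = d))
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
  co <- glmmTMB::fixef(g)$cond
  expect_lt(max(abs(fit$fixed_effects$estimate - unname(co))), 0.03)
  expect_lt(abs(fit$theta - glmmTMB::sigma(g)), 0.05)
})

test_that("adding a constant to the offset shifts only the intercept", {
  sim <- generate_dataset(generator_config(
    n_regions = 1, sites_per_region = 3, fish_per_site = 6, n_taxa = 3,
    taxon_cov = diag(c(0.5, 0, 0, 0.3)^2), seed = 23,
    cell_probabilities = c(brown_male = 0.4, blue_male = 0.2,
                           brown_female = 0.2, blue_female = 0.2)))
  des <- burden_design(nesting = "fish", taxon_structure = "reduced")
  ctl <- burden_control(outer_tol = 1e-8)
  fit1 <- suppressWarnings(fit_burden_model(sim$hosts, sim$counts, des, ctl))
  hosts2 <- sim$hosts
  hosts2$total_length_cm <- hosts2$total_length_cm * exp(0.7)  # offset + 0.7
  fit2 <- suppressWarnings(fit_burden_model(hosts2, sim$counts, des, ctl))
  e1 <- fit1$fixed_effects$estimate
  e2 <- fit2$fixed_effects$estimate
  expect_equal(e2[1], e1[1] - 0.7, tolerance = 1e-3)
  expect_equal(e2[-1], e1[-1], tolerance = 1e-3)
})

test_that("reported Wald z equals estimate/SE and p is two-sided normal", {
  sim <- generate_dataset(generator_config(
    n_regions = 1, sites_per_region = 2, fish_per_site = 8, n_taxa = 3,
    taxon_cov = diag(c(0.5, 0, 0, 0.3)^2), seed = 29,
    cell_probabilities = c(brown_male = 0.4, blue_male = 0.2,
                           brown_female = 0.2, blue_female = 0.2)))
  fit <- suppressWarnings(
    fit_burden_model(sim$hosts, sim$counts, small_design(), small_control()))
  fe <- fit$fixed_effects
  expect_equal(fe$z, fe$estimate / fe$se)
  expect_equal(fe$p, 2 * pnorm(-abs(fe$z)))
})

test_that("under the null the Wald interaction test has near-nominal size", {
  # a regular regime — 240 fish with all four cells guaranteed, no
  # taxon-level heterogeneity, fitted model well specified — where the
  # normal reference behind the Wald test is expected to hold.  (In tiny,
  # extremely unbalanced designs the Wald test is anti-conservative; that
  # is the documented motivation for the permutation test, not a defect of
  # the Wald machinery.)
  des <- burden_design(fixed = c("sex", "color", "sex:color"),
                       nesting = "fish", taxon_structure = "none")
  rejections <- 0L
  n_done <- 0L
  i <- 0L
  while (n_done < 200L && i < 240L) {
    i <- i + 1L
    cfg <- generator_config(
      n_regions = 1, sites_per_region = 4, fish_per_site = 60, n_taxa = 3,
      beta_depth = 0, beta_sex_male = 0.5, beta_color_brown = 0,
      beta_interaction = 0, sd_region = 0, sd_site = 0, sd_fish = 0.4,
      taxon_cov = matrix(0, 4, 4), theta = 1,
      cell_probabilities = c(brown_male = 0.45, blue_male = 0.15,
                             brown_female = 0.25, blue_female = 0.15),
      cell_allocation = "proportional", seed = 40000 + i)
    sim <- generate_dataset(cfg)
    fit <- tryCatch(
      suppressWarnings(fit_burden_model(sim$hosts, sim$counts, des,
                                        burden_control(outer_tol = 1e-5))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    p <- fit$fixed_effects$p[fit$fixed_effects$term == "sex[male]:color[brown]"]
    if (!is.finite(p)) next
    n_done <- n_done + 1L
    rejections <- rejections + (p < 0.05)
  }
  expect_equal(n_done, 200L)
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("taxon effects: cardinality, ordering and recovery of strong signal", {
  sim <- generate_dataset(generator_config(
    n_regions = 1, sites_per_region = 4, fish_per_site = 125, n_taxa = 8,
    taxon_cov = diag(c(0.8, 0, 0, 0.5)^2), sd_region = 0, sd_site = 0,
    sd_fish = 0.3, seed = 31,
    cell_probabilities = c(brown_male = 0.35, blue_male = 0.2,
                           brown_female = 0.25, blue_female = 0.2)))
  fit <- suppressWarnings(fit_burden_model(
    sim$hosts, sim$counts,
    burden_design(nesting = "fish", taxon_structure = "reduced"),
    burden_control(outer_tol = 1e-5)))
  eff <- extract_taxon_effects(fit)
  expect_equal(nrow(eff), 8)
  expect_false(is.unsorted(eff$total_slope))
  truth <- sim$truth$taxon_effects[eff$taxon_id, "interaction"]
  expect_gt(cor(truth, eff$deviation), 0.5)
  # total slope decomposes as fixed effect + deviation
  b_int <- fit$fixed_effects$estimate[
    fit$fixed_effects$term == "sex[male]:color[brown]"]
  expect_equal(eff$total_slope, b_int + eff$deviation)
})

test_that("a taxon covariance at the zero boundary flags degenerate deviations", {
  fit <- structure(list(
    fixed_effects = tibble::tibble(
      term = c("(Intercept)", "sex[male]:color[brown]"),
      estimate = c(0.5, -0.2), se = c(0.1, 0.1), z = c(5, -2),
      p = c(0, 0.05)),
    taxon_cov = matrix(c(1e-8, 0, 0, 1e-8), 2, 2,
                       dimnames = rep(list(c("intercept",
                                             "sex[male]:color[brown]")), 2)),
    taxon_modes = tibble::tibble(
      taxon_id = rep(c("T01", "T02"), each = 2),
      term = rep(c("intercept", "sex[male]:color[brown]"), 2),
      mode = c(1e-6, -1e-6, 2e-6, 1e-6), cond_sd = rep(1e-4, 4))),
    class = "burden_fit")
  expect_warning(eff <- extract_taxon_effects(fit), "zero")
  expect_true(all(eff$deviation == 0))
  expect_true(attr(eff, "degenerate"))
})
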