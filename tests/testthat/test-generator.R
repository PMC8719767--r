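test_that("same config and seed give byte-identical datasets", {
  cfg <- generator_config(n_regions = 2, sites_per_region = 2, fish_per_site = 3,
                          n_taxa = 4, seed = 11)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
})

test_that("count table has exactly n_fish x n_taxa rows of non-negative integers", {
  cfg <- generator_config(n_regions = 2, sites_per_region = 2, fish_per_site = 5,
                          n_taxa = 3, seed = 3)
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$counts), 60)
  expect_true(all(sim$counts$count >= 0))
  expect_true(all(sim$counts$count == floor(sim$counts$count)))
  # nesting consistency: each fish maps to exactly one site, each site to one region
  expect_true(all(table(sim$hosts$fish_id, sim$hosts$location) <= 1))
  by_loc <- unique(sim$hosts[, c("region", "location")])
  expect_equal(anyDuplicated(by_loc$location), 0L)
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(generator_config(n_taxa = 0), "n_taxa")
  expect_error(generator_config(theta = -1), "theta")
  expect_error(generator_config(taxon_cov = matrix(1, 2, 2)), "taxon_cov")
  expect_error(generator_config(taxon_cov = matrix(-1, 4, 4)), "taxon_cov")
  expect_error(generator_config(cell_probabilities = c(a = 1, b = 0, c = 0, d = 0)),
               "cell_probabilities")
  expect_error(generator_config(length_range_cm = c(10, 5)), "length_range_cm")
})

test_that("Poisson limit: empirical mean matches exp(intercept) with unit lengths", {
  cfg <- generator_config(n_regions = 1, sites_per_region = 1, fish_per_site = 10000,
                          n_taxa = 1, beta_intercept = 1.2, beta_depth = 0,
                          beta_sex_male = 0, beta_color_brown = 0,
                          beta_interaction = 0, sd_region = 0, sd_site = 0,
                          sd_fish = 0, taxon_cov = matrix(0, 4, 4), theta = 1e8,
                          length_range_cm = c(1, 1), seed = 21)
  sim <- generate_dataset(cfg)
  mu <- exp(1.2)
  mc_se <- sqrt(mu / 1e4)  # Poisson-limit variance
  expect_lt(abs(mean(sim$counts$count) - mu), 3 * mc_se)
})

test_that("counts are overdispersed relative to Poisson at finite theta", {
  cfg <- generator_config(n_regions = 1, sites_per_region = 1, fish_per_site = 2000,
                          n_taxa = 1, beta_intercept = 0.5, beta_depth = 0,
                          beta_sex_male = 0, beta_color_brown = 0,
                          beta_interaction = 0, sd_region = 0, sd_site = 0,
                          sd_fish = 0, taxon_cov = matrix(0, 4, 4), theta = 2,
                          length_range_cm = c(1, 1), seed = 8)
  y <- generate_dataset(cfg)$counts$count
  expect_gt(var(y), mean(y))
})

test_that("with all random effects off, a pooled NB fit recovers the coefficients", {
  cfg <- generator_config(n_regions = 1, sites_per_region = 2, fish_per_site = 2500,
                          n_taxa = 2, beta_intercept = -1, beta_depth = -0.2,
                          beta_sex_male = 0.6, beta_color_brown = 0.1,
                          beta_interaction = -0.5, sd_region = 0, sd_site = 0,
                          sd_fish = 0, taxon_cov = matrix(0, 4, 4), theta = 1.5,
                          seed = 5)
  sim <- generate_dataset(cfg)
  d <- dplyr::left_join(sim$counts, sim$hosts, by = "fish_id")
  d$male <- as.numeric(d$sex == "male")
  d$brown <- as.numeric(d$color == "brown")
  d$depth_s <- as.numeric(scale(d$depth_m)) + 2
  fit <- MASS::glm.nb(count ~ depth_s + male + brown + male:brown +
                        offset(log(total_length_cm)), data = d)
  est <- coef(summary(fit))
  truth <- c(-1, -0.2, 0.6, 0.1, -0.5)
  expect_true(all(abs(est[, "Estimate"] - truth) < 3 * est[, "Std. Error"]))
})

test_that("sex-color cell frequencies follow the configured probabilities", {
  probs <- c(brown_male = 59, blue_male = 4, brown_female = 15,
             blue_female = 11) / 89
  ok <- 0L
  for (i in 1:100) {
    cfg <- generator_config(n_regions = 1, sites_per_region = 1,
                            fish_per_site = 500, n_taxa = 1, seed = 3000 + i)
    h <- generate_dataset(cfg)$hosts
    cell <- paste(h$color, h$sex, sep = "_")
    obs <- table(factor(cell, levels = names(probs)))
    p <- suppressWarnings(chisq.test(obs, p = probs)$p.value)
    ok <- ok + (p > 0.01)
  }
  expect_gte(ok, 95)
})

test_that("adding taxa does not perturb host covariates under a fixed seed", {
  cfg3 <- generator_config(n_regions = 2, sites_per_region = 2, fish_per_site = 3,
                           n_taxa = 3, seed = 13)
  cfg6 <- generator_config(n_regions = 2, sites_per_region = 2, fish_per_site = 3,
                           n_taxa = 6, seed = 13)
  sim3 <- generate_dataset(cfg3)
  sim6 <- generate_dataset(cfg6)
  expect_identical(sim3$hosts, sim6$hosts)
  # the first three taxa are also unchanged
  c3 <- dplyr::filter(sim6$counts, taxon_id %in% c("T01", "T02", "T03"))
  expect_identical(sim3$counts, c3)
})

test_that("write_dataset emits the contracted CSV columns", {
  dir <- withr::local_tempdir()
  sim <- generate_dataset(generator_config(n_regions = 1, sites_per_region = 2,
                                           fish_per_site = 2, n_taxa = 2))
  paths <- write_dataset(sim, dir)
  hosts <- readr::read_csv(paths[["hosts"]], show_col_types = FALSE)
  expect_named(hosts, c("fish_id", "region", "location", "depth_m", "sex",
                        "color", "total_length_cm", "total_mass_kg",
                        "liver_mass_kg"))
  counts <- readr::read_csv(paths[["counts"]], show_col_types = FALSE)
  expect_named(counts, c("fish_id", "taxon_id", "count"))
})
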