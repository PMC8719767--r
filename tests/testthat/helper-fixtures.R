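# Shared fixture builders (all data generated in code).

# Minimal valid host table with configurable cells.
make_hosts <- function(n_male_brown = 6, n_male_blue = 2,
                       n_female_brown = 3, n_female_blue = 3,
                       n_sites = 2, seed = 1) {
  n <- n_male_brown + n_male_blue + n_female_brown + n_female_blue
  withr::with_seed(seed, {
    sex <- c(rep("male", n_male_brown + n_male_blue),
             rep("female", n_female_brown + n_female_blue))
    color <- c(rep("brown", n_male_brown), rep("blue", n_male_blue),
               rep("brown", n_female_brown), rep("blue", n_female_blue))
    site <- rep_len(seq_len(n_sites), n)
    tibble::tibble(
      fish_id = sprintf("F%03d", seq_len(n)),
      region = "R1",
      location = sprintf("S%d", site),
      depth_m = 10 + 5 * site + runif(n, -1, 1),
      sex = sex, color = color,
      total_length_cm = runif(n, 50, 90),
      total_mass_kg = 1e-5 * runif(n, 50, 90)^3,
      liver_mass_kg = 0.02 * 1e-5 * runif(n, 50, 90)^3)
  })
}

# Complete count grid with NB draws under a flat mean.
make_counts <- function(hosts, n_taxa = 2, mu = 3, theta = 2, seed = 2) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(fish_id = hosts$fish_id,
                               taxon_id = sprintf("T%02d", seq_len(n_taxa)))
    grid$count <- rnbinom(nrow(grid), size = theta, mu = mu)
    grid
  })
}

# Generator configuration for small, fully identifiable null datasets used
# by the permutation-calibration checks: no color or interaction effect
# anywhere (fixed or taxon-level), fish-level heterogeneity only.
# Proportional cell allocation fixes the cells at 9/3/5/3 of 20 fish, so
# the interaction is identifiable in every draw.
null_calibration_config <- function(seed, fish_per_site = 5) {
  generator_config(
    n_regions = 1, sites_per_region = 4, fish_per_site = fish_per_site,
    n_taxa = 3,
    beta_intercept = -1.7, beta_depth = 0, beta_sex_male = 0.5,
    beta_color_brown = 0, beta_interaction = 0,
    sd_region = 0, sd_site = 0, sd_fish = 0.4,
    taxon_cov = diag(c(1, 0.2, 0, 0)^2), theta = 1,
    cell_probabilities = c(brown_male = 0.45, blue_male = 0.15,
                           brown_female = 0.25, blue_female = 0.15),
    cell_allocation = "proportional",
    seed = seed)
}

# Fast design/control for small refit-heavy checks.
small_design <- function() {
  burden_design(fixed = c("sex", "color", "sex:color"), nesting = "fish",
                taxon_structure = "reduced")
}
small_control <- function(...) burden_control(outer_tol = 1e-5, ...)

# A null-generated dataset is usable for the constrained permutation test
# only if the sex-color cells keep the interaction identifiable.
calibration_feasible <- function(hosts, n_blue_males = 4) {
  sum(hosts$sex == "male") >= n_blue_males &&
    sum(hosts$sex == "female" & hosts$color == "blue") >= 1 &&
    sum(hosts$sex == "female" & hosts$color == "brown") >= 1
}
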