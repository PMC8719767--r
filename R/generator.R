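#' Configuration for the synthetic host-parasite data generator
#'
#' Bundles every generative parameter of the burden model's data-generating
#' process: the sampling design (regions, sites within regions, fish within
#' sites, parasite taxa), the sex-color cell probabilities, the log-scale
#' fixed-effect coefficients, the nested random-intercept standard
#' deviations, the 4x4 covariance of taxon-level (intercept, sex, color,
#' interaction) deviations, the NB2 dispersion `theta`, and the covariate
#' generators (uniform lengths and depths, log-normal mass-length allometry,
#' log-normal hepatosomatic ratio).
#'
#' Defaults mirror the lingcod study design: 89 fish spread over 4 regions
#' and 28 sites, 25 parasite taxa, and sex-color cell probabilities
#' proportional to the observed 59 brown males, 4 blue males, 15 brown
#' females and 11 blue females.  The depth effect applies to depth
#' standardized with [scale_plus_two()], matching how the burden model codes
#' depth, so fitted coefficients are directly comparable to these truths.
#'
#' @param n_regions,sites_per_region,fish_per_site,n_taxa Design sizes
#'   (positive integers).
#' @param n_fish Total number of fish; defaults to
#'   `n_regions * sites_per_region * fish_per_site`.  Fish are allocated to
#'   sites round-robin, so unbalanced totals (e.g. 89 fish over 28 sites)
#'   give site occupancies differing by at most one.
#' @param cell_probabilities Named probabilities over the four sex-color
#'   cells (`brown_male`, `blue_male`, `brown_female`, `blue_female`);
#'   must sum to 1.
#' @param cell_allocation `"multinomial"` draws each fish's cell
#'   independently; `"proportional"` fixes the cell counts at the
#'   largest-remainder apportionment of `n_fish * cell_probabilities`
#'   (conditioning on the study's realized design, e.g. exactly 59/4/15/11
#'   at 89 fish) and randomizes only which fish falls in which cell.
#' @param beta_intercept,beta_depth,beta_sex_male,beta_color_brown,beta_interaction
#'   Log-scale fixed-effect coefficients (reference levels: female, blue).
#' @param sd_region,sd_site,sd_fish Standard deviations of the nested
#'   random intercepts (log scale); zero allowed.
#' @param taxon_cov 4x4 symmetric positive-semidefinite covariance of the
#'   per-taxon (intercept, sex, color, interaction) deviation vector.
#' @param theta NB2 dispersion (> 0); variance is `mu + mu^2 / theta`, so
#'   large `theta` approaches Poisson.
#' @param length_range_cm,depth_range_m Uniform ranges for fish total length
#'   and site collection depth.
#' @param mass_length_allometry List with elements `a`, `b`, `sdlog`: body
#'   mass (kg) is `a * length^b * exp(rnorm(1, 0, sdlog))`.
#' @param hsi_meanlog,hsi_sdlog Log-normal parameters of the liver-to-body
#'   mass ratio used to generate liver mass.
#' @param seed Integer master seed.
#' @return A `generator_config` object (validated list).
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_regions = 4,
                             sites_per_region = 7,
                             fish_per_site = 3,
                             n_fish = NULL,
                             n_taxa = 25,
                             cell_probabilities = c(brown_male = 59, blue_male = 4,
                                                    brown_female = 15, blue_female = 11) / 89,
                             cell_allocation = c("multinomial", "proportional"),
                             beta_intercept = -1.7,
                             beta_depth = -0.12,
                             beta_sex_male = 0.94,
                             beta_color_brown = 0.08,
                             beta_interaction = -0.717,
                             sd_region = 0.3,
                             sd_site = 0.3,
                             sd_fish = 0.5,
                             taxon_cov = diag(c(1, 0.3, 0.3, 0.5)^2),
                             theta = 1,
                             length_range_cm = c(45, 100),
                             depth_range_m = c(7.6, 72.2),
                             mass_length_allometry = list(a = 1e-5, b = 3, sdlog = 0.1),
                             hsi_meanlog = log(0.02),
                             hsi_sdlog = 0.3,
                             seed = 1L) {
  cell_allocation <- match.arg(cell_allocation)
  cfg <- list(n_regions = n_regions, sites_per_region = sites_per_region,
              fish_per_site = fish_per_site, n_fish = n_fish, n_taxa = n_taxa,
              cell_probabilities = cell_probabilities,
              cell_allocation = cell_allocation,
              beta_intercept = beta_intercept, beta_depth = beta_depth,
              beta_sex_male = beta_sex_male,
              beta_color_brown = beta_color_brown,
              beta_interaction = beta_interaction,
              sd_region = sd_region, sd_site = sd_site, sd_fish = sd_fish,
              taxon_cov = taxon_cov, theta = theta,
              length_range_cm = length_range_cm, depth_range_m = depth_range_m,
              mass_length_allometry = mass_length_allometry,
              hsi_meanlog = hsi_meanlog, hsi_sdlog = hsi_sdlog,
              seed = seed)
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param config A list with `generator_config` fields.
#' @export
validate_generator_config <- function(config) {
  check_scalar_count(config$n_regions, "n_regions")
  check_scalar_count(config$sites_per_region, "sites_per_region")
  check_scalar_count(config$fish_per_site, "fish_per_site")
  check_scalar_count(config$n_taxa, "n_taxa")
  if (is.null(config$n_fish))
    config$n_fish <- config$n_regions * config$sites_per_region * config$fish_per_site
  check_scalar_count(config$n_fish, "n_fish")
  p <- config$cell_probabilities
  cells <- c("brown_male", "blue_male", "brown_female", "blue_female")
  if (!is.numeric(p) || length(p) != 4 || is.null(names(p)) ||
      !setequal(names(p), cells))
    stop_field("cell_probabilities",
               "must be 4 named probabilities over brown_male, blue_male, brown_female, blue_female")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_field("cell_probabilities", "must be non-negative and sum to 1")
  config$cell_probabilities <- p[cells]
  if (is.null(config$cell_allocation)) config$cell_allocation <- "multinomial"
  if (!config$cell_allocation %in% c("multinomial", "proportional"))
    stop_field("cell_allocation", "must be 'multinomial' or 'proportional'")
  for (f in c("beta_intercept", "beta_depth", "beta_sex_male",
              "beta_color_brown", "beta_interaction")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 || !is.finite(config[[f]]))
      stop_field(f, "must be a single finite number")
  }
  for (f in c("sd_region", "sd_site", "sd_fish")) {
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 || config[[f]] < 0)
      stop_field(f, "must be a single non-negative number")
  }
  if (!is.matrix(config$taxon_cov) || !all(dim(config$taxon_cov) == c(4, 4)))
    stop_field("taxon_cov", "must be a 4x4 matrix")
  psd_factor(config$taxon_cov, "taxon_cov")
  check_scalar_pos(config$theta, "theta")
  for (f in c("length_range_cm", "depth_range_m")) {
    r <- config[[f]]
    if (!is.numeric(r) || length(r) != 2 || anyNA(r) || r[2] < r[1] || r[1] <= 0)
      stop_field(f, "must be a positive, non-decreasing range c(lo, hi)")
  }
  al <- config$mass_length_allometry
  if (!is.list(al) || !all(c("a", "b", "sdlog") %in% names(al)) ||
      al$a <= 0 || al$sdlog < 0)
    stop_field("mass_length_allometry", "must be list(a > 0, b, sdlog >= 0)")
  if (!is.numeric(config$seed) || length(config$seed) != 1 || is.na(config$seed))
    stop_field("seed", "must be a single integer")
  config$seed <- as.integer(config$seed)
  structure(config, class = "generator_config")
}

#' Simulate a host table and parasite count table
#'
#' Draws a complete synthetic dataset from the generative model the burden
#' GLMM assumes: nested region/site/fish random intercepts, correlated
#' taxon-level deviations of (intercept, sex, color, sex-by-color) response,
#' a log total-length offset, and NB2 counts.  Covariates (length, depth,
#' mass, liver mass) are drawn from the distributions configured in
#' [generator_config()].
#'
#' Random-number use is split into counter-based substreams keyed on the
#' master seed: one stream for the host table, one per taxon for its
#' deviation vector, one per taxon for its counts.  Changing `n_taxa`
#' therefore never perturbs host covariates drawn under the same seed.
#'
#' @param config A [generator_config()].
#' @return A `morph_sim` object: list with `hosts` (tibble, one row per
#'   fish), `counts` (long tibble, `n_fish * n_taxa` rows of
#'   fish_id/taxon_id/count), and `truth` (the config plus every realized
#'   random-effect draw and the depth scaling constants).
#' @examples
#' sim <- generate_dataset(generator_config(n_regions = 2, sites_per_region = 2,
#'                                          fish_per_site = 3, n_taxa = 4))
#' dplyr::glimpse(sim$hosts)
#' @export
generate_dataset <- function(config) {
  config <- validate_generator_config(unclass(config))
  n_sites <- config$n_regions * config$sites_per_region
  n_fish <- config$n_fish
  n_taxa <- config$n_taxa

  host <- with_seed(derive_seed(config$seed, 1L), {
    site_tbl <- tibble(
      region = rep(sprintf("R%d", seq_len(config$n_regions)),
                   each = config$sites_per_region),
      location = sprintf("R%d_S%d",
                         rep(seq_len(config$n_regions), each = config$sites_per_region),
                         rep(seq_len(config$sites_per_region), config$n_regions)),
      depth_m = runif(n_sites, config$depth_range_m[1], config$depth_range_m[2])
    )
    site_idx <- rep(seq_len(n_sites), length.out = n_fish)
    cells <- if (config$cell_allocation == "multinomial") {
      sample(names(config$cell_probabilities), n_fish, replace = TRUE,
             prob = config$cell_probabilities)
    } else {
      # largest-remainder apportionment, then a random fish-to-cell shuffle
      quota <- config$cell_probabilities * n_fish
      base <- floor(quota)
      short <- n_fish - sum(base)
      if (short > 0) {
        top_up <- order(quota - base, decreasing = TRUE)[seq_len(short)]
        base[top_up] <- base[top_up] + 1
      }
      sample(rep(names(config$cell_probabilities), base))
    }
    len <- runif(n_fish, config$length_range_cm[1], config$length_range_cm[2])
    al <- config$mass_length_allometry
    mass <- al$a * len^al$b * exp(rnorm(n_fish, 0, al$sdlog))
    hsi <- pmin(exp(rnorm(n_fish, config$hsi_meanlog, config$hsi_sdlog)), 0.95)
    u_region <- setNames(rnorm(config$n_regions, 0, config$sd_region),
                         unique(site_tbl$region))
    u_site <- setNames(rnorm(n_sites, 0, config$sd_site), site_tbl$location)
    fish_id <- sprintf("F%03d", seq_len(n_fish))
    u_fish <- setNames(rnorm(n_fish, 0, config$sd_fish), fish_id)
    hosts <- tibble(
      fish_id = fish_id,
      region = site_tbl$region[site_idx],
      location = site_tbl$location[site_idx],
      depth_m = site_tbl$depth_m[site_idx],
      sex = ifelse(grepl("_male$", cells), "male", "female"),
      color = ifelse(grepl("^blue", cells), "blue", "brown"),
      total_length_cm = len,
      total_mass_kg = mass,
      liver_mass_kg = hsi * mass
    )
    list(hosts = hosts, u_region = u_region, u_site = u_site, u_fish = u_fish)
  })
  hosts <- host$hosts

  depth_s <- if (length(unique(hosts$depth_m)) > 1) {
    scale_plus_two(hosts$depth_m)
  } else {
    structure(rep(2, n_fish), center = hosts$depth_m[1], scale = 1)
  }
  male <- as.numeric(hosts$sex == "male")
  brown <- as.numeric(hosts$color == "brown")

  fac <- psd_factor(config$taxon_cov)
  taxon_ids <- sprintf("T%02d", seq_len(n_taxa))
  taxon_eff <- t(vapply(seq_len(n_taxa), function(t) {
    with_seed(derive_seed(config$seed, 2L, t), as.numeric(fac %*% rnorm(4)))
  }, numeric(4)))
  dimnames(taxon_eff) <- list(taxon_ids,
                              c("intercept", "sex_male", "color_brown", "interaction"))

  eta_host <- config$beta_intercept +
    config$beta_depth * as.numeric(depth_s) +
    config$beta_sex_male * male +
    config$beta_color_brown * brown +
    config$beta_interaction * male * brown +
    host$u_region[hosts$region] + host$u_site[hosts$location] +
    host$u_fish[hosts$fish_id] + log(hosts$total_length_cm)

  counts <- purrr::map_dfr(seq_len(n_taxa), function(t) {
    eta <- eta_host + taxon_eff[t, 1] + taxon_eff[t, 2] * male +
      taxon_eff[t, 3] * brown + taxon_eff[t, 4] * male * brown
    y <- with_seed(derive_seed(config$seed, 3L, t),
                   rnbinom(n_fish, size = config$theta, mu = exp(eta)))
    tibble(fish_id = hosts$fish_id, taxon_id = taxon_ids[t], count = y)
  })
  counts <- dplyr::arrange(counts, .data$fish_id, .data$taxon_id)

  structure(
    list(hosts = hosts, counts = counts,
         truth = list(config = config,
                      u_region = host$u_region, u_site = host$u_site,
                      u_fish = host$u_fish, taxon_effects = taxon_eff,
                      depth_center = attr(depth_s, "center"),
                      depth_scale = attr(depth_s, "scale"))),
    class = "morph_sim")
}

#' @export
print.morph_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("<morph_sim> synthetic host-parasite dataset\n")
  cat(sprintf("  %d fish, %d regions x %d sites, %d taxa, %d count rows\n",
              nrow(x$hosts), cfg$n_regions,
              cfg$n_regions * cfg$sites_per_region, cfg$n_taxa, nrow(x$counts)))
  invisible(x)
}

#' Write a simulated dataset to hosts.csv / counts.csv
#'
#' @param sim A `morph_sim` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "morph_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(hosts = file.path(dir, "hosts.csv"),
             counts = file.path(dir, "counts.csv"))
  readr::write_csv(sim$hosts, paths[["hosts"]])
  readr::write_csv(sim$counts, paths[["counts"]])
  invisible(paths)
}

#' Read a generator configuration from a YAML key-value file
#'
#' Field names mirror [generator_config()] arguments; `taxon_cov` may be
#' given as a 16-element row-major vector or nested lists.
#'
#' @param path Path to a YAML file.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("reading config files requires the 'yaml' package")
  raw <- yaml::yaml.load_file(path)
  if (!is.null(raw$taxon_cov))
    raw$taxon_cov <- matrix(unlist(raw$taxon_cov), 4, 4, byrow = TRUE)
  if (!is.null(raw$cell_probabilities))
    raw$cell_probabilities <- unlist(raw$cell_probabilities)
  do.call(generator_config, raw)
}
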