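test_that("every replicate conserves the configured blue counts per sex", {
  hosts <- make_hosts(n_male_brown = 55, n_male_blue = 4, n_female_brown = 15,
                      n_female_blue = 11, n_sites = 6)
  sch1 <- permutation_scheme("males_only", n_replicates = 1, seed = 3)
  sch2 <- permutation_scheme("both_sexes", n_replicates = 1, seed = 3)
  for (r in seq_len(500)) {
    h1 <- permute_colors(hosts, sch1, r)
    expect_identical(sum(h1$sex == "male" & h1$color == "blue"), 4L)
    # females untouched under males_only
    expect_identical(h1$color[h1$sex == "female"],
                     hosts$color[hosts$sex == "female"])
    h2 <- permute_colors(hosts, sch2, r)
    expect_identical(sum(h2$sex == "male" & h2$color == "blue"), 4L)
    expect_identical(sum(h2$sex == "female" & h2$color == "blue"), 11L)
  }
})

test_that("the constrained draw is uniform over eligible subsets", {
  hosts <- make_hosts(n_male_brown = 2, n_male_blue = 1, n_female_brown = 2,
                      n_female_blue = 1)
  sch <- permutation_scheme("males_only", n_blue_males = 1,
                            n_replicates = 1, seed = 9)
  males <- hosts$fish_id[hosts$sex == "male"]
  picks <- vapply(seq_len(3000), function(r) {
    h <- permute_colors(hosts, sch, r)
    h$fish_id[h$sex == "male" & h$color == "blue"]
  }, character(1))
  freq <- table(factor(picks, levels = males)) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("infeasible constraints and invalid schemes error", {
  hosts <- make_hosts(n_male_brown = 1, n_male_blue = 1, n_female_brown = 2,
                      n_female_blue = 2)
  sch <- permutation_scheme("males_only", n_blue_males = 4, n_replicates = 5)
  expect_error(permute_colors(hosts, sch, 1), class = "morphburden_scheme_error")
  expect_error(permutation_scheme(n_replicates = 0), "n_replicates")
  sch2 <- permutation_scheme("both_sexes", n_blue_females = 10, n_replicates = 2)
  hosts2 <- make_hosts(n_male_brown = 10, n_male_blue = 2, n_female_brown = 2,
                       n_female_blue = 1)
  expect_error(permute_colors(hosts2, sch2, 1), class = "morphburden_scheme_error")
})

test_that("replicate draws are deterministic and order-independent", {
  hosts <- make_hosts(n_male_brown = 20, n_male_blue = 4, n_female_brown = 5,
                      n_female_blue = 5, n_sites = 4)
  sch <- permutation_scheme("males_only", n_replicates = 1, seed = 42)
  forward <- lapply(1:10, function(r) permute_colors(hosts, sch, r)$color)
  backward <- lapply(10:1, function(r) permute_colors(hosts, sch, r)$color)
  expect_identical(forward, rev(backward))
  again <- lapply(1:10, function(r) permute_colors(hosts, sch, r)$color)
  expect_identical(forward, again)
})

test_that("degenerate data where every replicate ties give extreme_proportion 1", {
  # all males share covariates and counts, so any 4-subset relabelling
  # produces a model identical up to row order; with tight optimizer
  # tolerances every permuted z ties with the observed z
  n_male <- 8
  hosts <- tibble::tibble(
    fish_id = sprintf("F%02d", 1:(n_male + 6)),
    region = "R1", location = "S1",
    depth_m = 10,
    sex = c(rep("male", n_male), rep("female", 6)),
    color = c(rep("blue", 4), rep("brown", n_male - 4),
              rep(c("blue", "brown"), 3)),
    total_length_cm = c(rep(70, n_male), 60, 62, 64, 66, 68, 70),
    total_mass_kg = 3.4, liver_mass_kg = 0.05)
  counts <- withr::with_seed(6, {
    per_taxon <- list(T01 = c(3, 8), T02 = c(1, 2))
    dplyr::bind_rows(lapply(names(per_taxon), function(tx) {
      tibble::tibble(
        fish_id = hosts$fish_id,
        taxon_id = tx,
        count = c(rep(per_taxon[[tx]][1], n_male),
                  rpois(6, per_taxon[[tx]][2])))
    }))
  })
  des <- burden_design(fixed = c("sex", "color", "sex:color"),
                       nesting = character(0), taxon_structure = "none",
                       use_offset = FALSE, scale_depth = FALSE)
  sch <- permutation_scheme("males_only", n_blue_males = 4,
                            n_replicates = 20, seed = 5)
  res <- suppressWarnings(run_permutation_test(
    hosts, counts, des, sch,
    burden_control(outer_tol = 1e-10, inner_tol = 1e-12)))
  expect_equal(res$extreme_proportion, 1)
  expect_equal(res$observed_more_extreme, 0)
})

test_that("run_permutation_test returns a coherent replicate table", {
  sim <- generate_dataset(null_calibration_config(seed = 90001))
  stopifnot(calibration_feasible(sim$hosts))
  sch <- permutation_scheme("males_only", n_replicates = 25, seed = 7)
  res <- suppressWarnings(run_permutation_test(
    sim$hosts, sim$counts, small_design(), sch, small_control()))
  expect_equal(nrow(res$replicates), 25)
  expect_true(res$extreme_proportion >= 0 && res$extreme_proportion <= 1)
  ok <- res$replicates$converged
  expect_equal(res$extreme_proportion,
               mean(abs(res$replicates$z[ok]) >= abs(res$observed_z) - 1e-4))
  expect_equal(res$n_failed, sum(!ok))
  # determinism: identical scheme seed reproduces the replicate z vector
  res2 <- suppressWarnings(run_permutation_test(
    sim$hosts, sim$counts, small_design(), sch, small_control()))
  expect_identical(res$replicates$z, res2$replicates$z)
  # add_one correction bounds the proportion away from zero
  res3 <- suppressWarnings(run_permutation_test(
    sim$hosts, sim$counts, small_design(), sch, small_control(), add_one = TRUE))
  expect_gt(res3$extreme_proportion, 0)
})

test_that("observed and replicate z are exchangeable under the null (KS sanity)", {
  # observed colors drawn by the same constrained mechanism as replicates,
  # so the observed z is one more draw from the permutation distribution
  obs_z <- numeric(0)
  rep_z <- numeric(0)
  i <- 0L
  while (length(obs_z) < 12L && i < 20L) {
    i <- i + 1L
    sim <- generate_dataset(null_calibration_config(seed = 80000 + i))
    sch <- permutation_scheme("males_only", n_blue_males = 4,
                              n_replicates = 40, seed = 80000 + i)
    hosts_i <- permute_colors(sim$hosts, sch, replicate_index = 90000 + i)
    res <- tryCatch(
      suppressWarnings(run_permutation_test(
        hosts_i, sim$counts, small_design(), sch, small_control())),
      morphburden_fit_error = function(e) NULL)
    if (is.null(res)) next
    obs_z <- c(obs_z, res$observed_z)
    rep_z <- c(rep_z, res$replicates$z[res$replicates$converged])
  }
  expect_gte(length(obs_z), 12L)
  ks <- suppressWarnings(stats::ks.test(obs_z, rep_z))
  expect_gt(ks$p.value, 0.01)
})
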