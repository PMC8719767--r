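#' Configure a full analysis run
#'
#' Exactly one data source must be supplied: either paths to `hosts.csv` /
#' `counts.csv`, or a [generator_config()] for a synthetic run.
#'
#' @param hosts_path,counts_path Input CSV paths.
#' @param generator A [generator_config()] for synthetic data.
#' @param stages Stages to run, a subset of `c("simulate", "condition",
#'   "burden", "permute", "permanova", "frequency")` (dependency order is
#'   enforced internally; `permute` requires `burden`).
#' @param seed Master seed for every stochastic stage.
#' @param outdir Output directory.
#' @param design,control,scheme Stage options passed through.
#' @param n_permanova Permutations for the PERMANOVA stage.
#' @param verbose Emit per-stage messages?
#' @return A `run_config` list.
#' @export
run_config <- function(hosts_path = NULL, counts_path = NULL, generator = NULL,
                       stages = c("simulate", "condition", "burden", "permute",
                                  "permanova", "frequency"),
                       seed = 1L, outdir = tempfile("morphburden_run_"),
                       design = burden_design(), control = burden_control(),
                       scheme = permutation_scheme(seed = seed),
                       n_permanova = 999, verbose = TRUE) {
  have_paths <- !is.null(hosts_path) || !is.null(counts_path)
  if (have_paths && !is.null(generator))
    abort("supply either input paths or a generator config, not both",
          class = "morphburden_config_error")
  if (!have_paths && is.null(generator))
    abort("supply input paths or a generator config",
          class = "morphburden_config_error")
  if (have_paths && (is.null(hosts_path) || is.null(counts_path)))
    abort("both hosts_path and counts_path are required",
          class = "morphburden_config_error")
  known <- c("simulate", "condition", "burden", "permute", "permanova",
             "frequency")
  bad <- setdiff(stages, known)
  if (length(bad))
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "morphburden_config_error")
  if (length(stages) == 0)
    abort("stage list must be non-empty", class = "morphburden_config_error")
  structure(list(hosts_path = hosts_path, counts_path = counts_path,
                 generator = generator,
                 stages = intersect(known, stages), seed = as.integer(seed),
                 outdir = outdir, design = design, control = control,
                 scheme = scheme, n_permanova = n_permanova,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

config_hash <- function(config) {
  # content hash of the deparsed config (output location and verbosity are
  # presentation, not analysis identity); used to stamp emitted tables
  txt <- paste(deparse(config[setdiff(names(config), c("verbose", "outdir"))]),
               collapse = "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(paste0("# config_hash: ", hash), con)
  close(con)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order — simulate (or
#' ingest) -> condition indices -> burden GLMM -> permutation test ->
#' PERMANOVA -> morph frequency — writing one stamped CSV per stage and a
#' manifest of per-stage status, outputs and content checksums.  Identical
#' config and seed give identical checksums.  A failed stage is recorded
#' and its dependents are skipped.
#'
#' @param config A [run_config()].
#' @return A `run_manifest`: list with `stages` tibble (stage, status,
#'   message), `files` tibble (stage, path, md5), `config_hash`, `seed`,
#'   and the in-memory stage `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (config$verbose) inform(sprintf(...))

  status <- list()
  files <- list()
  results <- list()
  failed <- character(0)

  record <- function(stage, st, msg = "") {
    status[[stage]] <<- tibble(stage = stage, status = st, message = msg)
  }
  emit <- function(stage, df, name) {
    path <- write_stamped_csv(df, file.path(config$outdir, name), hash)
    files[[name]] <<- tibble(stage = stage, path = path,
                             md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(stage, deps, fun) {
    if (!stage %in% config$stages) return(invisible())
    if (any(deps %in% failed) ||
        any(!deps %in% c(names(status)[vapply(status, function(s) s$status == "ok", logical(1))]))) {
      record(stage, "skipped (dependency)")
      say("stage %s skipped (dependency)", stage)
      return(invisible())
    }
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      failed <<- c(failed, stage)
      record(stage, "failed", conditionMessage(out))
      say("stage %s failed: %s", stage, conditionMessage(out))
    } else {
      results[[stage]] <<- out
      record(stage, "ok",
             sprintf("%.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      say("stage %s ok (%s)", stage, status[[stage]]$message)
    }
  }

  # data acquisition (always runs: everything depends on it)
  data_stage <- if (is.null(config$generator)) "ingest" else "simulate"
  t0 <- Sys.time()
  dat <- tryCatch({
    if (is.null(config$generator)) {
      hosts <- read_host_table(config$hosts_path)
      counts <- read_count_table(config$counts_path, hosts)
      list(hosts = hosts, counts = counts)
    } else {
      gen <- unclass(config$generator)
      gen$seed <- derive_seed(config$seed, 100L)
      sim <- generate_dataset(validate_generator_config(gen))
      list(hosts = sim$hosts, counts = sim$counts, truth = sim$truth)
    }
  }, error = function(e) e)
  if (inherits(dat, "error")) {
    record(data_stage, "failed", conditionMessage(dat))
    failed <- c(failed, data_stage, "condition", "burden", "permute",
                "permanova", "frequency")
  } else {
    record(data_stage, "ok",
           sprintf("%.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    results$data <- dat
    emit(data_stage, dat$hosts, "hosts.csv")
    emit(data_stage, dat$counts, "counts.csv")
  }

  run_stage("condition", data_stage, function() {
    fits <- list(fultons_k = fit_condition_model(dat$hosts, "fultons_k"),
                 hsi = fit_condition_model(dat$hosts, "hsi"))
    tab <- dplyr::bind_rows(
      dplyr::mutate(fits$fultons_k$fixed_effects, model = "fultons_k"),
      dplyr::mutate(fits$hsi$fixed_effects, model = "hsi"))
    emit("condition", tab, "condition_fits.csv")
    fits
  })

  run_stage("burden", data_stage, function() {
    fit <- fit_burden_model(dat$hosts, dat$counts, config$design, config$control)
    emit("burden", fit$fixed_effects, "burden_fit.csv")
    if (nrow(fit$taxon_modes) > 0) {
      slopes <- extract_taxon_effects(fit)
      emit("burden", slopes, "taxon_slopes.csv")
    }
    fit
  })

  run_stage("permute", c(data_stage, "burden"), function() {
    scheme <- config$scheme
    scheme$seed <- derive_seed(config$seed, 101L)
    perm <- run_permutation_test(dat$hosts, dat$counts, config$design,
                                 scheme, config$control)
    emit("permute", perm$replicates,
         paste0("permutation_", scheme$mode, ".csv"))
    emit("permute",
         tibble(observed_z = perm$observed_z,
                extreme_proportion = perm$extreme_proportion,
                n_failed = perm$n_failed),
         paste0("permutation_", scheme$mode, "_summary.csv"))
    perm
  })

  run_stage("permanova", data_stage, function() {
    D <- community_dissimilarity(dat$counts)
    covars <- dplyr::mutate(dat$hosts,
                            sex_color = paste(.data$sex, .data$color, sep = "_"))
    tab <- permanova(D, covars, c("sex_color", "location", "depth_m"),
                     n_permutations = config$n_permanova,
                     seed = derive_seed(config$seed, 102L))
    emit("permanova", tab, "permanova.csv")
    tab
  })

  run_stage("frequency", data_stage, function() {
    summ <- morph_frequency_summary(dat$hosts)
    test <- sex_color_chisq(summ$table)
    tab <- dplyr::mutate(summ$proportions,
                         chisq = test$statistic, df = test$df,
                         p_value = test$p_value)
    emit("frequency", tab, "morph_frequency.csv")
    list(summary = summ, test = test)
  })

  structure(list(stages = dplyr::bind_rows(status),
                 files = dplyr::bind_rows(files),
                 config_hash = hash, seed = config$seed,
                 outdir = config$outdir,
                 package_version = as.character(utils::packageVersion("morphburden")),
                 results = results),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> morphburden %s, seed %d, config %s\n",
              x$package_version, x$seed, x$config_hash))
  print(as.data.frame(x$stages), row.names = FALSE)
  if (nrow(x$files)) {
    cat("outputs:\n")
    print(as.data.frame(x$files[, c("path", "md5")]), row.names = FALSE)
  }
  invisible(x)
}
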