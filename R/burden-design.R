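#' Specify the parasite-burden model design
#'
#' The default reproduces the full burden model: fixed effects depth (scaled
#' with [scale_plus_two()]), sex, color and their interaction with treatment
#' contrasts referenced at female/blue (so reported terms are `sex[male]`
#' and `color[brown]`); nested random intercepts for fish within sampling
#' location within sampling region; a correlated 4-vector of taxon-level
#' random effects on (intercept, sex, color, interaction); and an offset of
#' log total length (cm) with coefficient fixed at 1.
#'
#' @param fixed Character subset of `c("depth", "sex", "color", "sex:color")`
#'   (the intercept is always included; `"sex:color"` requires both main
#'   effects).  An empty vector fits an intercept-only model.
#' @param nesting Character subset of `c("region", "location", "fish")`
#'   naming the scalar random-intercept blocks to include, outermost first.
#' @param taxon_structure `"full"` for the correlated (intercept, sex,
#'   color, interaction) 4-vector per taxon, `"reduced"` for a correlated
#'   (intercept, interaction) 2-vector (more stable on small fixtures), or
#'   `"none"`.
#' @param use_offset Include the log total-length offset (coefficient fixed
#'   at 1, never estimated)?  The offset uses raw log length in cm:
#'   standardizing inside an offset would change the model family.
#' @param scale_depth Standardize depth with [scale_plus_two()]?
#' @return A `burden_design` list.
#' @export
burden_design <- function(fixed = c("depth", "sex", "color", "sex:color"),
                          nesting = c("region", "location", "fish"),
                          taxon_structure = c("full", "reduced", "none"),
                          use_offset = TRUE,
                          scale_depth = TRUE) {
  taxon_structure <- match.arg(taxon_structure)
  bad <- setdiff(fixed, c("depth", "sex", "color", "sex:color"))
  if (length(bad))
    abort(paste0("unknown fixed term(s): ", paste(bad, collapse = ", ")),
          class = "morphburden_design_error")
  if ("sex:color" %in% fixed && !all(c("sex", "color") %in% fixed))
    abort("`sex:color` requires both `sex` and `color` main effects",
          class = "morphburden_design_error")
  bad <- setdiff(nesting, c("region", "location", "fish"))
  if (length(bad))
    abort(paste0("unknown nesting level(s): ", paste(bad, collapse = ", ")),
          class = "morphburden_design_error")
  structure(list(fixed = fixed,
                 nesting = intersect(c("region", "location", "fish"), nesting),
                 taxon_structure = taxon_structure,
                 use_offset = isTRUE(use_offset),
                 scale_depth = isTRUE(scale_depth)),
            class = "burden_design")
}

#' Optimizer control for the burden model
#'
#' @param outer_tol Relative tolerance of the outer bounded quasi-Newton
#'   optimization over (fixed effects, log-theta, log-SDs, taxon covariance
#'   factor).
#' @param inner_tol Convergence threshold on the infinity norm of the inner
#'   gradient at the joint random-effect mode.
#' @param max_inner,max_outer Iteration caps.
#' @param compute_se Compute Wald standard errors?  Disable for speed when
#'   only point estimates are needed.
#' @param se_method `"conditional"` (default) differentiates the Laplace
#'   objective over the fixed effects only, i.e. Wald SEs conditional on
#'   the estimated variance parameters — the convention of classic
#'   mixed-model software, slightly anti-conservative.  `"full"` takes the
#'   fixed-effect block of the inverse Hessian over all interior outer
#'   parameters, additionally carrying theta/variance-parameter
#'   uncertainty; being a high-dimensional finite-difference Hessian it is
#'   slower and can be numerically fragile on large models.
#' @param start Optional warm start: a `burden_fit` from a previous call on
#'   comparably shaped data, or a numeric outer-parameter vector.
#' @return A list of control settings.
#' @export
burden_control <- function(outer_tol = 1e-6, inner_tol = 1e-8,
                           max_inner = 50L, max_outer = 500L,
                           compute_se = TRUE,
                           se_method = c("conditional", "full"),
                           start = NULL) {
  list(outer_tol = outer_tol, inner_tol = inner_tol,
       max_inner = as.integer(max_inner), max_outer = as.integer(max_outer),
       compute_se = isTRUE(compute_se), se_method = match.arg(se_method),
       start = start)
}

# Assemble the model matrices and sparse random-effect row layout consumed
# by the C++ Laplace core.
prep_burden_data <- function(hosts, counts, design) {
  hosts <- validate_hosts(hosts)
  counts <- validate_counts(counts, hosts, complete = TRUE)

  dat <- dplyr::left_join(counts, hosts, by = "fish_id")
  dat <- dplyr::arrange(dat, .data$taxon_id, .data$fish_id)

  male <- as.numeric(dat$sex == "male")
  brown <- as.numeric(dat$color == "brown")

  scaling <- list()
  cols <- list("(Intercept)" = rep(1, nrow(dat)))
  if ("depth" %in% design$fixed) {
    if (design$scale_depth) {
      host_depth <- scale_plus_two(hosts$depth_m)
      scaling <- list(depth_center = attr(host_depth, "center"),
                      depth_scale = attr(host_depth, "scale"))
      depth_by_fish <- setNames(as.numeric(host_depth), hosts$fish_id)
      cols[["depth"]] <- depth_by_fish[dat$fish_id]
    } else {
      cols[["depth"]] <- dat$depth_m
    }
  }
  if ("sex" %in% design$fixed) cols[["sex[male]"]] <- male
  if ("color" %in% design$fixed) cols[["color[brown]"]] <- brown
  if ("sex:color" %in% design$fixed)
    cols[["sex[male]:color[brown]"]] <- male * brown
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  offset <- if (design$use_offset) log(dat$total_length_cm) else rep(0, nrow(dat))

  # scalar random-intercept blocks, outermost first; locations and fish are
  # labelled within their parent so accidental label reuse cannot alias
  blocks <- list()
  if ("region" %in% design$nesting) blocks$region <- factor(dat$region)
  if ("location" %in% design$nesting)
    blocks$location <- factor(paste(dat$region, dat$location, sep = ":"))
  if ("fish" %in% design$nesting) blocks$fish <- factor(dat$fish_id)

  d <- switch(design$taxon_structure, full = 4L, reduced = 2L, none = 0L)
  taxon <- factor(dat$taxon_id)
  n_taxa <- if (d > 0) nlevels(taxon) else 0L

  n <- nrow(dat)
  s <- length(blocks)
  k <- s + d
  Zi <- matrix(-2L, n, max(k, 1))
  Zv <- matrix(0, n, max(k, 1))
  Zl <- matrix(-2L, n, max(k, 1))
  col0 <- 0L
  block_cols <- integer(0)
  if (s > 0) {
    for (b in seq_len(s)) {
      f <- blocks[[b]]
      Zi[, b] <- col0 + as.integer(f) - 1L
      Zv[, b] <- 1
      Zl[, b] <- b - 1L
      block_cols[b] <- nlevels(f)
      col0 <- col0 + nlevels(f)
    }
  }
  if (d > 0) {
    r <- switch(design$taxon_structure,
                full = cbind(1, male, brown, male * brown),
                reduced = cbind(1, male * brown))
    for (m in seq_len(d)) {
      j <- s + m
      Zi[, j] <- col0 + (as.integer(taxon) - 1L) * d + (m - 1L)
      Zv[, j] <- r[, m]
      Zl[, j] <- -1L
    }
  }
  q <- col0 + n_taxa * d

  list(dat = list(y = as.numeric(dat$count), X = X, offset = offset,
                  Zi = Zi, Zv = Zv, Zl = Zl, d = d, q = as.integer(q),
                  n_taxa = as.integer(n_taxa)),
       row_fish = dat$fish_id, row_male = male,
       scalar_blocks = names(blocks), block_levels = lapply(blocks, levels),
       taxon_levels = if (d > 0) levels(taxon) else character(0),
       taxon_terms = switch(design$taxon_structure,
                            full = c("intercept", "sex[male]", "color[brown]",
                                     "sex[male]:color[brown]"),
                            reduced = c("intercept", "sex[male]:color[brown]"),
                            none = character(0)),
       scaling = scaling, design = design,
       n_obs = n, n_fish = nrow(hosts))
}

validate_hosts <- function(hosts) {
  required <- c("fish_id", "region", "location", "depth_m", "sex", "color",
                "total_length_cm")
  missing <- setdiff(required, names(hosts))
  if (length(missing))
    abort(paste0("host table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "morphburden_schema_error")
  if (anyDuplicated(hosts$fish_id))
    abort("duplicated fish_id in host table",
          class = "morphburden_schema_error")
  bad <- which(!hosts$sex %in% c("male", "female"))
  if (length(bad))
    abort(paste0("row ", bad[1], ": sex must be 'male' or 'female'"),
          class = "morphburden_schema_error")
  bad <- which(!hosts$color %in% c("blue", "brown"))
  if (length(bad))
    abort(paste0("row ", bad[1], ": color must be 'blue' or 'brown'"),
          class = "morphburden_schema_error")
  bad <- which(!is.finite(hosts$total_length_cm) | hosts$total_length_cm <= 0)
  if (length(bad))
    abort(paste0("row ", bad[1], ": total_length_cm must be positive"),
          class = "morphburden_schema_error")
  bad <- which(!is.finite(hosts$depth_m) | hosts$depth_m < 0)
  if (length(bad))
    abort(paste0("row ", bad[1], ": depth_m must be non-negative"),
          class = "morphburden_schema_error")
  as_tibble(hosts)
}

validate_counts <- function(counts, hosts, complete = FALSE) {
  required <- c("fish_id", "taxon_id", "count")
  missing <- setdiff(required, names(counts))
  if (length(missing))
    abort(paste0("count table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "morphburden_schema_error")
  orphan <- setdiff(counts$fish_id, hosts$fish_id)
  if (length(orphan))
    abort(paste0("count table references unknown fish_id: ", orphan[1]),
          class = "morphburden_integrity_error")
  if (anyDuplicated(counts[c("fish_id", "taxon_id")]))
    abort("duplicate (fish_id, taxon_id) pair in count table",
          class = "morphburden_integrity_error")
  bad <- which(!is.finite(counts$count) | counts$count < 0 |
                 counts$count != floor(counts$count))
  if (length(bad))
    abort(paste0("row ", bad[1], ": count must be a non-negative integer"),
          class = "morphburden_schema_error")
  counts <- as_tibble(counts)
  if (complete) {
    grid <- tidyr::expand_grid(fish_id = hosts$fish_id,
                               taxon_id = unique(counts$taxon_id))
    filled <- dplyr::left_join(grid, counts, by = c("fish_id", "taxon_id"))
    n_struct <- sum(is.na(filled$count))
    if (n_struct > 0) {
      inform(sprintf("filled %d absent (fish, taxon) pair(s) with structural zeros",
                     n_struct))
      filled$count[is.na(filled$count)] <- 0
    }
    counts <- filled
  }
  counts
}

# Rewrite the color-dependent entries of a prepared dataset in place of a
# full re-preparation: used by the permutation test, where only the color
# labels change between replicates.
update_prep_colors <- function(prep, hosts) {
  color_by_fish <- setNames(hosts$color, hosts$fish_id)
  brown <- as.numeric(color_by_fish[prep$row_fish] == "brown")
  male <- prep$row_male
  X <- prep$dat$X
  if ("color[brown]" %in% colnames(X)) X[, "color[brown]"] <- brown
  if ("sex[male]:color[brown]" %in% colnames(X))
    X[, "sex[male]:color[brown]"] <- male * brown
  prep$dat$X <- X
  d <- prep$dat$d
  if (d > 0) {
    s <- length(prep$scalar_blocks)
    r <- switch(prep$design$taxon_structure,
                full = cbind(1, male, brown, male * brown),
                reduced = cbind(1, male * brown))
    for (m in seq_len(d)) prep$dat$Zv[, s + m] <- r[, m]
  }
  prep
}
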