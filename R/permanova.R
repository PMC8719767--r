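#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|u - v|) / sum(u + v)`: 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param u,v Equal-length non-negative numeric vectors, not both all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(1, 2), c(3, 0)) # 4/6
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v))
    abort("`u` and `v` must have equal length", class = "morphburden_domain_error")
  if (any(u < 0) || any(v < 0))
    abort("abundances must be non-negative", class = "morphburden_domain_error")
  tot <- sum(u) + sum(v)
  if (tot == 0)
    abort("Bray-Curtis is undefined when both vectors are all zero",
          class = "morphburden_distance_error")
  sum(abs(u - v)) / tot
}

#' Pairwise dissimilarity matrix of parasite communities
#'
#' Pivots the long count table to a fish-by-taxon abundance matrix and
#' computes all pairwise dissimilarities.  Fish with all-zero parasite
#' vectors are excluded first (Bray-Curtis is undefined for them) with a
#' logged warning; the exclusion count is attached as an attribute.
#'
#' @param counts Long count tibble (`fish_id`, `taxon_id`, `count`).
#' @param method `"bray"` (default, on raw counts) or `"jaccard"`
#'   (presence/absence: `2B / (1 + B)` of the binary Bray-Curtis `B`).
#' @return A symmetric dissimilarity matrix with fish_id dimnames and
#'   attributes `n_excluded` / `excluded_fish`.
#' @export
community_dissimilarity <- function(counts, method = c("bray", "jaccard")) {
  method <- match.arg(method)
  wide <- tidyr::pivot_wider(counts, id_cols = "fish_id",
                             names_from = "taxon_id", values_from = "count",
                             values_fill = 0)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$fish_id
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    warn(sprintf("excluding %d fish with all-zero parasite vectors: %s",
                 sum(empty), paste(rownames(mat)[empty], collapse = ", ")))
    mat <- mat[!empty, , drop = FALSE]
  }
  if (method == "jaccard") mat <- (mat > 0) * 1
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      b <- bray_curtis(mat[i, ], mat[j, ])
      if (method == "jaccard") b <- 2 * b / (1 + b)
      D[i, j] <- D[j, i] <- b
    }
  }
  attr(D, "n_excluded") <- sum(empty)
  attr(D, "excluded_fish") <- wide$fish_id[empty]
  D
}

# Gower-centered inner-product matrix of -d^2/2
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(M) {
  qr_m <- qr(M)
  Q <- qr.Q(qr_m)[, seq_len(qr_m$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Sequential (Type-I) partitioning of a dissimilarity matrix in the given
#' term order, following the McArdle-Anderson direct decomposition of the
#' Gower-centered matrix: per term, pseudo-F against the residual mean
#' square and `R^2 = SS_term / SS_total`.  Significance is assessed by free
#' (unrestricted) permutation of observation labels; `p = (#{F* >= F} + 1)
#' / (n_permutations + 1)`, the identity permutation included.
#'
#' @param dist Symmetric dissimilarity matrix (e.g. from
#'   [community_dissimilarity()]) with observation dimnames.
#' @param data Data frame of covariates, rows matching `dist` (matched by
#'   dimnames when present).
#' @param terms Character vector of column names of `data`, in the order in
#'   which their sequential sums of squares are to be assigned.  Character
#'   or factor columns enter as factors; numeric columns as 1-df continuous
#'   terms.
#' @param n_permutations Number of random permutations (>= 1).
#' @param seed Seed for the permutation stream.
#' @param strata Optional factor (length `n`): labels are then permuted
#'   only within strata levels (restricted permutation). Free permutation
#'   is the default.
#' @return A `permanova_table` tibble: term, df, ss, r2, pseudo_f,
#'   p_value, plus Residual and Total rows.
#' @examples
#' D <- matrix(1, 4, 4) - diag(4)
#' permanova(D, data.frame(g = c("a", "a", "b", "b")), "g",
#'           n_permutations = 99, seed = 1)
#' @export
permanova <- function(dist, data, terms, n_permutations = 999, seed = 1L,
                      strata = NULL) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n != ncol(D) || max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0))
    abort("`dist` must be a symmetric matrix with zero diagonal",
          class = "morphburden_domain_error")
  if (!is.null(rownames(D)) && !is.null(data$fish_id) &&
      all(rownames(D) %in% data$fish_id)) {
    data <- data[match(rownames(D), data$fish_id), , drop = FALSE]
  }
  if (nrow(data) != n)
    abort("`data` rows must match `dist`", class = "morphburden_domain_error")
  missing <- setdiff(terms, names(data))
  if (length(missing))
    abort(paste0("unknown term(s): ", paste(missing, collapse = ", ")),
          class = "morphburden_domain_error")
  check_scalar_count(n_permutations, "n_permutations")

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # sequential hat matrices
  model_cols <- function(v) {
    if (is.numeric(v)) matrix(v, ncol = 1) else {
      f <- factor(v)
      stats::model.matrix(~f)[, -1, drop = FALSE]
    }
  }
  mats <- lapply(terms, function(tm) model_cols(data[[tm]]))
  hats <- vector("list", length(terms))
  M <- matrix(1, n, 1)
  h_prev <- hat_matrix(M)
  df <- ranks <- numeric(length(terms))
  rank_prev <- 1
  for (j in seq_along(terms)) {
    M <- cbind(M, mats[[j]])
    h_j <- hat_matrix(M)
    rank_j <- qr(M)$rank
    df[j] <- rank_j - rank_prev
    hats[[j]] <- h_j - h_prev
    h_prev <- h_j
    rank_prev <- rank_j
  }
  h_full <- h_prev
  df_res <- n - rank_prev

  decompose <- function(Gm) {
    ss <- vapply(hats, function(hd) sum(hd * Gm), numeric(1))
    ss_res <- sum((diag(n) - h_full) * Gm)
    list(ss = ss, ss_res = ss_res)
  }
  obs <- decompose(G)
  f_obs <- if (df_res > 0 && obs$ss_res > 1e-12) {
    (obs$ss / df) / (obs$ss_res / df_res)
  } else {
    rep(NA_real_, length(terms))
  }
  if (df_res == 0)
    warn("residual degrees of freedom are zero; pseudo-F undefined")
  if (df_res > 0 && obs$ss_res <= 1e-12)
    warn("residual sum of squares is zero (perfect separation); pseudo-F undefined")

  p <- rep(NA_real_, length(terms))
  if (all(is.finite(f_obs))) {
    if (!is.null(strata)) {
      strata <- factor(rep_len(strata, n))
      draw_perm <- function() {
        idx <- seq_len(n)
        for (lev in levels(strata)) {
          pos <- which(strata == lev)
          if (length(pos) > 1) idx[pos] <- pos[sample.int(length(pos))]
        }
        idx
      }
    } else {
      draw_perm <- function() sample.int(n)
    }
    exceed <- rep(1, length(terms))  # identity permutation counts
    with_seed(derive_seed(seed, 20L), {
      for (b in seq_len(n_permutations - 1)) {
        idx <- draw_perm()
        per <- decompose(G[idx, idx])
        f_b <- (per$ss / df) / (per$ss_res / df_res)
        exceed <- exceed + (f_b >= f_obs - 1e-12)
      }
    })
    p <- exceed / n_permutations
  }

  out <- tibble(term = c(terms, "Residual", "Total"),
                df = c(df, df_res, n - 1),
                ss = c(obs$ss, obs$ss_res, ss_total),
                r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
                pseudo_f = c(f_obs, NA_real_, NA_real_),
                p_value = c(p, NA_real_, NA_real_))
  class(out) <- c("permanova_table", class(out))
  out
}
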