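#' Blue-morph frequency summary by sex
#'
#' Tabulates sex by color, computes per-sex blue proportions, and excludes
#' (with a logged count) fish whose sex or color is not definitively
#' male/female or blue/brown.
#'
#' @param hosts Host tibble with `sex` and `color` columns.
#' @return A list: `table` (2x2 integer sex-by-color matrix),
#'   `proportions` tibble (sex, n, n_blue, prop_blue), `n_excluded`.
#' @export
morph_frequency_summary <- function(hosts) {
  if (is.null(hosts) || nrow(hosts) == 0)
    abort("empty host table", class = "morphburden_domain_error")
  ok <- hosts$sex %in% c("male", "female") & hosts$color %in% c("blue", "brown")
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    inform(sprintf("excluding %d fish without definitive sex/color", n_excluded))
  h <- hosts[ok, ]
  if (nrow(h) == 0)
    abort("no definitively identified fish", class = "morphburden_domain_error")
  tab <- table(factor(h$sex, levels = c("female", "male")),
               factor(h$color, levels = c("blue", "brown")))
  tab <- unclass(tab)
  names(dimnames(tab)) <- c("sex", "color")
  props <- dplyr::summarise(
    dplyr::group_by(h, .data$sex),
    n = dplyr::n(),
    n_blue = sum(.data$color == "blue"),
    prop_blue = mean(.data$color == "blue"),
    .groups = "drop")
  if (length(unique(h$sex)) < 2)
    warn("only one sex present; summary has a single row")
  list(table = tab, proportions = props, n_excluded = n_excluded)
}

#' Chi-squared test of color frequency by sex
#'
#' Pearson chi-squared test of independence on a 2x2 sex-by-color table,
#' with expected counts from the margins.  The Yates continuity correction
#' is off by default (large-sample design).
#'
#' @param table 2x2 integer matrix (sex by color).
#' @param continuity_correction Apply the Yates correction?
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @examples
#' sex_color_chisq(matrix(c(20, 5, 10, 25), 2))
#' @export
sex_color_chisq <- function(table, continuity_correction = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != floor(tab)))
    abort("`table` must be a 2x2 matrix of non-negative integer counts",
          class = "morphburden_domain_error")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    abort("degenerate table: a zero margin leaves expected counts of zero",
          class = "morphburden_domain_error")
  res <- suppressWarnings(chisq.test(tab, correct = continuity_correction))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
}
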