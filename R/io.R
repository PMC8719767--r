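#' Read and validate a host table
#'
#' Expects a UTF-8 CSV with header columns `fish_id`, `region`, `location`,
#' `depth_m`, `sex`, `color`, `total_length_cm`, `total_mass_kg`,
#' `liver_mass_kg` (the last two optional for burden-only analyses).
#' Validation errors name the offending column or row.
#'
#' @param path CSV path.
#' @return Validated host tibble.
#' @export
read_host_table <- function(path) {
  hosts <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_hosts(hosts)
}

#' Read and validate a long parasite count table
#'
#' Expects a CSV with columns `fish_id`, `taxon_id`, `count`.  Every
#' fish_id must resolve to a host; duplicated (fish, taxon) pairs error.
#' The table is completed to the full fish-by-taxon grid, filling absent
#' pairs with structural zeros (a dissection that did not record a taxon
#' observed zero individuals of it); each fill is logged.
#'
#' @param path CSV path.
#' @param hosts Host tibble the counts must reference.
#' @return Completed count tibble with `n_fish * n_taxa` rows.
#' @export
read_count_table <- function(path, hosts) {
  counts <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  validate_counts(counts, hosts, complete = TRUE)
}
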