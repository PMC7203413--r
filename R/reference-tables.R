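# Published reference tables shipped as plain-text extdata: linkage-group
# summaries of the two S. bicolor BTx623 x S. halepense G9E BC1F1 mapping
# populations (H4, H6) and the table of S. propinquum-allele runs observed
# in them. Used as worked examples and as cross-checks of the package's own
# summary construction.

#' Reference linkage-group summary of a mapping population
#'
#' Published per-linkage-group map statistics (marker count, cM length,
#' average/maximum spacing, average AA and AB counts, AB/AA ratio) for the
#' H4- and H6-derived *S. bicolor* x *S. halepense* BC1F1 populations.
#'
#' @param population `"H4"` or `"H6"`.
#' @return Data.frame with columns LG, n_markers, length_cm, avg_spacing,
#'   max_spacing, avg_AA, avg_AB, AB_AA_ratio.
#' @export
reference_map_summary <- function(population = c("H4", "H6")) {
  population <- match.arg(population)
  path <- system.file("extdata",
                      paste0("map_summary_", population, ".tsv"),
                      package = "tetrabc", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Reference table of propinquum-allele runs
#'
#' Published genomic regions with runs of 3 or more consecutive mapped
#' *S. propinquum*-derived alleles in the H4 and H6 populations: one row per
#' distinct run, with per-population bp spans (NA where the run was not
#' observed in that population).
#'
#' @return Data.frame with columns chrom, lg_h4, lg_h6, h4_start, h4_end,
#'   h6_start, h6_end, plus `start_a`/`end_a`/`start_b`/`end_b` aliases
#'   (a = H4, b = H6) accepted by [summarize_run_table()].
#' @export
reference_run_table <- function() {
  path <- system.file("extdata", "propinquum_runs.tsv",
                      package = "tetrabc", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$start_a <- df$h4_start; df$end_a <- df$h4_end
  df$start_b <- df$h6_start; df$end_b <- df$h6_end
  df
}
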