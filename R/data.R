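# Bundled reference tables (plain-text, under inst/extdata) so the worked
# examples and acceptance checks run offline.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "rorscan")
  if (path == "") stop_rorscan(sprintf("bundled table %s not found", name), "config_error")
  path
}

#' Historical Chinese population records used for founder dating
#'
#' Seven census records from 684 B.C. to 1949 A.D. with the externally
#' estimated mutation age obtained under each record's growth rate. The
#' 1949 figure is stored in millions (the census sources mix units); the
#' `population_unit` column normalises this.
#'
#' @return data frame: `label`, `population`, `population_unit`,
#'   `years_till_now`, `estimated_age`.
#' @export
historical_populations <- function() {
  read_delim_auto(extdata("historical_populations.tsv"))
}

#' Published BRCA1/BRCA2 bin scan table
#'
#' The published per-bin layout: carrier counts, bin boundaries (CDS
#' position tokens, including intronic boundary offsets such as `5468-1`),
#' ROR point estimates with confidence intervals, and raw p-values. The raw
#' p-values are the inputs from which the published FDR column is exactly
#' reproducible with [bh_adjust()] applied per gene; the ROR point
#' estimates themselves are not recomputable because the underlying per-bin
#' phenotype counts are unpublished.
#'
#' @return data frame with columns `gene`, `bin`, `n_carriers`, `region`,
#'   `start`, `end`, `ror`, `ci_low`, `ci_high`, `p_raw`.
#' @export
published_bin_scan <- function() {
  df <- read_delim_auto(extdata("published_bins.tsv"))
  df$start <- as.character(df$start)
  df$end <- as.character(df$end)
  df
}

#' Published clinical status x carrier summary counts
#'
#' Status-level subject totals with carrier / non-carrier splits for the
#' 7,919-subject screening cohort (729 deleterious-mutation carriers).
#'
#' @return data frame: `status`, `n`, `carriers`, `non_carriers`.
#' @export
clinical_summary_counts <- function() {
  read_delim_auto(extdata("clinical_summary.tsv"))
}
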