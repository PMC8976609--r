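# STR marker association and founder core-haplotype sharing.
#
# Nine short-tandem-repeat markers flanking BRCA1 (D17S800, D17S1320,
# D17S1321, D17S855, D17S1323, D17S1327, D17S1326, D17S1325, D17S791,
# spanning ~5.8 Mbp) are the default panel. Allele-frequency differences
# between founder-mutation carriers and controls are tested per marker with
# a Pearson chi-square on the allele-count contingency table (two alleles
# per typed subject). Haplotype phasing is performed externally; this
# module consumes phased per-chromosome allele vectors.

#' Default STR marker panel flanking BRCA1
#' @export
brca1_str_panel <- function() {
  c(
    "D17S800", "D17S1320", "D17S1321", "D17S855", "D17S1323",
    "D17S1327", "D17S1326", "D17S1325", "D17S791"
  )
}

genotype_alleles <- function(genotypes, marker) {
  require_columns(genotypes, c("subject_id", "marker", "allele1", "allele2"), "genotype table")
  g <- genotypes[genotypes$marker == marker, , drop = FALSE]
  al <- c(as.character(g$allele1), as.character(g$allele2))
  n_missing <- sum(is.na(al))
  if (n_missing > 0) {
    warn_rorscan(
      sprintf("%d missing allele(s) dropped at marker %s", n_missing, marker),
      "missing_alleles"
    )
  }
  list(alleles = al[!is.na(al)], n_typed = nrow(g))
}

#' Chi-square test of STR allele frequencies between carriers and controls
#'
#' Pearson chi-square (no continuity correction) on the allele x group
#' contingency table; each typed subject contributes two alleles. Alleles
#' observed fewer than `min_count` times in total can be pooled into an
#' `"other"` class with `pool_rare = TRUE` (off by default).
#'
#' @param carrier_genotypes,control_genotypes genotype tables with columns
#'   `subject_id, marker, allele1, allele2`.
#' @param marker marker name; must belong to `panel`.
#' @param panel marker panel (default [brca1_str_panel()]).
#' @param pool_rare pool rare alleles into an `"other"` class.
#' @param min_count pooling threshold (default 5).
#' @return list with `marker`, `table` (group x allele counts), `chi2`,
#'   `df`, `p_value`, and `note` (non-`NULL` when the test is skipped for a
#'   degenerate table).
#' @export
allele_freq_test <- function(carrier_genotypes, control_genotypes, marker,
                             panel = brca1_str_panel(), pool_rare = FALSE,
                             min_count = 5) {
  if (!is.null(panel) && !(marker %in% panel)) {
    stop_rorscan(sprintf("marker %s is not in the panel", marker), "config_error")
  }
  ca <- genotype_alleles(carrier_genotypes, marker)
  co <- genotype_alleles(control_genotypes, marker)
  if (ca$n_typed == 0L || co$n_typed == 0L) {
    stop_rorscan(sprintf("marker %s: need >= 1 typed subject per group", marker), "config_error")
  }
  alleles <- c(ca$alleles, co$alleles)
  if (pool_rare) {
    rare <- names(which(table(alleles) < min_count))
    alleles[alleles %in% rare] <- "other"
    ca$alleles[ca$alleles %in% rare] <- "other"
    co$alleles[co$alleles %in% rare] <- "other"
  }
  lev <- sort(unique(alleles))
  tab <- rbind(
    carrier = table(factor(ca$alleles, levels = lev)),
    control = table(factor(co$alleles, levels = lev))
  )
  if (length(lev) < 2L) {
    message(sprintf("marker %s monomorphic: chi-square skipped (df = 0)", marker))
    return(list(
      marker = marker, table = tab, chi2 = NA_real_, df = 0L,
      p_value = NA_real_, note = "monomorphic"
    ))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    marker = marker, table = tab,
    chi2 = unname(ct$statistic), df = unname(ct$parameter),
    p_value = unname(ct$p.value), note = NULL
  )
}

#' Test all panel markers with optional BH correction
#'
#' @inheritParams allele_freq_test
#' @param adjust apply Benjamini-Hochberg across the panel (off by default:
#'   per-marker chi-square values are conventionally reported uncorrected).
#' @return data frame with `marker`, `chi2`, `df`, `p_value` and, when
#'   `adjust = TRUE`, `p_adj`.
#' @export
str_panel_test <- function(carrier_genotypes, control_genotypes,
                           panel = brca1_str_panel(), adjust = FALSE, ...) {
  res <- lapply(panel, function(m) {
    allele_freq_test(carrier_genotypes, control_genotypes, m, panel = panel, ...)
  })
  out <- data.frame(
    marker = panel,
    chi2 = vapply(res, function(r) r$chi2 %||% NA_real_, 0),
    df = vapply(res, function(r) as.integer(r$df), 0L),
    p_value = vapply(res, function(r) r$p_value %||% NA_real_, 0),
    stringsAsFactors = FALSE
  )
  if (adjust) {
    ok <- !is.na(out$p_value)
    out$p_adj <- NA_real_
    out$p_adj[ok] <- bh_adjust(out$p_value[ok])
  }
  out
}

#' Core-haplotype sharing among founder-mutation carriers
#'
#' For each marker, reports the modal allele among carrier chromosomes, its
#' carrier-chromosome frequency, and the same allele's frequency among
#' control chromosomes. A founder effect is flagged when the carrier modal
#' frequency exceeds the control frequency at `min_consecutive` or more
#' consecutive markers in panel order.
#'
#' @param phased phased haplotype table with columns `subject_id`,
#'   `chrom_index` (1 or 2), `marker`, `allele`. Genotype-style input
#'   without `chrom_index` is rejected with a pointer to external phasing.
#' @param carriers subject ids of mutation carriers.
#' @param carrier_chrom which carrier chromosome bears the mutation
#'   (default 1, the convention used by [simulate_str_panel()]); `NULL`
#'   uses both carrier chromosomes.
#' @param panel marker order (default [brca1_str_panel()]); markers absent
#'   from `phased` are dropped.
#' @param min_consecutive consecutive-marker threshold for the founder flag
#'   (default 3).
#' @return list with `summary` (per-marker data frame: `marker`,
#'   `modal_allele`, `carrier_freq`, `control_freq`, chromosome counts),
#'   `founder_effect` flag and `min_consecutive`.
#' @export
core_haplotype_sharing <- function(phased, carriers, carrier_chrom = 1,
                                   panel = brca1_str_panel(), min_consecutive = 3) {
  if (is.null(phased$chrom_index)) {
    stop_rorscan(
      "input is not phased (no chrom_index column); reconstruct haplotypes with an external phasing tool first",
      "contract_error"
    )
  }
  require_columns(phased, c("subject_id", "chrom_index", "marker", "allele"), "phased table")
  markers <- panel[panel %in% unique(phased$marker)]
  if (length(markers) == 0L) markers <- unique(phased$marker)

  is_carrier <- phased$subject_id %in% carriers
  carrier_rows <- is_carrier
  if (!is.null(carrier_chrom)) {
    carrier_rows <- carrier_rows & phased$chrom_index == carrier_chrom
  }
  control_rows <- !is_carrier

  rows <- lapply(markers, function(m) {
    ca <- as.character(phased$allele[carrier_rows & phased$marker == m])
    co <- as.character(phased$allele[control_rows & phased$marker == m])
    tab <- sort(table(ca), decreasing = TRUE)
    modal <- names(tab)[1] # ties break to the smaller allele label
    data.frame(
      marker = m,
      modal_allele = modal,
      carrier_freq = unname(tab[1]) / length(ca),
      control_freq = if (length(co)) mean(co == modal) else NA_real_,
      n_carrier_chrom = length(ca),
      n_control_chrom = length(co),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  exceed <- !is.na(summary$control_freq) & summary$carrier_freq > summary$control_freq
  runs <- rle(exceed)
  founder <- any(runs$lengths[runs$values] >= min_consecutive)
  list(summary = summary, founder_effect = founder, min_consecutive = min_consecutive)
}
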