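# The ROR scan: per-bin odds ratios, the ratio-of-odds-ratios statistic,
# Woolf confidence intervals, Benjamini-Hochberg correction and OCCR/BCCR
# region calls.
#
# For each bin, carriers of a deleterious mutation with representative CDS
# coordinate in the bin are the exposed group; the comparison group is the
# gene-wide non-carriers of the same clinical status. The odds ratio of
# breast cancer and of ovarian cancer are each taken against the cancer-free
# arm, and the scan statistic is their ratio,
#   ROR = OR_breast / OR_ovarian.
# Because both ORs share the cancer-free arm, the arm cancels algebraically
# and ROR equals the odds ratio of the reduced 2x2 table
# (breast carriers-in-bin, breast non-carriers; ovarian carriers-in-bin,
# ovarian non-carriers). ROR < 1 marks the ovarian direction (OCCR),
# ROR > 1 the breast direction (BCCR).

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of the 2x2 table `(a, b; c, d)` (exposed cases,
#' unexposed cases; exposed controls, unexposed controls) with the Woolf
#' log-normal confidence interval and the matching two-sided z p-value. Zero
#' cells are handled with the Haldane-Anscombe correction: +0.5 to all four
#' cells of an affected table, keeping the interval finite.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf_level confidence level (default 0.95).
#' @param correction `"haldane"` (default) or `"none"`; with `"none"`, a
#'   zero cell is an error.
#' @return list with `or`, `ci_low`, `ci_high`, `log_se`, `p_value`,
#'   `corrected` (whether +0.5 was applied).
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95, correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop_rorscan("odds ratio requires four non-negative counts", "domain_error")
  }
  if (all(cells == 0)) {
    stop_rorscan("odds ratio undefined: all cells are zero", "domain_error")
  }
  corrected <- any(cells == 0)
  if (corrected) {
    if (correction == "none") {
      stop_rorscan("zero cell with correction = 'none'", "domain_error")
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    log_se = se,
    p_value = 2 * stats::pnorm(-abs(log(or) / se)),
    corrected = corrected
  )
}

#' ROR of a bin from the reduced breast/ovarian table
#'
#' The cancer-free arm cancels in the ratio of the two odds ratios, so the
#' ROR, its confidence interval and p-value are computed on the reduced 2x2
#' table of breast vs ovarian carriers-in-bin against gene-wide
#' non-carriers.
#'
#' @param b_bin breast-cancer subjects carrying a deleterious variant in the
#'   bin.
#' @param B_nc breast-cancer gene-wide non-carriers.
#' @param o_bin,O_nc ovarian analogues.
#' @param conf_level confidence level for the Woolf interval.
#' @return list with `ror`, `ci_low`, `ci_high`, `p_value`, `log_se`,
#'   `corrected`.
#' @export
bin_ror <- function(b_bin, B_nc, o_bin, O_nc, conf_level = 0.95) {
  res <- odds_ratio(b_bin, B_nc, o_bin, O_nc, conf_level = conf_level)
  names(res)[names(res) == "or"] <- "ror"
  res
}

#' Full per-bin statistics including the component odds ratios
#'
#' Computes the breast and ovarian odds ratios against the cancer-free arm
#' plus the ROR (on the reduced table, where the cancer-free arm cancels).
#' The identity `ror = or_breast / or_ovarian` is exact whenever no zero-cell
#' correction fires.
#'
#' @param b_bin,o_bin,c_bin carriers-in-bin among breast, ovarian and
#'   cancer-free subjects.
#' @param B_nc,O_nc,C_nc gene-wide non-carrier totals for the three arms.
#' @param conf_level confidence level.
#' @return one-row data frame with `or_breast`, `or_ovarian`, `ror`,
#'   `ci_low`, `ci_high`, `p_raw`.
#' @export
bin_stats <- function(b_bin, o_bin, c_bin, B_nc, O_nc, C_nc, conf_level = 0.95) {
  ob <- odds_ratio(b_bin, B_nc, c_bin, C_nc, conf_level = conf_level)
  oo <- odds_ratio(o_bin, O_nc, c_bin, C_nc, conf_level = conf_level)
  rr <- bin_ror(b_bin, B_nc, o_bin, O_nc, conf_level = conf_level)
  data.frame(
    or_breast = ob$or,
    or_ovarian = oo$or,
    ror = rr$ror,
    ci_low = rr$ci_low,
    ci_high = rr$ci_high,
    p_raw = rr$p_value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR correction (`stats::p.adjust(method = "BH")`),
#' returned in the input order. Applied per gene in the scan (m = the
#' gene's bin count).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order; `p_adj >= p_raw` elementwise.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_rorscan("p-values must lie in [0, 1]", "domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Call OCCR/BCCR regions from adjusted per-bin statistics
#'
#' A bin is called OCCR when its adjusted p-value is below `alpha` and
#' ROR < 1, BCCR when adjusted p < `alpha` and ROR > 1, otherwise none.
#'
#' @param stats data frame with columns `ror` and `p_adj`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return `stats` with a `call` column (`"OCCR"`, `"BCCR"` or `"none"`).
#' @export
call_regions <- function(stats, alpha = 0.05) {
  stats$call <- ifelse(
    stats$p_adj < alpha & stats$ror < 1, "OCCR",
    ifelse(stats$p_adj < alpha & stats$ror > 1, "BCCR", "none")
  )
  stats
}

#' Scan a gene for cluster regions
#'
#' End-to-end ROR scan: restricts to the gene's deleterious variants, bins
#' the carrier positions ([build_bins()]), forms per-bin phenotype counts,
#' computes ROR statistics, adjusts per gene with Benjamini-Hochberg and
#' calls regions.
#'
#' Subjects with both a breast and an ovarian primary are excluded from both
#' case arms by default (set `include_double_primary = TRUE` to count them
#' in both). Subjects carrying deleterious variants in more than one bin are
#' excluded from the phenotype counts with a warning.
#'
#' @param subjects,variants cohort tables ([read_cohort()],
#'   [simulate_cohort()]).
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param n_bins,carriers_per_bin passed to [build_bins()].
#' @param alpha significance level for region calls.
#' @param include_double_primary count breast-and-ovary subjects in both
#'   case arms instead of excluding them.
#' @param conf_level confidence level for Woolf intervals.
#' @return data frame with one row per bin: `gene`, `bin`, `n_carriers`,
#'   `start`, `end`, `or_breast`, `or_ovarian`, `ror`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_adj`, `call`.
#' @export
scan_regions <- function(subjects, variants, gene = c("BRCA1", "BRCA2"),
                         n_bins = NULL, carriers_per_bin = 60, alpha = 0.05,
                         include_double_primary = FALSE, conf_level = 0.95) {
  gene <- match.arg(gene)
  del <- variants[is_deleterious(variants$classification) & variants$gene == gene, , drop = FALSE]
  if (nrow(del) == 0L) stop_rorscan(sprintf("no deleterious %s variants", gene), "config_error")
  if (is.null(del$cds_base)) {
    coords <- parse_cdna(del$hgvs_c)
    del$cds_base <- coords$base
    del$cds_offset <- coords$offset
  }
  if (is.null(del$cds_offset)) del$cds_offset <- 0L

  # one multiset entry per subject per distinct position
  sp <- unique(data.frame(
    subject_id = del$subject_id,
    base = del$cds_base,
    offset = del$cds_offset,
    stringsAsFactors = FALSE
  ))
  bins <- build_bins(sp[, c("base", "offset")],
    n_bins = n_bins,
    carriers_per_bin = carriers_per_bin
  )
  sp$bin <- bin_assign(sp, bins)

  per_subject <- tapply(sp$bin, sp$subject_id, function(b) unique(b))
  multi <- names(per_subject)[vapply(per_subject, length, 1L) > 1L]
  if (length(multi) > 0L) {
    warn_rorscan(
      sprintf(
        "%d carrier%s with deleterious variants in more than one bin excluded from the scan",
        length(multi), if (length(multi) > 1) "s" else ""
      ),
      "multi_bin_carrier"
    )
  }
  subject_bin <- vapply(per_subject, `[`, 0L, 1L)
  subject_bin <- subject_bin[!(names(subject_bin) %in% multi)]

  status <- subjects$status[match(names(subject_bin), subjects$subject_id)]
  gene_carriers <- unique(del$subject_id)
  noncarrier <- !(subjects$subject_id %in% gene_carriers)

  breast_status <- "breast"
  ovary_status <- "ovary"
  if (include_double_primary) {
    breast_status <- c(breast_status, "breast_and_ovary")
    ovary_status <- c(ovary_status, "breast_and_ovary")
  }

  count_bin <- function(statuses) {
    as.integer(table(factor(subject_bin[status %in% statuses], levels = bins$bin)))
  }
  b_bin <- count_bin(breast_status)
  o_bin <- count_bin(ovary_status)
  c_bin <- count_bin("cancer_free")
  B_nc <- sum(noncarrier & subjects$status %in% breast_status)
  O_nc <- sum(noncarrier & subjects$status %in% ovary_status)
  C_nc <- sum(noncarrier & subjects$status == "cancer_free")

  stats <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    bin_stats(b_bin[i], o_bin[i], c_bin[i], B_nc, O_nc, C_nc, conf_level = conf_level)
  }))
  stats$p_adj <- bh_adjust(stats$p_raw)
  stats <- call_regions(stats, alpha = alpha)

  out <- cbind(
    data.frame(gene = gene, stringsAsFactors = FALSE),
    bins[, c("bin", "n_carriers", "start", "end")],
    stats
  )
  attr(out, "bins") <- bins
  attr(out, "excluded_multi_bin") <- multi
  out
}

#' Export called regions as a BED-like CDS-coordinate track
#'
#' @param scan scan table from [scan_regions()].
#' @param path output TSV path.
#' @return invisibly, the exported data frame (gene, start, end, call, ror).
#' @export
export_region_track <- function(scan, path) {
  bins <- attr(scan, "bins")
  called <- scan$call != "none"
  track <- data.frame(
    gene = scan$gene[called],
    start = if (is.null(bins)) scan$start[called] else bins$start_base[called],
    end = if (is.null(bins)) scan$end[called] else bins$end_base[called],
    call = scan$call[called],
    ror = scan$ror[called],
    stringsAsFactors = FALSE
  )
  utils::write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(track)
}
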