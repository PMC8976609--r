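# Per-province founder-mutation frequency summaries with sample-size
# masking.
#
# Map panels showing carrier spots by province are unreliable where few
# subjects were sampled; provinces with fewer than 100 subjects are masked
# light, fewer than 50 dark (nested: dark overrides light). Carrier counts
# for masked provinces are still reported (and included in national
# totals); the mask is a display flag.

#' Summarise founder-mutation carriers by province
#'
#' @param subjects,variants cohort tables.
#' @param mutations character vector of `"GENE:hgvs"` descriptions, e.g.
#'   `"BRCA1:c.5470_5477delATTGGGCA"`.
#' @param light_below,dark_below masking thresholds (default 100 and 50;
#'   boundary-exact, so exactly 100 subjects is unmasked and exactly 50 is
#'   light).
#' @return long data frame, one row per province x mutation: `province`,
#'   `sample_size`, `mask` (`"none"`, `"light"`, `"dark"`), `mutation`,
#'   `carriers`, `spot_size` (proportional to the carrier count). Subjects
#'   without a province fall into an `"unknown"` bucket.
#' @export
summarize_geography <- function(subjects, variants, mutations,
                                light_below = 100, dark_below = 50) {
  parts <- strsplit(mutations, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    stop_rorscan(
      sprintf("mutations must be 'GENE:hgvs': %s", paste(mutations[bad], collapse = ", ")),
      "config_error"
    )
  }
  gene <- vapply(parts, `[`, "", 1)
  hgvs <- vapply(parts, function(p) paste(p[-1], collapse = ":"), "")

  prov <- as.character(subjects$province)
  prov[is.na(prov) | prov == ""] <- "unknown"
  sizes <- table(prov)
  provinces <- names(sizes)
  mask <- ifelse(sizes < dark_below, "dark",
    ifelse(sizes < light_below, "light", "none"))

  del <- variants[is_deleterious(variants$classification), , drop = FALSE]
  rows <- lapply(seq_along(mutations), function(i) {
    ids <- unique(del$subject_id[del$gene == gene[i] & del$hgvs_c == hgvs[i]])
    carrier_prov <- prov[subjects$subject_id %in% ids]
    counts <- table(factor(carrier_prov, levels = provinces))
    data.frame(
      province = provinces,
      sample_size = as.integer(sizes),
      mask = unname(mask),
      mutation = mutations[i],
      carriers = as.integer(counts),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$spot_size <- out$carriers
  rownames(out) <- NULL
  out
}
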