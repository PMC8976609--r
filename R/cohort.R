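# Cohort domain model: subjects, variant calls, carrier summaries.
#
# A subject is one enrolled individual with a clinical status drawn from a
# frozen six-level vocabulary (breast, ovary, breast_and_ovary,
# breast_or_ovary_plus_other, other_site, cancer_free), an optional age at
# diagnosis/enrolment (>= 18), a tri-state family history and an optional
# province. A variant call is one deleterious-or-otherwise classified
# BRCA1/2 variant observed in one subject, keyed by its HGVS cDNA
# description. "Deleterious" means classification pathogenic or
# likely_pathogenic throughout the package.

.status_levels <- c(
  "breast", "ovary", "breast_and_ovary",
  "breast_or_ovary_plus_other", "other_site", "cancer_free"
)

.default_status_aliases <- c(
  "ovarian" = "ovary",
  "breast and ovary" = "breast_and_ovary",
  "breast or ovary and other sites" = "breast_or_ovary_plus_other",
  "breast or ovary plus other" = "breast_or_ovary_plus_other",
  "other sites" = "other_site",
  "other" = "other_site",
  "cancer free" = "cancer_free",
  "healthy" = "cancer_free",
  "control" = "cancer_free"
)

.fh_levels <- c("positive", "negative", "unknown")

.classification_levels <- c("pathogenic", "likely_pathogenic", "VUS", "other")

.classification_aliases <- c(
  "p" = "pathogenic",
  "lp" = "likely_pathogenic",
  "likely pathogenic" = "likely_pathogenic",
  "uncertain" = "VUS",
  "vus" = "VUS",
  "uncertain significance" = "VUS"
)

normalize_token <- function(x) gsub("[ -]+", "_", trimws(tolower(x)))

map_status <- function(status, aliases = NULL) {
  tok <- normalize_token(status)
  alias <- c(
    stats::setNames(.default_status_aliases, normalize_token(names(.default_status_aliases))),
    if (!is.null(aliases)) stats::setNames(as.character(aliases), normalize_token(names(aliases)))
  )
  hit <- !is.na(match(tok, names(alias)))
  tok[hit] <- alias[tok[hit]]
  bad <- is.na(tok) | !(tok %in% .status_levels)
  if (any(bad)) {
    stop_rorscan(
      sprintf(
        "unmappable clinical status at line%s %s: %s",
        if (sum(bad) > 1) "s" else "",
        paste(which(bad), collapse = ", "),
        paste(unique(status[bad]), collapse = ", ")
      ),
      "record_error"
    )
  }
  tok
}

map_family_history <- function(fh) {
  tok <- normalize_token(fh)
  tok[tok %in% c("yes", "pos", "fh+", "1")] <- "positive"
  tok[tok %in% c("no", "neg", "fh-", "0")] <- "negative"
  tok[is.na(tok) | tok == ""] <- "unknown"
  bad <- !(tok %in% .fh_levels)
  if (any(bad)) {
    stop_rorscan(
      sprintf(
        "unmappable family history at lines %s",
        paste(which(bad), collapse = ", ")
      ),
      "record_error"
    )
  }
  tok
}

map_classification <- function(cls) {
  tok <- normalize_token(cls)
  hit <- !is.na(match(tok, names(.classification_aliases)))
  tok[hit] <- .classification_aliases[tok[hit]]
  tok[!(tok %in% .classification_levels)] <- "other"
  tok
}

#' Flag deleterious variant calls
#'
#' Deleterious means classification `pathogenic` or `likely_pathogenic`.
#'
#' @param classification character vector of classifications.
#' @return logical vector.
#' @export
is_deleterious <- function(classification) {
  classification %in% c("pathogenic", "likely_pathogenic")
}

#' Read a cohort from delimited subject and variant tables
#'
#' Both files are UTF-8 delimited tables with a header row; the delimiter is
#' auto-detected between tab and comma. The subject table needs columns
#' `subject_id` and `status` (optional: `age`, `family_history`,
#' `province`); the variant table needs `subject_id`, `gene`, `hgvs_c` and
#' `classification`. Unknown columns are preserved but ignored. Variant CDS
#' coordinates are parsed on read ([parse_cdna()]) into `cds_base` /
#' `cds_offset` columns.
#'
#' @param subjects_path path to the subject table.
#' @param variants_path path to the variant table.
#' @param status_aliases optional named character vector mapping local status
#'   spellings onto the six canonical levels.
#' @return list with data frames `subjects` and `variants`.
#' @export
read_cohort <- function(subjects_path, variants_path, status_aliases = NULL) {
  subjects <- read_delim_auto(subjects_path)
  require_columns(subjects, c("subject_id", "status"), basename(subjects_path))
  variants <- read_delim_auto(variants_path)
  require_columns(
    variants, c("subject_id", "gene", "hgvs_c", "classification"),
    basename(variants_path)
  )

  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$status <- map_status(subjects$status, status_aliases)
  if (is.null(subjects$age)) subjects$age <- NA_real_
  subjects$age <- suppressWarnings(as.numeric(subjects$age))
  under <- !is.na(subjects$age) & subjects$age < 18
  if (any(under)) {
    stop_rorscan(
      sprintf(
        "subjects under 18 at lines %s (enrolment requires age >= 18)",
        paste(which(under), collapse = ", ")
      ),
      "record_error"
    )
  }
  subjects$family_history <- map_family_history(
    if (is.null(subjects$family_history)) rep(NA_character_, nrow(subjects)) else subjects$family_history
  )
  if (is.null(subjects$province)) subjects$province <- NA_character_

  variants$subject_id <- as.character(variants$subject_id)
  bad_gene <- !(variants$gene %in% c("BRCA1", "BRCA2"))
  if (any(bad_gene)) {
    stop_rorscan(
      sprintf(
        "unknown gene at lines %s: %s",
        paste(which(bad_gene), collapse = ", "),
        paste(unique(variants$gene[bad_gene]), collapse = ", ")
      ),
      "record_error"
    )
  }
  orphan <- !(variants$subject_id %in% subjects$subject_id)
  if (any(orphan)) {
    stop_rorscan(
      sprintf(
        "variant calls referencing absent subjects at lines %s: %s",
        paste(which(orphan), collapse = ", "),
        paste(unique(variants$subject_id[orphan]), collapse = ", ")
      ),
      "record_error"
    )
  }
  variants$classification <- map_classification(variants$classification)
  coords <- parse_cdna(variants$hgvs_c)
  variants$cds_base <- coords$base
  variants$cds_offset <- coords$offset

  list(subjects = subjects, variants = variants)
}

#' Write a cohort back to delimited tables
#'
#' Round-trip companion of [read_cohort()]: writes tab-separated subject and
#' variant tables that the reader accepts unchanged.
#'
#' @param cohort list with `subjects` and `variants` data frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "subjects.tsv")
  vp <- file.path(dir, "variants.tsv")
  utils::write.table(cohort$subjects, sp,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA"
  )
  vd <- cohort$variants
  vd$cds_base <- NULL
  vd$cds_offset <- NULL
  utils::write.table(vd, vp, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(c(subjects = sp, variants = vp))
}

#' Summarise carriers by clinical status, gene and mutation
#'
#' A subject carrying at least one deleterious variant counts once as a
#' carrier; carriage is defined per subject per gene, so a subject with
#' deleterious variants in both genes counts once in each gene's carrier
#' count but once in the overall total.
#'
#' @param subjects,variants cohort tables as returned by [read_cohort()] or
#'   [simulate_cohort()].
#' @return object of class `cohort_summary`: a list with `by_status`
#'   (status, n, carriers, non_carriers), `by_gene` carrier counts,
#'   `recurrence` (gene, hgvs_c, carriers) and `total_carriers`.
#' @export
summarize_carriers <- function(subjects, variants) {
  del <- variants[is_deleterious(variants$classification), , drop = FALSE]
  carrier_ids <- unique(del$subject_id)
  status <- factor(subjects$status, levels = .status_levels)
  n <- as.integer(table(status))
  carriers <- as.integer(table(status[subjects$subject_id %in% carrier_ids]))
  by_status <- data.frame(
    status = .status_levels,
    n = n,
    carriers = carriers,
    non_carriers = n - carriers,
    stringsAsFactors = FALSE
  )
  gene_subject <- unique(del[, c("gene", "subject_id")])
  by_gene <- data.frame(
    gene = c("BRCA1", "BRCA2"),
    carriers = c(
      sum(gene_subject$gene == "BRCA1"),
      sum(gene_subject$gene == "BRCA2")
    ),
    stringsAsFactors = FALSE
  )
  rec <- unique(del[, c("gene", "hgvs_c", "subject_id")])
  if (nrow(rec) == 0L) {
    recurrence <- data.frame(
      gene = character(0), hgvs_c = character(0),
      carriers = integer(0), stringsAsFactors = FALSE
    )
  } else {
    recurrence <- stats::aggregate(
      rec["subject_id"],
      by = rec[, c("gene", "hgvs_c")], FUN = length
    )
    names(recurrence)[3] <- "carriers"
    recurrence <- recurrence[order(-recurrence$carriers, recurrence$gene), ]
    rownames(recurrence) <- NULL
  }
  structure(
    list(
      by_status = by_status,
      by_gene = by_gene,
      recurrence = recurrence,
      total_carriers = length(carrier_ids),
      n_subjects = nrow(subjects)
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort of %d subjects, %d deleterious-mutation carriers\n",
    x$n_subjects, x$total_carriers
  ))
  print(x$by_status, row.names = FALSE)
  cat("\nPer-gene carriers:\n")
  print(x$by_gene, row.names = FALSE)
  invisible(x)
}

#' Write a cohort summary to delimited and JSON files
#'
#' @param summary a `cohort_summary`.
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, the summary.
#' @export
write_summary <- function(summary, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(summary$by_status, path_tsv,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(summary), path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}

#' Proportion with one-decimal percent formatting
#'
#' @param n numerator count.
#' @param d denominator count (> 0).
#' @return list with `n`, `d`, `proportion`, `percent` (numeric, one
#'   decimal) and `label` such as `"9.5% (50/527)"`.
#' @export
proportion_pct <- function(n, d) {
  if (is.na(d) || d <= 0) {
    stop_rorscan("undefined fraction: zero denominator", "domain_error")
  }
  p <- n / d
  pct <- as.numeric(sprintf("%.1f", 100 * p))
  list(
    n = n, d = d, proportion = p, percent = pct,
    label = sprintf("%.1f%% (%d/%d)", pct, n, d)
  )
}

#' Recurrence fraction of a mutation among a gene's carriers
#'
#' Fraction of the gene's deleterious-mutation carriers that carry the given
#' mutation, as used to rank founder/recurrent mutations.
#'
#' @param variants variant table.
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param mutation HGVS cDNA description of the mutation.
#' @param denominator optional explicit carrier denominator; by default the
#'   number of distinct subjects with any deleterious variant in `gene`
#'   (different published sentences use slightly different denominators for
#'   the same gene, so an explicit override is accepted).
#' @return as [proportion_pct()].
#' @export
recurrent_fraction <- function(variants, gene, mutation, denominator = NULL) {
  del <- variants[is_deleterious(variants$classification) & variants$gene == gene, , drop = FALSE]
  d <- denominator %||% length(unique(del$subject_id))
  n <- length(unique(del$subject_id[del$hgvs_c == mutation]))
  proportion_pct(n, d)
}
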