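# Bayes allelic penetrance estimation for individual recurrent mutations.
#
# Given the carrier frequency of a mutation among cases of the target cancer
# (f_case), among cancer-free controls (f_ctrl), and the population lifetime
# risk K of the cancer, Bayes inversion of the carrier frequencies gives the
# lifetime risk in carriers:
#
#   P(disease | carrier) = f_case * K / (f_case * K + f_ctrl * (1 - K))
#
# i.e. P(carrier) is mixed over disease status by K. The default baseline is
# K = 0.053, the estimated mean lifetime breast cancer risk for Chinese
# women from the Gail model; 0.35 is the conventional lower bound of
# carrier breast/ovarian cancer risk and is reported as a reference
# comparison. Zero control carriers give complete (100%) penetrance; equal
# case and control frequencies give the baseline K. No small-sample
# smoothing is applied by default (the complete-penetrance boundary requires
# the uncorrected estimator); `smooth = TRUE` adds 0.5 carriers / 1 subject
# to each arm.

#' Bayes allelic penetrance of a mutation
#'
#' @param f_case carrier frequency among cases of the target cancer, or a
#'   carrier count when `n_case` is given.
#' @param f_ctrl carrier frequency among cancer-free controls (conventionally
#'   the family-history-negative subset), or a count when `n_ctrl` is given.
#' @param K population lifetime risk of the cancer (default 0.053, breast
#'   cancer in Chinese women).
#' @param n_case,n_ctrl optional denominators; when given, `f_case` /
#'   `f_ctrl` are interpreted as carrier counts.
#' @param reference penetrance reference bound (default 0.35).
#' @param smooth add 0.5 carriers and 1 subject per arm (off by default).
#' @return object of class `penetrance_estimate`: list with `penetrance`,
#'   `above_reference`, `f_case`, `f_ctrl`, `K`, `reference`.
#' @examples
#' bayes_penetrance(f_case = 0.02, f_ctrl = 0.001) # 0.528
#' bayes_penetrance(f_case = 0.004, f_ctrl = 0) # complete penetrance
#' @export
bayes_penetrance <- function(f_case, f_ctrl, K = 0.053, n_case = NULL, n_ctrl = NULL,
                             reference = 0.35, smooth = FALSE) {
  if (!is.null(n_case)) f_case <- (f_case + 0.5 * smooth) / (n_case + smooth)
  if (!is.null(n_ctrl)) f_ctrl <- (f_ctrl + 0.5 * smooth) / (n_ctrl + smooth)
  if (is.na(K) || K <= 0 || K >= 1) {
    stop_rorscan("lifetime risk K must lie in (0, 1)", "domain_error")
  }
  if (any(is.na(c(f_case, f_ctrl))) || f_case < 0 || f_case > 1 || f_ctrl < 0 || f_ctrl > 1) {
    stop_rorscan("carrier frequencies must lie in [0, 1]", "domain_error")
  }
  if (f_case == 0 && f_ctrl == 0) {
    stop_rorscan("penetrance undefined: mutation observed in neither arm", "domain_error")
  }
  p <- f_case * K / (f_case * K + f_ctrl * (1 - K))
  structure(
    list(
      penetrance = p,
      above_reference = p >= reference,
      f_case = f_case, f_ctrl = f_ctrl, K = K, reference = reference
    ),
    class = "penetrance_estimate"
  )
}

#' @export
print.penetrance_estimate <- function(x, ...) {
  cat(sprintf(
    "Bayes allelic penetrance: %.3f (%s the %.2f reference; K = %.3f)\n",
    x$penetrance, if (x$above_reference) "at or above" else "below",
    x$reference, x$K
  ))
  invisible(x)
}

#' Carrier frequency of a mutation in a subject subset
#'
#' @param subjects,variants cohort tables.
#' @param gene,mutation the mutation (gene + HGVS cDNA description).
#' @param statuses clinical statuses defining the subset.
#' @param family_history `"any"`, `"positive"` or `"negative"`.
#' @return list with `freq`, `carriers`, `n`.
#' @export
mutation_carrier_frequency <- function(subjects, variants, gene, mutation,
                                       statuses, family_history = "any") {
  keep <- subjects$status %in% statuses
  if (family_history != "any") keep <- keep & subjects$family_history == family_history
  ids <- subjects$subject_id[keep]
  hit <- variants$gene == gene & variants$hgvs_c == mutation &
    is_deleterious(variants$classification) & variants$subject_id %in% ids
  carriers <- length(unique(variants$subject_id[hit]))
  list(freq = if (length(ids) > 0) carriers / length(ids) else NA_real_,
       carriers = carriers, n = length(ids))
}

#' Family-history-stratified penetrance of a mutation
#'
#' One Bayes allelic estimate per family-history stratum (positive,
#' negative) plus the pooled estimate. Case arm: breast-cancer subjects by
#' default. Control arm: cancer-free subjects; the pooled estimate uses the
#' family-history-negative subset by default (`controls = "fh_negative"`),
#' mirroring the convention of selecting family-history-negative cancer-free
#' women as the healthy control panel.
#'
#' @param subjects,variants cohort tables.
#' @param gene,mutation the target mutation.
#' @param K population lifetime risk.
#' @param case_status clinical status defining cases (default `"breast"`).
#' @param controls control set for the pooled stratum: `"fh_negative"` or
#'   `"all_cancer_free"`.
#' @param reference penetrance reference bound.
#' @return data frame with one row per stratum (`all`, `FH_positive`,
#'   `FH_negative`): counts, frequencies, `penetrance`, `above_reference`.
#'   Empty strata are skipped with a warning. Attribute
#'   `crosses_reference` flags strata straddling the reference bound.
#' @export
stratified_penetrance <- function(subjects, variants, gene, mutation, K = 0.053,
                                  case_status = "breast",
                                  controls = c("fh_negative", "all_cancer_free"),
                                  reference = 0.35) {
  controls <- match.arg(controls)
  pooled_fh <- if (controls == "fh_negative") "negative" else "any"
  strata <- list(
    all = list(case_fh = "any", ctrl_fh = pooled_fh),
    FH_positive = list(case_fh = "positive", ctrl_fh = "positive"),
    FH_negative = list(case_fh = "negative", ctrl_fh = "negative")
  )
  rows <- lapply(names(strata), function(s) {
    fh <- strata[[s]]
    ca <- mutation_carrier_frequency(subjects, variants, gene, mutation,
      statuses = case_status, family_history = fh$case_fh
    )
    co <- mutation_carrier_frequency(subjects, variants, gene, mutation,
      statuses = "cancer_free", family_history = fh$ctrl_fh
    )
    if (ca$n == 0 || co$n == 0) {
      warn_rorscan(sprintf("stratum %s skipped: empty arm", s), "empty_stratum")
      return(NULL)
    }
    if (ca$freq == 0 && co$freq == 0) {
      warn_rorscan(sprintf("stratum %s skipped: mutation unobserved", s), "empty_stratum")
      return(NULL)
    }
    est <- bayes_penetrance(ca$freq, co$freq, K = K, reference = reference)
    data.frame(
      stratum = s,
      n_case = ca$n, carriers_case = ca$carriers, f_case = ca$freq,
      n_ctrl = co$n, carriers_ctrl = co$carriers, f_ctrl = co$freq,
      penetrance = est$penetrance,
      above_reference = est$above_reference,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_rorscan("no stratum with data for the mutation", "domain_error")
  fh_rows <- out$stratum != "all"
  attr(out, "crosses_reference") <-
    sum(fh_rows) >= 2 && length(unique(out$above_reference[fh_rows])) > 1
  out
}
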