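# Seed-deterministic synthetic cohorts, STR panels and penetrance sampling
# distributions.
#
# The cohort generator emulates a nationwide case-control screening study:
# fixed numbers of breast-cancer cases, ovarian-cancer cases and cancer-free
# controls; deleterious variants placed along the CDS as a mixture of a
# uniform background and founder-hotspot point masses; and a region map
# specifying the designed ratio-of-odds-ratios (ROR) per CDS interval.
#
# Phenotype structure: carrier status is drawn per arm (a multinomial
# conditional construction rather than a full liability model). Ovarian
# carriers draw positions from the base density f; breast carriers from the
# tilted density f * rho / Z, where rho is the region map and Z its
# normaliser. With the breast carrier odds set to (ovarian odds) * Z, the
# ROR of any interval on which rho is constant converges to exactly rho as
# n grows; `true_ror()` gives the designed value of any interval in closed
# form, which the recovery tests use as the estimand.

#' Simulation configuration
#'
#' Defaults mirror the screening-study scale this scan was designed for:
#' 2,400 breast cases, 1,697 ovarian cases and 3,641 cancer-free controls;
#' a 5,592-bp CDS (BRCA1); a 2.5% control carrier frequency (90/3,641); and
#' an ovarian-arm carrier odds of 0.24 (332/1,365).
#'
#' @param seed mandatory integer seed; all generators restore the caller's
#'   RNG state.
#' @param n_breast,n_ovarian,n_controls arm sizes.
#' @param cds_length CDS length in bp.
#' @param regions optional data frame `start`, `end`, `ror`: non-overlapping
#'   CDS intervals with their designed ROR (1 elsewhere).
#' @param hotspots optional data frame `position`, `fraction` and optionally
#'   `label` (HGVS description): founder point masses in the position
#'   density; fractions must sum to < 1.
#' @param control_carrier_freq carrier probability in the cancer-free arm.
#' @param odds_ovarian carrier odds in the ovarian arm.
#' @param odds_breast carrier odds in the breast arm; `NULL` (default)
#'   derives it so that intervals outside `regions` have designed ROR 1 and
#'   each region's designed ROR equals its `ror` entry.
#' @param gene gene label for the variant table.
#' @param str_markers,str_alleles STR panel size and alleles per marker.
#' @param recomb per-marker recombination fraction to the focal locus
#'   (length `str_markers`); defaults decay toward the central marker.
#' @param founder_generations age of the founder mutation in generations.
#' @param n_founder_carriers,n_str_controls subjects in the haplotype panel.
#' @param K population lifetime risk carried along for penetrance work.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_breast = 2400, n_ovarian = 1697, n_controls = 3641,
                       cds_length = 5592,
                       regions = NULL,
                       hotspots = NULL,
                       control_carrier_freq = 0.025,
                       odds_ovarian = 0.24,
                       odds_breast = NULL,
                       gene = "BRCA1",
                       str_markers = 9,
                       str_alleles = 6,
                       recomb = NULL,
                       founder_generations = 100,
                       n_founder_carriers = 31,
                       n_str_controls = 50,
                       K = 0.053) {
  if (missing(seed) || is.na(seed)) stop_rorscan("a seed is mandatory", "config_error")
  if (!is.null(regions)) {
    require_columns(regions, c("start", "end", "ror"), "region map")
    regions <- regions[order(regions$start), , drop = FALSE]
    if (any(regions$ror <= 0)) stop_rorscan("region ROR must be > 0", "config_error")
    if (any(regions$start < 1 | regions$end > cds_length | regions$start > regions$end)) {
      stop_rorscan("regions must lie within [1, cds_length]", "config_error")
    }
    if (nrow(regions) > 1 && any(regions$start[-1] <= regions$end[-nrow(regions)])) {
      stop_rorscan("regions must not overlap", "config_error")
    }
  }
  if (!is.null(hotspots)) {
    require_columns(hotspots, c("position", "fraction"), "hotspot table")
    if (sum(hotspots$fraction) >= 1 || any(hotspots$fraction <= 0)) {
      stop_rorscan("hotspot fractions must be positive and sum to < 1", "config_error")
    }
    if (is.null(hotspots$label)) {
      hotspots$label <- sprintf("c.%d_%ddelAT", hotspots$position, hotspots$position + 1L)
    }
  }
  if (control_carrier_freq < 0 || control_carrier_freq > 1) {
    stop_rorscan("control_carrier_freq must lie in [0, 1]", "config_error")
  }
  recomb <- recomb %||% {
    half <- ceiling(str_markers / 2)
    d <- abs(seq_len(str_markers) - half)
    pmin(0.5, 0.005 + 0.01 * d)
  }
  if (length(recomb) != str_markers || any(recomb < 0 | recomb > 0.5)) {
    stop_rorscan("recomb must have one fraction in [0, 0.5] per marker", "config_error")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_breast = n_breast, n_ovarian = n_ovarian, n_controls = n_controls,
      cds_length = cds_length, regions = regions, hotspots = hotspots,
      control_carrier_freq = control_carrier_freq,
      odds_ovarian = odds_ovarian, odds_breast = odds_breast,
      gene = gene,
      str_markers = str_markers, str_alleles = str_alleles, recomb = recomb,
      founder_generations = founder_generations,
      n_founder_carriers = n_founder_carriers, n_str_controls = n_str_controls,
      K = K
    ),
    class = "sim_config"
  )
}

# Mixture components of the position density: hotspot atoms plus uniform
# segments split at region boundaries. w_f is the base density weight,
# w_b the unnormalised breast tilt f * rho; Z = sum(w_b).
position_mixture <- function(config) {
  L <- config$cds_length
  reg <- config$regions
  breaks <- sort(unique(c(1, if (!is.null(reg)) c(reg$start, reg$end + 1), L + 1)))
  seg_start <- breaks[-length(breaks)]
  seg_end <- breaks[-1] - 1
  keep <- seg_end >= seg_start
  seg_start <- seg_start[keep]
  seg_end <- seg_end[keep]
  rho_at <- function(pos) {
    r <- rep(1, length(pos))
    if (!is.null(reg)) {
      for (i in seq_len(nrow(reg))) {
        r[pos >= reg$start[i] & pos <= reg$end[i]] <- reg$ror[i]
      }
    }
    r
  }
  hs <- config$hotspots
  H <- if (is.null(hs)) 0 else sum(hs$fraction)
  atom_pos <- if (is.null(hs)) integer(0) else hs$position
  atom_label <- if (is.null(hs)) character(0) else hs$label
  atom_wf <- if (is.null(hs)) numeric(0) else hs$fraction
  seg_wf <- (1 - H) * (seg_end - seg_start + 1) / L
  rho <- c(rho_at(atom_pos), rho_at(seg_start))
  wf <- c(atom_wf, seg_wf)
  list(
    atom_pos = atom_pos, atom_label = atom_label,
    seg_start = seg_start, seg_end = seg_end,
    n_atoms = length(atom_pos),
    w_f = wf, w_b = wf * rho, Z = sum(wf * rho), rho = rho
  )
}

#' Designed ROR of a CDS interval under a simulation configuration
#'
#' Closed-form value the scan estimates for the interval: the breast-vs-
#' ovarian carrier-odds ratio implied by the configuration's region map,
#' hotspots and arm odds.
#'
#' @param config a [sim_config()].
#' @param start,end interval bounds (CDS bp, inclusive).
#' @return the designed ROR.
#' @export
true_ror <- function(config, start, end) {
  mix <- position_mixture(config)
  omega_b <- config$odds_breast %||% (config$odds_ovarian * mix$Z)
  in_atom <- mix$atom_pos >= start & mix$atom_pos <= end
  ov <- pmax(0, pmin(mix$seg_end, end) - pmax(mix$seg_start, start) + 1) /
    (mix$seg_end - mix$seg_start + 1)
  frac <- c(as.numeric(in_atom), ov)
  f_int <- sum(mix$w_f * frac)
  fr_int <- sum(mix$w_b * frac)
  (omega_b / (config$odds_ovarian * mix$Z)) * (fr_int / f_int)
}

sample_positions <- function(n, mix, weights) {
  if (n == 0L) {
    return(data.frame(position = integer(0), label = character(0), stringsAsFactors = FALSE))
  }
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  pos <- integer(n)
  is_atom <- comp <= mix$n_atoms
  pos[is_atom] <- mix$atom_pos[comp[is_atom]]
  seg_i <- comp[!is_atom] - mix$n_atoms
  lo <- mix$seg_start[seg_i]
  hi <- mix$seg_end[seg_i]
  pos[!is_atom] <- lo + floor(stats::runif(sum(!is_atom)) * (hi - lo + 1))
  label <- sprintf("c.%ddelA", pos)
  label[is_atom] <- mix$atom_label[comp[is_atom]]
  data.frame(position = pos, label = label, stringsAsFactors = FALSE)
}

.province_weights <- c(
  Guangdong = 0.17, Jiangsu = 0.12, Shandong = 0.11, Henan = 0.10,
  Sichuan = 0.09, Hebei = 0.08, Hunan = 0.08, Zhejiang = 0.07,
  Chongqing = 0.06, Yunnan = 0.05, Ningxia = 0.04, Qinghai = 0.024,
  Tibet = 0.006
)

#' Simulate a case-control cohort with designed cluster regions
#'
#' Generates subject and variant tables with the statistical structure the
#' scan assumes; see [sim_config()] for the knobs. Given the same
#' configuration (including seed) the output is byte-identical.
#'
#' @param config a [sim_config()].
#' @return list with `subjects`, `variants` and the echoed `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    mix <- position_mixture(config)
    omega_b <- config$odds_breast %||% (config$odds_ovarian * mix$Z)
    p_breast <- omega_b / (1 + omega_b)
    p_ovary <- config$odds_ovarian / (1 + config$odds_ovarian)

    n <- c(config$n_breast, config$n_ovarian, config$n_controls)
    status <- rep(c("breast", "ovary", "cancer_free"), n)
    ids <- sprintf("S%05d", seq_along(status))

    age_mean <- c(breast = 45, ovary = 52, cancer_free = 36)[status]
    age <- pmax(18, round(stats::rnorm(length(status), age_mean, 9)))
    fh_case <- c(0.25, 0.65, 0.10) # positive / negative / unknown
    fh_ctrl <- c(0.18, 0.72, 0.10)
    fh <- ifelse(status == "cancer_free",
      sample(c("positive", "negative", "unknown"), length(status), TRUE, fh_ctrl),
      sample(c("positive", "negative", "unknown"), length(status), TRUE, fh_case)
    )
    province <- sample(names(.province_weights), length(status), TRUE, .province_weights)

    subjects <- data.frame(
      subject_id = ids, status = status, age = age,
      family_history = fh, province = province,
      stringsAsFactors = FALSE
    )

    carrier_p <- c(p_breast, p_ovary, config$control_carrier_freq)[
      match(status, c("breast", "ovary", "cancer_free"))
    ]
    carrier <- stats::runif(length(status)) < carrier_p

    draws <- lapply(c("breast", "ovary", "cancer_free"), function(st) {
      idx <- which(carrier & status == st)
      w <- if (st == "breast") mix$w_b else mix$w_f
      cbind(sample_positions(length(idx), mix, w), subject_id = ids[idx])
    })
    pos <- do.call(rbind, draws)
    variants <- data.frame(
      subject_id = pos$subject_id,
      gene = config$gene,
      hgvs_c = pos$label,
      classification = "pathogenic",
      cds_base = pos$position,
      cds_offset = 0L,
      stringsAsFactors = FALSE
    )
    variants <- variants[order(match(variants$subject_id, ids)), , drop = FALSE]
    rownames(variants) <- NULL
    list(subjects = subjects, variants = variants, config = config)
  })
}

#' Simulate an STR haplotype panel with a shared founder core
#'
#' Founder chromosomes descend from one ancestral haplotype through a
#' star genealogy: over `founder_generations` meioses, marker j's allele
#' survives unreplaced with probability `(1 - recomb[j])^g`, otherwise it is
#' redrawn from the population allele frequencies. Control chromosomes are
#' population draws. Carrier subjects carry the founder chromosome as
#' chromosome 1 plus one population chromosome; this convention is what
#' [core_haplotype_sharing()] assumes by default.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (unphased table), `phased` (per-chromosome
#'   table), `carriers` (ids), `ancestral` (ancestral alleles),
#'   `allele_freqs` (marker x allele matrix) and `expected_sharing`, the
#'   closed-form expected frequency of the ancestral allele among founder
#'   chromosomes: `(1-c_j)^g + (1 - (1-c_j)^g) * p_j(ancestral)`.
#' @export
simulate_str_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    m <- config$str_markers
    A <- config$str_alleles
    markers <- if (m == 9) brca1_str_panel() else sprintf("M%02d", seq_len(m))
    freqs <- t(vapply(seq_len(m), function(j) {
      w <- stats::rgamma(A, shape = 1.5)
      w / sum(w)
    }, numeric(A)))
    rownames(freqs) <- markers
    colnames(freqs) <- as.character(seq_len(A))
    ancestral <- vapply(seq_len(m), function(j) {
      sample.int(A, 1, prob = freqs[j, ])
    }, 0L)

    g <- config$founder_generations
    surv <- (1 - config$recomb)^g

    draw_pop_chrom <- function() {
      vapply(seq_len(m), function(j) sample.int(A, 1, prob = freqs[j, ]), 0L)
    }
    founder_chrom <- function() {
      keep <- stats::runif(m) < surv
      al <- draw_pop_chrom()
      al[keep] <- ancestral[keep]
      al
    }

    carrier_ids <- sprintf("FC%03d", seq_len(config$n_founder_carriers))
    control_ids <- sprintf("CT%03d", seq_len(config$n_str_controls))

    chrom_rows <- function(id, chrom, alleles) {
      data.frame(
        subject_id = id, chrom_index = chrom, marker = markers,
        allele = as.character(alleles), stringsAsFactors = FALSE
      )
    }
    phased <- do.call(rbind, c(
      lapply(carrier_ids, function(id) {
        rbind(chrom_rows(id, 1L, founder_chrom()), chrom_rows(id, 2L, draw_pop_chrom()))
      }),
      lapply(control_ids, function(id) {
        rbind(chrom_rows(id, 1L, draw_pop_chrom()), chrom_rows(id, 2L, draw_pop_chrom()))
      })
    ))
    a1 <- phased[phased$chrom_index == 1L, ]
    a2 <- phased[phased$chrom_index == 2L, ]
    genotypes <- data.frame(
      subject_id = a1$subject_id, marker = a1$marker,
      allele1 = a1$allele, allele2 = a2$allele, stringsAsFactors = FALSE
    )
    expected_sharing <- surv + (1 - surv) * freqs[cbind(seq_len(m), ancestral)]
    list(
      genotypes = genotypes, phased = phased, carriers = carrier_ids,
      ancestral = stats::setNames(as.character(ancestral), markers),
      allele_freqs = freqs,
      expected_sharing = stats::setNames(expected_sharing, markers)
    )
  })
}

#' Sample case/control carrier frequencies under a true penetrance
#'
#' Generative model for penetrance parameter-recovery checks: carriers have
#' population frequency `q` and lifetime risk `penetrance`; non-carriers'
#' risk is set so the population prevalence equals `K`. Case-control
#' sampling then gives carrier frequencies
#' `f_case ~ Binom(n_case, q * penetrance / K) / n_case` and
#' `f_ctrl ~ Binom(n_ctrl, q * (1 - penetrance) / (1 - K)) / n_ctrl`, for
#' which the Bayes allelic estimator is consistent.
#'
#' @param n_case,n_ctrl arm sizes.
#' @param q population carrier frequency; needs `q * penetrance <= K`.
#' @param penetrance true lifetime risk in carriers.
#' @param K population lifetime risk.
#' @return list with `f_case`, `f_ctrl` and the underlying counts.
#' @export
simulate_penetrance_counts <- function(n_case, n_ctrl, q, penetrance, K = 0.053) {
  if (q < 0 || q > 1 || penetrance < 0 || penetrance > 1) {
    stop_rorscan("q and penetrance must lie in [0, 1]", "config_error")
  }
  if (q * penetrance > K) {
    stop_rorscan("infeasible: q * penetrance exceeds the population risk K", "config_error")
  }
  fc <- q * penetrance / K
  fh <- q * (1 - penetrance) / (1 - K)
  x_case <- stats::rbinom(1, n_case, fc)
  x_ctrl <- stats::rbinom(1, n_ctrl, fh)
  list(
    f_case = x_case / n_case, f_ctrl = x_ctrl / n_ctrl,
    x_case = x_case, x_ctrl = x_ctrl
  )
}
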