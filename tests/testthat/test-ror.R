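test_that("odds ratios follow the cross-product with Woolf intervals", {
  expect_equal(odds_ratio(1, 1, 1, 1)$or, 1)

  # direct cross-product arithmetic
  o <- odds_ratio(10, 90, 5, 95)
  expect_equal(o$or, (10 * 95) / (90 * 5), tolerance = 1e-12)
  expect_equal(o$or, 2.1111, tolerance = 1e-4)
  expect_equal(o$ci_low, exp(log(o$or) - 1.96 * sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)),
    tolerance = 1e-4
  )

  # whole-gene breast OR from the published status table
  tab <- clinical_summary_counts()
  br <- tab[tab$status == "breast", ]
  cf <- tab[tab$status == "cancer_free", ]
  o2 <- odds_ratio(br$carriers, br$non_carriers, cf$carriers, cf$non_carriers)
  expect_equal(o2$or, (285 * 3551) / (2115 * 90), tolerance = 1e-12)
  expect_equal(o2$or, 5.317, tolerance = 1e-3)

  expect_error(odds_ratio(0, 0, 0, 0), class = "rorscan_domain_error")
  # zero cells are finite under the Haldane-Anscombe correction
  oz <- odds_ratio(0, 10, 5, 5)
  expect_true(is.finite(oz$or) && is.finite(oz$ci_low))
  expect_true(oz$corrected)
  expect_error(odds_ratio(0, 10, 5, 5, correction = "none"), class = "rorscan_domain_error")
})

test_that("the cancer-free arm cancels exactly in the ROR", {
  # equal carrier rates in both case arms give ROR 1
  expect_equal(bin_ror(10, 1000, 9, 900)$ror, 1)

  # designed example: identical for any control counts
  r <- bin_ror(10, 1000, 30, 900)$ror
  expect_equal(r, (10 / 1000) / (30 / 900), tolerance = 1e-12)
  for (seed in 1:25) {
    set.seed(seed)
    s <- bin_stats(
      b_bin = 10, o_bin = 30, c_bin = sample(0:500, 1),
      B_nc = 1000, O_nc = 900, C_nc = sample(1:5000, 1)
    )
    expect_equal(s$ror, r, tolerance = 1e-12)
  }

  # and ror = or_breast / or_ovarian when no correction fires
  s <- bin_stats(12, 20, 7, 800, 600, 2000)
  expect_equal(s$ror, s$or_breast / s$or_ovarian, tolerance = 1e-12)
})

test_that("ROR increases strictly with the breast carrier count", {
  rors <- vapply(5:30, function(b) bin_ror(b, 1000, 20, 900)$ror, 0)
  expect_true(all(diff(rors) > 0))
})

test_that("BH adjustment matches the published FDR columns exactly", {
  pub <- published_bin_scan()
  p1 <- pub$p_raw[pub$gene == "BRCA1"]
  expect_equal(
    bh_adjust(p1),
    c(0.63, 0.6189, 0.0012186, 0.8066, 0.6189, 0.7542, 0.27342, 0.48555, 0.0012186),
    tolerance = 1e-10
  )
  p2 <- pub$p_raw[pub$gene == "BRCA2"]
  expect_equal(
    bh_adjust(p2),
    c(0.012425, 0.9981, 0.1005, 0.044725, 0.285125),
    tolerance = 1e-10
  )
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "rorscan_domain_error")
})

test_that("BH agrees with the step-up definition on all permutations", {
  base_sets <- list(
    c(0.001, 0.02, 0.04, 0.049, 0.3, 0.9),
    c(0.5, 0.5, 0.01, 0.04),
    c(0.0001539, 0.0002708, 0.09114, 0.8066)
  )
  for (p in base_sets) {
    perms <- all_perms(p)
    for (i in seq_len(nrow(perms))) {
      expect_equal(bh_adjust(perms[i, ]), bh_oracle(perms[i, ]), tolerance = 1e-12)
    }
  }
})

test_that("region calls follow the adjusted p-value and ROR direction", {
  stats <- data.frame(
    ror = c(0.29, 3.47, 0.49, 1.0),
    p_adj = c(0.0012186, 0.012425, 0.1005, 0.03)
  )
  called <- call_regions(stats, alpha = 0.05)
  expect_equal(called$call, c("OCCR", "BCCR", "none", "none"))
})

test_that("the scan ties the pieces together on a synthetic cohort", {
  cfg <- sim_config(
    seed = 301,
    regions = data.frame(start = 1154, end = 2111, ror = 0.25)
  )
  sim <- simulate_cohort(cfg)
  scan <- scan_regions(sim$subjects, sim$variants, "BRCA1", n_bins = 9)
  expect_equal(nrow(scan), 9L)
  expect_true(all(scan$p_adj >= scan$p_raw))
  expect_true(all(scan$ci_low <= scan$ror & scan$ror <= scan$ci_high))
  expect_equal(scan$p_adj, bh_adjust(scan$p_raw))
  # the designed ovarian region is called in the right direction
  hit <- scan$call == "OCCR"
  expect_true(any(hit))
  expect_true(all(scan$ror[hit] < 1))

  # track export carries only called bins
  path <- withr::local_tempfile(fileext = ".tsv")
  track <- export_region_track(scan, path)
  expect_equal(nrow(track), sum(scan$call != "none"))
  expect_true(file.exists(path))
})

test_that("double-primary subjects are excluded from both case arms by default", {
  subjects <- make_subjects(c("breast", "ovary", "breast_and_ovary", "cancer_free", "cancer_free"))
  variants <- make_variants(
    c("S0001", "S0002", "S0003"),
    c("c.100delA", "c.200delA", "c.100delA")
  )
  scan <- scan_regions(subjects, variants, "BRCA1", n_bins = 2)
  expect_equal(sum(scan$n_carriers), 3L) # binning counts all carriers
  # but the double-primary subject sits in neither case arm, so including
  # it must change the statistics
  scan2 <- scan_regions(subjects, variants, "BRCA1",
    n_bins = 2,
    include_double_primary = TRUE
  )
  expect_false(identical(scan$ror, scan2$ror))
})

test_that("multi-bin carriers are dropped from the scan with a warning", {
  subjects <- make_subjects(rep(c("breast", "ovary"), 4))
  variants <- make_variants(
    c("S0001", "S0001", "S0002", "S0003", "S0004"),
    c("c.100delA", "c.900delA", "c.100delA", "c.900delA", "c.500delA")
  )
  expect_warning(
    scan_regions(subjects, variants, "BRCA1", n_bins = 2),
    class = "rorscan_multi_bin_carrier"
  )
})
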