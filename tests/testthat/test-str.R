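make_genotypes <- function(ids, marker, a1, a2) {
  data.frame(
    subject_id = ids, marker = marker,
    allele1 = as.character(a1), allele2 = as.character(a2),
    stringsAsFactors = FALSE
  )
}

test_that("identical allele distributions give a null chi-square", {
  ca <- make_genotypes(sprintf("C%02d", 1:20), "D17S855", rep(c("3", "5"), 10), rep(c("5", "3"), 10))
  co <- make_genotypes(sprintf("H%02d", 1:30), "D17S855", rep(c("3", "5"), 15), rep(c("5", "3"), 15))
  res <- allele_freq_test(ca, co, "D17S855")
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("the Pearson statistic matches its hand computation on a 2x2 table", {
  # carriers: 40 copies of allele 3, 0 of allele 5; controls 25 / 25
  ca <- make_genotypes(sprintf("C%02d", 1:20), "D17S1323", "3", "3")
  co <- make_genotypes(sprintf("H%02d", 1:25), "D17S1323", "3", "5")
  res <- allele_freq_test(ca, co, "D17S1323")
  # N * (ad - bc)^2 / (row1 * row2 * col1 * col2)
  hand <- 90 * (40 * 25 - 0 * 25)^2 / (40 * 50 * 65 * 25)
  expect_equal(res$chi2, hand, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  # margins conserve allele counts: two per typed subject
  expect_equal(sum(res$table), 2 * (20 + 25))

  # symmetric under group relabelling
  swapped <- allele_freq_test(co, ca, "D17S1323")
  expect_equal(swapped$chi2, res$chi2, tolerance = 1e-12)
})

test_that("degenerate and misconfigured tables are handled explicitly", {
  ca <- make_genotypes(sprintf("C%02d", 1:5), "D17S800", "7", "7")
  co <- make_genotypes(sprintf("H%02d", 1:5), "D17S800", "7", "7")
  expect_message(res <- allele_freq_test(ca, co, "D17S800"), "monomorphic")
  expect_equal(res$df, 0L)
  expect_true(is.na(res$p_value))

  expect_error(allele_freq_test(ca, co, "D99S999"), class = "rorscan_config_error")
  expect_error(
    allele_freq_test(ca[0, ], co, "D17S800"),
    class = "rorscan_config_error"
  )
})

test_that("rare-allele pooling collapses sparse classes when asked", {
  ca <- make_genotypes(sprintf("C%02d", 1:10), "D17S791", c(rep("3", 9), "9"), "3")
  co <- make_genotypes(sprintf("H%02d", 1:10), "D17S791", "3", c(rep("5", 9), "11"))
  pooled <- allele_freq_test(ca, co, "D17S791", pool_rare = TRUE, min_count = 5)
  expect_true("other" %in% colnames(pooled$table))
  unpooled <- allele_freq_test(ca, co, "D17S791")
  expect_gt(ncol(unpooled$table), ncol(pooled$table))
})

test_that("core haplotype sharing flags a founder effect when present", {
  markers <- brca1_str_panel()
  one_chrom <- function(id, chrom, alleles) {
    data.frame(
      subject_id = id, chrom_index = chrom, marker = markers,
      allele = as.character(alleles), stringsAsFactors = FALSE
    )
  }
  # all carrier chromosomes identical; controls spread over other alleles
  carriers <- sprintf("C%02d", 1:10)
  phased <- rbind(
    do.call(rbind, lapply(carriers, function(id) {
      rbind(one_chrom(id, 1L, rep("4", 9)), one_chrom(id, 2L, rep(c("1", "2"), length.out = 9)))
    })),
    do.call(rbind, lapply(sprintf("H%02d", 1:10), function(id) {
      rbind(one_chrom(id, 1L, rep(c("1", "2", "3", "4"), length.out = 9)),
            one_chrom(id, 2L, rep(c("2", "3"), length.out = 9)))
    }))
  )
  sh <- core_haplotype_sharing(phased, carriers)
  expect_equal(sh$summary$carrier_freq, rep(1, 9))
  expect_true(sh$founder_effect)

  # carrier chromosomes indistinguishable from controls: no founder flag
  same <- rbind(
    do.call(rbind, lapply(carriers, function(id) {
      rbind(one_chrom(id, 1L, rep("5", 9)), one_chrom(id, 2L, rep("5", 9)))
    })),
    do.call(rbind, lapply(sprintf("H%02d", 1:10), function(id) {
      rbind(one_chrom(id, 1L, rep("5", 9)), one_chrom(id, 2L, rep("5", 9)))
    }))
  )
  sh_same <- core_haplotype_sharing(same, carriers)
  expect_false(sh_same$founder_effect)

  # genotype-style (unphased) input is refused with direction to phase first
  geno <- make_genotypes(carriers, "D17S855", "4", "4")
  expect_error(core_haplotype_sharing(geno, carriers), class = "rorscan_contract_error")
})

test_that("simulated founder sharing decays with recombination distance", {
  cfg <- sim_config(
    seed = 77, founder_generations = 60,
    recomb = c(0.05, 0.03, 0.015, 0.005, 0.001, 0.005, 0.015, 0.03, 0.05)
  )
  reps <- 40
  dev <- matrix(NA_real_, reps, cfg$str_markers)
  shar <- matrix(NA_real_, reps, cfg$str_markers)
  for (r in seq_len(reps)) {
    cfg_r <- sim_config(
      seed = 7000 + r, founder_generations = 60,
      recomb = cfg$recomb
    )
    pan <- simulate_str_panel(cfg_r)
    founder <- pan$phased[pan$phased$chrom_index == 1L &
      pan$phased$subject_id %in% pan$carriers, ]
    obs <- vapply(names(pan$ancestral), function(m) {
      mean(founder$allele[founder$marker == m] == pan$ancestral[m])
    }, 0)
    shar[r, ] <- obs
    dev[r, ] <- obs - pan$expected_sharing
  }
  se <- apply(dev, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(dev)) <= 3 * se + 1e-9))
  # monotone decay away from the focal marker on average
  avg <- colMeans(shar)
  expect_gt(avg[5], avg[1])
  expect_gt(avg[5], avg[9])
})

test_that("the panel-wide test table carries optional BH adjustment", {
  cfg <- sim_config(seed = 5150, founder_generations = 40)
  pan <- simulate_str_panel(cfg)
  carriers_g <- pan$genotypes[pan$genotypes$subject_id %in% pan$carriers, ]
  controls_g <- pan$genotypes[!(pan$genotypes$subject_id %in% pan$carriers), ]
  res <- str_panel_test(carriers_g, controls_g, adjust = TRUE)
  expect_equal(nrow(res), 9L)
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_adj[ok] >= res$p_value[ok]))
})
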