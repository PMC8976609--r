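test_that("the Bayes allelic estimator reproduces its boundary behaviour", {
  # zero control carriers: complete penetrance
  expect_equal(bayes_penetrance(0.004, 0)$penetrance, 1)
  expect_true(bayes_penetrance(0.004, 0)$above_reference)
  # no enrichment: the population baseline
  for (f in c(0.001, 0.01, 0.2)) {
    expect_equal(bayes_penetrance(f, f)$penetrance, 0.053, tolerance = 1e-12)
  }
  # direct evaluation of the formula
  expect_equal(bayes_penetrance(0.02, 0.001)$penetrance, 0.5281515, tolerance = 1e-6)
  expect_false(bayes_penetrance(0.02, 0.001, K = 0.053)$penetrance >= 1)

  expect_error(bayes_penetrance(0, 0), class = "rorscan_domain_error")
  expect_error(bayes_penetrance(0.5, 0.1, K = 0), class = "rorscan_domain_error")
  expect_error(bayes_penetrance(1.2, 0.1), class = "rorscan_domain_error")
})

test_that("penetrance is monotone in the two carrier frequencies", {
  f_case <- seq(0.001, 0.2, length.out = 30)
  up <- vapply(f_case, function(f) bayes_penetrance(f, 0.005)$penetrance, 0)
  expect_true(all(diff(up) > 0))
  f_ctrl <- seq(0.0005, 0.05, length.out = 30)
  down <- vapply(f_ctrl, function(f) bayes_penetrance(0.02, f)$penetrance, 0)
  expect_true(all(diff(down) < 0))
  # limits: K as the ratio approaches 1, 0 as f_case vanishes
  expect_lt(bayes_penetrance(1e-9, 0.01)$penetrance, 1e-6)
})

test_that("counts with smoothing pull complete penetrance off the boundary", {
  raw <- bayes_penetrance(4, 0, n_case = 1000, n_ctrl = 2615)
  expect_equal(raw$penetrance, 1)
  sm <- bayes_penetrance(4, 0, n_case = 1000, n_ctrl = 2615, smooth = TRUE)
  expect_lt(sm$penetrance, 1)
})

test_that("family-history strata separate penetrance as designed", {
  # FH-positive controls carry nothing; FH-negative controls do
  subjects <- rbind(
    make_subjects(rep("breast", 40), fh = rep(c("positive", "negative"), each = 20), prefix = "B"),
    make_subjects(rep("cancer_free", 200), fh = rep(c("positive", "negative"), each = 100), prefix = "H")
  )
  carriers <- c("B0001", "B0002", "B0021", "B0022", "H0150", "H0151") # H015x are FH-negative
  variants <- make_variants(carriers, rep("c.3109C>T", 6), gene = "BRCA2")
  est <- stratified_penetrance(subjects, variants, "BRCA2", "c.3109C>T",
    controls = "all_cancer_free"
  )
  pos <- est[est$stratum == "FH_positive", ]
  neg <- est[est$stratum == "FH_negative", ]
  expect_equal(pos$penetrance, 1)
  expect_lt(neg$penetrance, 1)
  expect_true(attr(est, "crosses_reference"))
})

test_that("the pooled estimate lies between stratum estimates", {
  # random stratified cohorts with the same family-history composition in
  # both arms (the pooled frequencies are then stratum mixtures with common
  # weights, making the pooled estimate a mediant of the stratum estimates)
  for (seed in 1:15) {
    set.seed(seed)
    n_case <- 400
    n_ctrl <- 600
    w_pos <- sample(8:32, 1) / 40 # exact multiples so both arms share the composition
    case_fh <- rep(c("positive", "negative"), round(c(w_pos, 1 - w_pos) * n_case))
    ctrl_fh <- rep(c("positive", "negative"), round(c(w_pos, 1 - w_pos) * n_ctrl))
    subjects <- rbind(
      make_subjects(rep("breast", length(case_fh)), fh = case_fh, prefix = "B"),
      make_subjects(rep("cancer_free", length(ctrl_fh)), fh = ctrl_fh, prefix = "H")
    )
    carriers <- unlist(lapply(split(subjects$subject_id, interaction(subjects$status, subjects$family_history)),
      function(ids) sample(ids, min(length(ids), sample(1:8, 1)))
    ))
    variants <- make_variants(carriers, rep("c.981_982delAT", length(carriers)))
    est <- stratified_penetrance(subjects, variants, "BRCA1", "c.981_982delAT",
      controls = "all_cancer_free"
    )
    stratum <- est$penetrance[est$stratum != "all"]
    pooled <- est$penetrance[est$stratum == "all"]
    expect_gte(pooled, min(stratum) - 1e-12)
    expect_lte(pooled, max(stratum) + 1e-12)
  }
})

test_that("identical stratum frequencies give identical estimates", {
  subjects <- rbind(
    make_subjects(rep("breast", 100), fh = rep(c("positive", "negative"), 50), prefix = "B"),
    make_subjects(rep("cancer_free", 100), fh = rep(c("positive", "negative"), 50), prefix = "H")
  )
  carriers <- c("B0001", "B0002", "H0001", "H0002") # one per stratum x arm
  variants <- make_variants(carriers, rep("c.10A>T", 4))
  est <- stratified_penetrance(subjects, variants, "BRCA1", "c.10A>T",
    controls = "all_cancer_free"
  )
  expect_equal(length(unique(round(est$penetrance, 12))), 1L)
})

test_that("empty strata are skipped with a warning", {
  subjects <- rbind(
    make_subjects(rep("breast", 10), fh = "negative", prefix = "B"),
    make_subjects(rep("cancer_free", 10), fh = "negative", prefix = "H")
  )
  variants <- make_variants("B0001", "c.10A>T")
  expect_warning(
    est <- stratified_penetrance(subjects, variants, "BRCA1", "c.10A>T"),
    class = "rorscan_empty_stratum"
  )
  expect_false("FH_positive" %in% est$stratum)
})
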