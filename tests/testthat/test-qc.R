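test_that("up/down classification uses inclusive two-fold and p cutoffs", {
  rec <- make_records(c("borderline", "exact", "miss_p", "down", "est"),
                      fold_change = c(1.95, 2.0, 4, 0.4, 12),
                      adj_p = c(0.015, 0.05, 0.2, 0.01, NA),
                      fc_is_estimate = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ud <- up_down_counts(rec)
  # 1.95-fold misses the cutoff despite p = 0.015; FC 2.0 at p 0.05 counts;
  # estimated-FC records are excluded (they carry no p)
  expect_equal(unname(ud), c(1, 1))
})

test_that("up/down counts match an exhaustive filter on labelled records", {
  set.seed(3)
  n <- 50
  fc <- 2^runif(n, -3, 3)
  p <- runif(n)
  rec <- make_records(sprintf("P%02d", 1:n), fold_change = fc, adj_p = p)
  ud <- up_down_counts(rec, fc_cut = 2, p_cut = 0.05)
  expect_equal(unname(ud[["up"]]), sum(fc >= 2 & p <= 0.05))
  expect_equal(unname(ud[["down"]]), sum(fc <= 0.5 & p <= 0.05))
})

test_that("percentage metrics handle zero denominators and complementarity", {
  expect_equal(up_percent(94, 6), 94)
  expect_equal(up_percent(27, 73), 27)
  expect_true(is.na(up_percent(0, 0)))
  expect_equal(turboid_percent(80, 20), 80)
  expect_equal(turboid_percent(0, 5), 0)
  # complementarity whenever defined
  for (ab in list(c(3, 7), c(10, 0), c(1, 1))) {
    expect_equal(up_percent(ab[1], ab[2]) + up_percent(ab[2], ab[1]), 100)
  }
})

test_that("carboxylase share uses pooled detected intensity", {
  carb <- reference_set(c("PYC-1", "POD-2"), "carb")
  m <- toy_matrix(rbind(c(25, 25, 25), c(50, 50, 50), c(25, NA, 25)),
                  rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                  protein_ids = c("PYC-1", "other", "POD-2"))
  br <- bait_runs_of(m)
  # pooled: (75 + 50) / (75 + 150 + 50)
  expect_equal(carboxylase_percent(m, br, carb), 100 * 125 / 275)
  # equals per-run averaging only when per-run totals are equal: here they
  # are not (one carboxylase value dropped out), so the two disagree
  per_run <- sapply(br, function(r) {
    v <- unclass(m)[, r]
    100 * sum(v[c("PYC-1", "POD-2")], na.rm = TRUE) / sum(v, na.rm = TRUE)
  })
  expect_false(isTRUE(all.equal(mean(per_run), carboxylase_percent(m, br, carb))))

  # all intensity in carboxylases
  m2 <- toy_matrix(rbind(c(5, 5, 5)), rbind(c(1, 1, 1)), protein_ids = "PYC-1")
  expect_equal(carboxylase_percent(m2, bait_runs_of(m2), carb), 100)
})

test_that("carboxylase share responds correctly to perturbations", {
  carb <- reference_set("PYC-1", "carb")
  base <- toy_matrix(rbind(c(25, 25, 25), c(75, 75, 75)),
                     rbind(c(1, 1, 1), c(1, 1, 1)),
                     protein_ids = c("PYC-1", "other"))
  p0 <- carboxylase_percent(base, bait_runs_of(base), carb)
  expect_equal(p0, 25)
  # raising a carboxylase intensity strictly raises the share
  up <- toy_matrix(rbind(c(50, 25, 25), c(75, 75, 75)),
                   rbind(c(1, 1, 1), c(1, 1, 1)),
                   protein_ids = c("PYC-1", "other"))
  expect_gt(carboxylase_percent(up, bait_runs_of(up), carb), p0)
  # adding an all-absent protein changes nothing
  pad <- toy_matrix(rbind(c(25, 25, 25), c(75, 75, 75), c(NA, NA, NA)),
                    rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                    protein_ids = c("PYC-1", "other", "ghost"))
  expect_equal(carboxylase_percent(pad, bait_runs_of(pad), carb), p0)
})

test_that("tissue-reference overlap percentage is a plain set intersection", {
  ref <- reference_set(c("A", "B", "C", "D"), "tissue")
  expect_equal(epidermal_percent(c("A", "B"), ref), 100)
  expect_equal(epidermal_percent(c("X", "Y"), ref), 0)
  set.seed(5)
  cand <- sprintf("P%02d", 1:40)
  planted <- sample(cand, 31)
  expect_equal(epidermal_percent(cand, reference_set(planted, "t")),
               100 * 31 / 40)
})

test_that("replicate detection overlap matches exhaustive region enumeration", {
  m <- toy_matrix(rbind(c(1, 1, 1), c(1, 1, NA), c(NA, 1, 1), c(1, NA, NA), c(NA, NA, NA)),
                  matrix(1, 5, 3))
  ov <- replicate_overlap(m, bait_runs_of(m))
  expect_equal(ov$n, 4)
  expect_equal(ov$frac_all, 1 / 4)
  det <- !is.na(unclass(m)[, bait_runs_of(m)])
  for (pat in names(ov$regions)) {
    bits <- as.integer(strsplit(pat, "")[[1]]) == 1
    expect_equal(ov$regions[[pat]],
                 sum(apply(det, 1, function(r) all(r == bits)) & any(bits)),
                 label = paste("region", pat))
  }
  # identical runs: everything in the all-runs region
  m2 <- toy_matrix(cbind(c(1, 2), c(1, 2)), cbind(c(1, 1), c(1, 1)))
  expect_equal(replicate_overlap(m2, bait_runs_of(m2)[1:2])$frac_all, 1)
  # disjoint runs
  m3 <- toy_matrix(cbind(c(1, NA), c(NA, 2)), cbind(c(1, 1), c(1, 1)))
  expect_equal(replicate_overlap(m3, bait_runs_of(m3)[1:2])$frac_all, 0)
})

test_that("replicate R-squared behaves as simple regression on shared log2 values", {
  set.seed(8)
  v <- 2^rnorm(100, 15, 2)
  m <- toy_matrix(cbind(v, 2 * v, 2^rnorm(100, 15, 2)), matrix(1, 100, 3))
  br <- bait_runs_of(m)
  # proportional runs are perfectly determined on the log scale
  expect_equal(replicate_r2(m, br[1], br[2]), 1)
  # symmetry
  expect_equal(replicate_r2(m, br[1], br[3]), replicate_r2(m, br[3], br[1]))
  # a protein detected in only one run does not enter the fit
  v2 <- unclass(m); v2[1, br[2]] <- NA
  m_drop <- pl_matrix(v2, pl_samples(m))
  v3 <- v2; v3[1, br[1]] <- NA
  m_none <- pl_matrix(v3, pl_samples(m))
  expect_equal(replicate_r2(m_drop, br[1], br[3]), replicate_r2(m, br[1], br[3]))
  # fewer than 3 shared proteins: undefined
  tiny <- toy_matrix(cbind(c(1, 2, NA), c(1, NA, 2)), matrix(1, 3, 2))
  expect_true(is.na(replicate_r2(tiny, bait_runs_of(tiny)[1], bait_runs_of(tiny)[2])))
})

test_that("independent runs give near-zero R-squared at large n", {
  set.seed(9)
  m <- toy_matrix(cbind(2^rnorm(2000, 15, 2), 2^rnorm(2000, 15, 2)),
                  matrix(1, 2000, 2))
  br <- bait_runs_of(m)
  expect_lt(replicate_r2(m, br[1], br[2]), 0.05)
})

test_that("metric cross-correlation is simple linear regression over reports", {
  rep5 <- data.frame(x = 1:5, y = 1:5)
  mc <- metric_correlation(rep5, "x", "y")
  expect_equal(mc$r2, 1)
  expect_equal(mc$slope, 1)
  # constant x: undefined
  expect_true(is.na(metric_correlation(data.frame(x = rep(2, 5), y = 1:5), "x", "y")$r2))
  # permuting the pairing destroys a planted linear link
  set.seed(10)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.05)
  linked <- metric_correlation(data.frame(x = x, y = y), "x", "y")
  shuffled <- metric_correlation(data.frame(x = x, y = sample(y)), "x", "y")
  expect_gt(linked$r2, 0.9)
  expect_lt(shuffled$r2, 0.5)
})
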