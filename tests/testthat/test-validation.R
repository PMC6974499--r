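test_that("roc_auc follows the Mann-Whitney pair-counting identity", {
  expect_equal(roc_auc(c(0, 1, 2, 3),
                       c("control", "control", "patient", "patient")), 1)
  expect_equal(roc_auc(rep(5, 6), rep(c("control", "patient"), 3)), 0.5)

  # exhaustive pair-count oracle on random small instances
  set.seed(123)
  for (rep in 1:25) {
    scores <- round(rnorm(16), 1)  # rounding induces ties
    labels <- rep(c("control", "patient"), each = 8)
    got <- roc_auc(scores, labels)
    wins <- 0
    for (p in scores[labels == "patient"]) {
      for (c in scores[labels == "control"]) {
        wins <- wins + (p > c) + 0.5 * (p == c)
      }
    }
    expect_equal(got, wins / 64)
  }
  expect_error(roc_auc(1:4, rep("patient", 4)), class = "ssmpca_value_error")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(30)
  labels <- sample(rep(c("control", "patient"), 15))
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(
                 labels, scores, levels = c("control", "patient"),
                 direction = "<", quiet = TRUE))))
})

test_that("AUC identities: complement under negation, monotone invariance", {
  set.seed(77)
  scores <- rnorm(20)  # continuous, tie-free
  labels <- rep(c("control", "patient"), 10)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(-scores, labels), 1 - a)
  expect_equal(roc_auc(exp(3 * scores), labels), a)
})

test_that("group_compare is the pooled-variance Student t test", {
  # hand-checked small vectors: patients (4,5,6), controls (1,2,3)
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- rep(c("control", "patient"), each = 3)
  got <- group_compare(scores, labels)
  # pooled s^2 = 1, t = 3 / (1 * sqrt(2/3)) = 3.674235
  expect_equal(got$t_statistic, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-3 / sqrt(2 / 3), df = 4),
               tolerance = 1e-12)
  expect_true(got$significant)

  # identical distributions: t = 0, p = 1
  same <- group_compare(c(1, 2, 3, 1, 2, 3), labels)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  # swapping labels negates t, p unchanged
  sw <- group_compare(scores, rev(labels))
  expect_equal(sw$t_statistic, -got$t_statistic)
  expect_equal(sw$p_value, got$p_value)

  expect_error(group_compare(rep(2, 6), labels),
               class = "ssmpca_degenerate_error")
  expect_error(group_compare(1:3, c("control", "control", "patient")),
               class = "ssmpca_value_error")
})

test_that("correlate matches direct product-moment computation", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(correlate(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(55)
  for (rep in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    got <- correlate(a, b)
    # direct-summation oracle
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(got$r, r, tolerance = 1e-12)
    tval <- r * sqrt(10 / (1 - r^2))
    expect_equal(got$p_value, 2 * pt(-abs(tval), df = 10), tolerance = 1e-10)
  }
  expect_error(correlate(1:3, 1:4), class = "ssmpca_dimension_error")
  expect_error(correlate(c(1, 1, 1), 1:3), class = "ssmpca_degenerate_error")
})

test_that("region weights are per-label voxel means over the mask", {
  gs <- c(4L, 4L, 4L)
  mask <- array(TRUE, gs); mask[1] <- FALSE
  labels <- array(0L, gs)
  labels[2:10] <- 1L; labels[11:20] <- 2L; labels[60:64] <- 3L
  atlas <- voi_atlas(labels, c(`1` = "regA", `2` = "regB", `3` = "regC"))
  w <- rnorm(sum(mask))
  pattern <- structure(list(weights = w, mask = mask, grid_shape = gs,
                            affine = diag(4)),
                       class = "covariance_pattern")
  got <- voi_region_weights(pattern, atlas)
  wvol <- unmask_to_volume(w, mask, fill = NA_real_)
  for (l in 1:3) {
    sel <- labels == l & mask
    expect_equal(got$weight[got$label == l], mean(wvol[sel]))
    expect_equal(got$n_voxels[got$label == l], sum(sel))
  }

  # constant pattern: every region weight equals the constant
  pat_c <- pattern; pat_c$weights <- rep(0.25, sum(mask))
  expect_true(all(abs(voi_region_weights(pat_c, atlas)$weight - 0.25) < 1e-12))

  # single-voxel region reports that voxel's weight
  lab1 <- array(0L, gs); lab1[30] <- 9L
  got1 <- voi_region_weights(pattern, voi_atlas(lab1, c(`9` = "dot")))
  expect_equal(got1$weight, wvol[30])

  # region fully outside the mask is missing, not zero
  lab2 <- array(0L, gs); lab2[1] <- 5L; lab2[40] <- 6L
  got2 <- voi_region_weights(pattern,
                             voi_atlas(lab2, c(`5` = "out", `6` = "in")))
  expect_true(is.na(got2$weight[got2$label == 5]))
  expect_false(is.na(got2$weight[got2$label == 6]))
})

test_that("pattern comparison is symmetric with unit self-similarity", {
  co <- generate_cohort(small_spec(seed = 14))
  fit <- derive_pattern(co$volumes)
  pattern <- fit$pattern
  atlas <- demo_voi_atlas(pattern$grid_shape, pattern$mask, n_regions = 12,
                          seed = 3)
  neg <- pattern; neg$weights <- -pattern$weights

  self <- compare_patterns(pattern, pattern, atlas,
                           scored_dataset = co$volumes)
  expect_equal(self$region_weight_correlation, 1, tolerance = 1e-12)
  expect_equal(self$score_correlation, 1, tolerance = 1e-12)

  anti <- compare_patterns(pattern, neg, atlas)
  expect_equal(anti$region_weight_correlation, -1, tolerance = 1e-12)

  other <- derive_pattern_pc1(generate_cohort(small_spec(seed = 15))$volumes)
  ab <- compare_patterns(pattern, other$pattern, atlas)
  ba <- compare_patterns(other$pattern, pattern, atlas)
  expect_equal(ab$region_weight_correlation, ba$region_weight_correlation,
               tolerance = 1e-12)
  expect_true(abs(ab$region_weight_correlation) <= 1)
})

test_that("patterns with overlapping truths correlate in region weights", {
  # two cohorts sharing half their blobs: region-weight correlation of the
  # derived patterns tracks the correlation of the true region means
  gs <- c(10L, 12L, 10L)
  mask <- ssmpca:::synthetic_brain_mask(gs)
  base_spec <- ssmpca:::default_pattern_spec(gs)
  alt_spec <- base_spec
  alt_spec$amplitude[4:6] <- -alt_spec$amplitude[4:6]  # flip half the blobs

  co_a <- generate_cohort(small_spec(seed = 20, voxel_noise_sd = 0.01))
  co_b <- generate_cohort(small_spec(seed = 21, voxel_noise_sd = 0.01,
                                     pattern_spec = alt_spec))
  pat_a <- derive_pattern(co_a$volumes)$pattern
  pat_b <- derive_pattern(co_b$volumes)$pattern
  atlas <- demo_voi_atlas(gs, pat_a$mask & pat_b$mask, n_regions = 15,
                          seed = 4)
  got <- compare_patterns(pat_a, pat_b, atlas)

  truth_pattern <- function(spec_df, m) {
    structure(list(weights = make_ground_truth_pattern(spec_df, gs, m),
                   mask = m, grid_shape = gs, affine = diag(4)),
              class = "covariance_pattern")
  }
  m <- pat_a$mask & pat_b$mask
  ta <- voi_region_weights(truth_pattern(base_spec, m), atlas)
  tb <- voi_region_weights(truth_pattern(alt_spec, m), atlas)
  truth_r <- correlate(ta$weight, tb$weight)$r
  # estimated-pattern region correlation tracks the truth-level correlation
  expect_lt(abs(abs(got$region_weight_correlation) - abs(truth_r)), 0.25)
  expect_true(got$region_weight_correlation > -1 &&
                got$region_weight_correlation < 1)
})

test_that("discrimination report combines AUC and t test on the same scores", {
  co <- generate_cohort(small_spec(seed = 16))
  fit <- derive_pattern(co$volumes)
  sc <- score_cohort(co$volumes, fit$pattern)
  rep <- discrimination_report(sc)
  expect_equal(rep$auc, roc_auc(sc$table$z, sc$table$group))
  expect_equal(rep$n_controls, 8)
  expect_equal(rep$n_patients, 8)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
})
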