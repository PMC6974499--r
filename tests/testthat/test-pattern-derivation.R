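test_that("a candidate with no group association is never selected", {
  set.seed(1)
  labels <- rep(c("control", "patient"), each = 10)
  x <- matrix(rep(rnorm(10), 2), 20, 1)  # identical across groups
  fit <- stepwise_logistic_aic(x, labels)
  expect_length(fit$selected, 0)
  expect_length(fit$coefficients, 0)
  expect_false(fit$separation)
  expect_equal(fit$aic_trace$aic[1],
               AIC(glm(rep(0:1, each = 10) ~ 1, family = binomial())))
})

test_that("forward stepwise matches exhaustive subset search under AIC", {
  # oracle: enumerate every subset, score by AIC of the refit model
  exhaustive_best <- function(x, y) {
    p <- ncol(x)
    best <- list(aic = AIC(glm(y ~ 1, family = binomial())),
                 subset = integer(0))
    for (m in 1:(2^p - 1)) {
      cols <- which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0)
      a <- AIC(suppressWarnings(
        glm(y ~ ., family = binomial(),
            data = data.frame(y = y, x[, cols, drop = FALSE]))))
      if (a < best$aic - 1e-10) best <- list(aic = a, subset = cols)
    }
    best
  }
  set.seed(2024)
  n <- 60
  mismatches <- 0L
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    x <- random_orthogonal_scores(n, k) * sqrt(n)
    y <- rbinom(n, 1, plogis(1.2 * x[, 1] - 0.8 * x[, min(2, k)]))
    if (length(unique(y)) < 2) next
    labels <- ifelse(y == 1, "patient", "control")
    fit <- stepwise_logistic_aic(x, labels)
    oracle <- exhaustive_best(x, y)
    if (!setequal(fit$selected, oracle$subset)) mismatches <- mismatches + 1L
  }
  # greedy forward selection and the exhaustive search coincide on
  # (near-)orthogonal candidates
  expect_identical(mismatches, 0L)
})

test_that("complete separation is flagged and the fallback fit is ordered", {
  x <- matrix(c(seq(-2, -0.5, length.out = 8), seq(0.5, 2, length.out = 8)),
              ncol = 1)
  labels <- rep(c("control", "patient"), each = 8)
  fit <- stepwise_logistic_aic(x, labels)
  expect_true(fit$separation)
  expect_identical(fit$selected, 1L)
  expect_true(is.finite(fit$coefficients))
  expect_gt(fit$coefficients, 0)
  # the penalized fallback preserves the monotone score ordering
  lp <- fit$intercept + x[, 1] * fit$coefficients
  expect_identical(order(lp), order(x[, 1]))
})

test_that("single-class labels are rejected", {
  expect_error(stepwise_logistic_aic(matrix(rnorm(10), 10, 1),
                                     rep("control", 10)),
               class = "ssmpca_value_error")
})

test_that("pattern combination is the coefficient-weighted loading sum", {
  set.seed(8)
  co <- generate_cohort(small_spec(seed = 4))
  vs <- apply_mask(co$volumes, co$truth$brain_mask)
  pca <- fit_pca(ssm_transform(vs))
  gmp <- ssm_transform(vs)$gmp

  args <- list(mask = vs$mask, grid_shape = vs$grid_shape)
  # single component, positive coefficient: pattern equals that loading
  p1 <- do.call(combine_pattern, c(list(pca, 1L, 2.5, gmp), args))
  expect_equal(p1$weights, pca$components[1, ], tolerance = 1e-12)
  expect_equal(sqrt(sum(p1$weights^2)), 1, tolerance = 1e-8)

  # zero second coefficient changes nothing
  p10 <- do.call(combine_pattern, c(list(pca, c(1L, 2L), c(2.5, 0), gmp),
                                    args))
  expect_equal(p10$weights, p1$weights, tolerance = 1e-12)

  # Pythagorean identity on orthonormal loadings with coefficients (3, 4)
  p34 <- do.call(combine_pattern, c(list(pca, c(1L, 2L), c(3, 4), gmp),
                                    args))
  expect_equal(abs(p34$normalization), 5, tolerance = 1e-8)
  expect_equal(p34$weights,
               sign(p34$normalization) *
                 (3 / 5 * pca$components[1, ] + 4 / 5 * pca$components[2, ]),
               tolerance = 1e-10)

  # scaling all coefficients by a positive constant leaves weights unchanged
  p_scaled <- do.call(combine_pattern,
                      c(list(pca, c(1L, 2L), 10 * c(3, 4), gmp), args))
  expect_equal(p_scaled$weights, p34$weights, tolerance = 1e-12)

  # component indices come out strictly increasing
  p_rev <- do.call(combine_pattern, c(list(pca, c(2L, 1L), c(4, 3), gmp),
                                      args))
  expect_identical(p_rev$component_indices, c(1L, 2L))
  expect_equal(p_rev$weights, p34$weights, tolerance = 1e-12)

  expect_error(do.call(combine_pattern, c(list(pca, integer(0), numeric(0),
                                               gmp), args)),
               class = "ssmpca_value_error")
})

test_that("derivation recovers a strongly expressed ground-truth pattern", {
  # low-noise regime: the signal component carries most of the variance, so
  # the candidate set collapses onto it and recovery is clean
  spec <- synthetic_cohort_spec(voxel_noise_sd = 0.01)
  rs <- vapply(1:3, function(sd) {
    spec$seed <- sd
    co <- generate_cohort(spec)
    fit <- derive_pattern(co$volumes)
    tw <- ssmpca:::truth_on_pattern_mask(co$truth, fit$pattern)
    abs(cor(fit$pattern$weights, tw))
  }, numeric(1))
  expect_gte(median(rs), 0.9)

  # orientation convention: derivation patients score higher on average
  spec$seed <- 1L
  co <- generate_cohort(spec)
  fit <- derive_pattern(co$volumes)
  raw <- score_subjects(co$volumes, fit$pattern)
  pat <- co$volumes$group_labels == "patient"
  expect_gt(mean(raw[pat]), mean(raw[!pat]))
  expect_equal(sqrt(sum(fit$pattern$weights^2)), 1, tolerance = 1e-8)
})

test_that("randomly permuted labels yield chance-level discrimination", {
  spec <- synthetic_cohort_spec(seed = 3L)
  co <- generate_cohort(spec)
  vs <- co$volumes
  set.seed(99)
  vs$group_labels <- sample(vs$group_labels)
  fit <- derive_pattern(vs)
  val <- generate_cohort(synthetic_cohort_spec(seed = 2000003L))
  sc <- score_cohort(val$volumes, fit$pattern)
  auc <- roc_auc(sc$table$z, sc$table$group)
  # chance level within binomial error for 20+20
  expect_gt(auc, 0.25)
  expect_lt(auc, 0.75)
})

test_that("duplicating every subject leaves the component subspace alone", {
  co <- generate_cohort(small_spec(seed = 12))
  vs <- apply_mask(co$volumes, co$truth$brain_mask)
  pca <- fit_pca(ssm_transform(vs))
  dup <- volume_set(vs$data[rep(seq_len(nrow(vs$data)), 2), ],
                    mask = vs$mask, grid_shape = vs$grid_shape,
                    subject_ids = make.unique(rep(vs$subject_ids, 2)),
                    group_labels = rep(vs$group_labels, 2),
                    camera_labels = rep(vs$camera_labels, 2))
  pca2 <- fit_pca(ssm_transform(dup))
  k <- length(pca$eigenvalues)
  n <- nrow(vs$data)
  for (j in seq_len(min(3, k))) {
    expect_gt(abs(cor(pca2$subject_scores[seq_len(n), j],
                      pca$subject_scores[, j])), 1 - 1e-6)
  }
})

test_that("the PC1 variant matches full derivation when PC1 carries the signal", {
  spec <- synthetic_cohort_spec(voxel_noise_sd = 0.01, seed = 5L)
  co <- generate_cohort(spec)
  full <- derive_pattern(co$volumes)
  pc1 <- derive_pattern_pc1(co$volumes)
  expect_identical(pc1$pattern$component_indices, 1L)
  expect_equal(sqrt(sum(pc1$pattern$weights^2)), 1, tolerance = 1e-8)
  expect_gt(abs(cor(full$pattern$weights, pc1$pattern$weights)), 0.99)
  s_full <- score_subjects(co$volumes, full$pattern)
  s_pc1 <- score_subjects(co$volumes, pc1$pattern)
  expect_gt(cor(s_full, s_pc1), 0.99)
  pat <- co$volumes$group_labels == "patient"
  expect_gte(mean(s_pc1[pat]), mean(s_pc1[!pat]))
})

test_that("derivation is deterministic for identical inputs", {
  co <- generate_cohort(small_spec(seed = 6))
  f1 <- derive_pattern(co$volumes)
  f2 <- derive_pattern(co$volumes)
  expect_identical(f1$pattern$weights, f2$pattern$weights)
  expect_identical(f1$pattern$component_indices,
                   f2$pattern$component_indices)
})
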