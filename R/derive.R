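#' Forward stepwise logistic regression under AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' component whose inclusion minimizes the Akaike information criterion
#' (AIC = 2k - 2 logLik), stopping at the first step where no addition
#' lowers the AIC.  This is the component-selection engine used to decide
#' which principal components enter a covariance pattern.
#'
#' Complete (or quasi-complete) separation is detected rather than treated
#' as an error: the AIC path is computed from the unpenalized log-likelihood
#' (bounded above at 0, so a separated model's AIC approaches `2k`), the
#' final coefficients are refit with a small L2 (ridge) penalty to keep them
#' finite and their relative sizes meaningful, and the result is flagged.
#'
#' @param subject_scores numeric subject-by-candidate matrix (e.g. PCA
#'   subject scores on the variance-selected components).
#' @param labels per-subject group label; `"patient"` is the positive class,
#'   every other label the reference.
#' @param penalty ridge penalty used by the separation fallback.
#' @return A list with `selected` (candidate indices in inclusion order),
#'   `coefficients` (per selected candidate, from the final model),
#'   `intercept`, `aic_trace` (data frame of the AIC path), and
#'   `separation` (logical flag).
#' @export
stepwise_logistic_aic <- function(subject_scores, labels, penalty = 1e-4) {
  x <- as.matrix(subject_scores)
  if (!ncol(x)) stop_ssm("value", "no candidate components supplied")
  y <- as.integer(labels == "patient")
  if (length(y) != nrow(x)) {
    stop_ssm("dimension", "labels length does not match score rows")
  }
  if (length(unique(y)) < 2L) {
    stop_ssm("value", "both groups must be present in `labels`")
  }

  fit_glm <- function(cols) {
    dat <- data.frame(y = y, x[, cols, drop = FALSE])
    withCallingHandlers(
      glm(y ~ ., data = dat, family = binomial()),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  null_fit <- fit_glm(integer(0))
  selected <- integer(0)
  cur_aic <- AIC(null_fit)
  trace <- data.frame(step = 0L, added = NA_integer_, aic = cur_aic)
  repeat {
    remaining <- setdiff(seq_len(ncol(x)), selected)
    if (!length(remaining)) break
    aics <- vapply(remaining,
                   function(j) AIC(fit_glm(c(selected, j))), numeric(1))
    best <- which.min(aics)
    if (aics[best] < cur_aic - 1e-10) {
      selected <- c(selected, remaining[best])
      cur_aic <- aics[best]
      trace <- rbind(trace, data.frame(step = length(selected),
                                       added = remaining[best],
                                       aic = cur_aic))
    } else break
  }

  if (!length(selected)) {
    return(list(selected = integer(0), coefficients = numeric(0),
                intercept = unname(coef(null_fit)[1]),
                aic_trace = trace, separation = FALSE))
  }
  final <- fit_glm(selected)
  sep <- detect_separation(final)
  if (sep) {
    pen <- ridge_logistic(x[, selected, drop = FALSE], y, penalty = penalty)
    beta <- pen$coefficients
    intercept <- pen$intercept
  } else {
    cf <- coef(final)
    intercept <- unname(cf[1])
    beta <- unname(cf[-1])
  }
  list(selected = selected, coefficients = beta, intercept = intercept,
       aic_trace = trace, separation = sep)
}

## Quasi-complete separation heuristic: fitted probabilities saturate or
## coefficients diverge.
detect_separation <- function(fit) {
  p <- fit$fitted.values
  any(p > 1 - 1e-8 & fit$y == 1) && any(p < 1e-8 & fit$y == 0) ||
    !fit$converged || max(abs(coef(fit)[-1]), 0) > 1e3
}

## L2-penalized logistic regression by iteratively reweighted least squares.
## Intercept unpenalized.  Small fixed penalty keeps maximum-likelihood
## estimates finite under separation while preserving relative coefficient
## sizes; written in-house because the available penalized fitters do not
## accept single-predictor designs.
ridge_logistic <- function(x, y, penalty = 1e-4, max_iter = 200, tol = 1e-10) {
  x <- as.matrix(x)
  X <- cbind(1, x)
  p <- ncol(X)
  pen <- diag(c(0, rep(penalty, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    new_beta <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(intercept = beta[1], coefficients = beta[-1],
       loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

#' Combine selected principal components into a covariance pattern
#'
#' The raw voxel weights are the linear combination of the selected
#' components' loading vectors, each weighted by its logistic-regression
#' coefficient (the voxel map whose subject projections equal the model's
#' linear predictor, up to the intercept).  The weights are then normalized
#' to unit Euclidean norm and oriented so that derivation patients score
#' higher on average than derivation controls; the signed normalization
#' scalar is recorded so raw derivation scores remain recoverable.
#'
#' @param pca an [fit_pca()] result from the derivation set.
#' @param selected indices of the components to combine.
#' @param coefficients one logistic coefficient per selected component.
#' @param gmp the derivation group mean profile (stored with the pattern and
#'   reused when scoring new scans).
#' @param mask,grid_shape,affine grid geometry carried into the pattern.
#' @param intercept,extra optional provenance stored in the derivation
#'   summary.
#' @return An object of class `covariance_pattern`.
#' @export
combine_pattern <- function(pca, selected, coefficients, gmp,
                            mask, grid_shape, affine = diag(4),
                            intercept = NA_real_, extra = list()) {
  stopifnot(inherits(pca, "ssm_pca"))
  if (!length(selected)) stop_ssm("value", "no components selected")
  if (length(coefficients) != length(selected)) {
    stop_ssm("dimension", "need one coefficient per selected component")
  }
  ord <- order(selected)
  selected <- selected[ord]
  coefficients <- coefficients[ord]
  raw <- drop(crossprod(pca$components[selected, , drop = FALSE],
                        coefficients))
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stop_ssm("degenerate", "selected components combine to zero")
  w <- raw / nrm
  ## orientation: derivation patients score higher on average
  dev_raw <- drop(pca$subject_scores[, selected, drop = FALSE] %*%
                    coefficients) / nrm
  is_pat <- pca$group_labels == "patient"
  is_ctl <- pca$group_labels == "control"
  sign_flip <- 1
  if (any(is_pat) && any(is_ctl) &&
      mean(dev_raw[is_pat]) < mean(dev_raw[is_ctl])) {
    sign_flip <- -1
    w <- -w
  }
  structure(
    list(weights = w, mask = mask, grid_shape = as.integer(grid_shape),
         affine = affine,
         component_indices = as.integer(selected),
         coefficients = as.numeric(coefficients),
         intercept = intercept,
         variance_fractions = pca$variance_fractions[selected],
         gmp = as.numeric(gmp),
         normalization = sign_flip * nrm,
         derivation_summary = c(list(
           n_control = sum(is_ctl), n_patient = sum(is_pat),
           version = as.character(packageVersion("ssmpca"))), extra)),
    class = "covariance_pattern"
  )
}

#' @export
print.covariance_pattern <- function(x, ...) {
  cat(sprintf("covariance_pattern: %d voxels, components [%s]\n",
              length(x$weights), paste(x$component_indices, collapse = ", ")))
  cat(sprintf("  coefficients: %s; variance fractions: %s\n",
              paste(signif(x$coefficients, 3), collapse = ", "),
              paste(signif(x$variance_fractions, 3), collapse = ", ")))
  cat(sprintf("  derived from %d controls / %d patients\n",
              x$derivation_summary$n_control, x$derivation_summary$n_patient))
  invisible(x)
}

#' Configuration for pattern derivation
#'
#' @param cum_var_threshold cumulative variance fraction defining the
#'   candidate component set (default 0.5: the components explaining the
#'   top half of total variance).
#' @param mask_threshold relative brain-mask threshold applied when the
#'   input set is unmasked.
#' @param gmp_group subjects defining the group mean profile, `"all"` or
#'   `"control"`.
#' @param seed integer seed recorded in the pattern provenance.
#' @return A list of class `derive_config`.
#' @export
derive_config <- function(cum_var_threshold = 0.5, mask_threshold = 0.35,
                          gmp_group = "all", seed = NA_integer_) {
  if (!(cum_var_threshold > 0 && cum_var_threshold <= 1)) {
    stop_ssm("config", "cum_var_threshold must lie in (0,1]")
  }
  if (!(mask_threshold > 0 && mask_threshold < 1)) {
    stop_ssm("config", "mask_threshold must lie in (0,1)")
  }
  structure(list(cum_var_threshold = cum_var_threshold,
                 mask_threshold = mask_threshold,
                 gmp_group = gmp_group, seed = seed),
            class = "derive_config")
}

## Shared front half of the derivation pipeline: optional masking, SSM
## transform, PCA.
derive_stages <- function(vs, config) {
  stopifnot(inherits(vs, "volume_set"))
  if (!any(vs$group_labels == "control") || !any(vs$group_labels == "patient")) {
    stop_ssm("value", "derivation requires both control and patient subjects")
  }
  if (all(vs$mask)) {
    vs <- apply_mask(vs, compute_brain_mask(vs, config$mask_threshold))
  }
  rp <- ssm_transform(vs, gmp_group = config$gmp_group)
  pca <- fit_pca(rp)
  list(vs = vs, rp = rp, pca = pca)
}

#' Derive a disease-related covariance pattern
#'
#' Runs the full identification pipeline on a derivation cohort: brain
#' masking (if the set is unmasked), SSM transform, PCA of the residual
#' profiles, selection of the components explaining the top share of total
#' variance, forward stepwise logistic regression (AIC) on their subject
#' scores, and linear combination of the selected components into a single
#' unit-norm pattern.  If the stepwise search selects no component, the
#' pattern falls back to principal component 1 alone and is flagged.
#'
#' @param vs a [volume_set()] containing both groups.
#' @param config a [derive_config()].
#' @return A list with `pattern` ([combine_pattern()] result), `pca`, and
#'   `profiles`.
#' @export
derive_pattern <- function(vs, config = derive_config()) {
  st <- derive_stages(vs, config)
  cand <- select_top_variance_components(st$pca$variance_fractions,
                                         config$cum_var_threshold)
  sw <- stepwise_logistic_aic(
    st$pca$subject_scores[, cand, drop = FALSE], st$vs$group_labels)
  fallback <- !length(sw$selected)
  if (fallback) {
    selected <- 1L
    coefficients <- 1
    intercept <- NA_real_
  } else {
    selected <- cand[sw$selected]
    coefficients <- sw$coefficients
    intercept <- sw$intercept
  }
  pattern <- combine_pattern(
    st$pca, selected, coefficients, gmp = st$rp$gmp,
    mask = st$vs$mask, grid_shape = st$vs$grid_shape, affine = st$vs$affine,
    intercept = intercept,
    extra = list(candidates = cand, separation = sw$separation,
                 empty_selection_fallback = fallback,
                 aic_trace = sw$aic_trace, seed = config$seed,
                 mode = "stepwise"))
  list(pattern = pattern, pca = st$pca, profiles = st$rp)
}

#' Derive the PC1-only variant of a pattern
#'
#' Identical pipeline to [derive_pattern()], but the pattern is principal
#' component 1 in isolation (unit norm, oriented so patients score higher);
#' the logistic fit on PC1 alone is retained only for reporting.
#'
#' @inheritParams derive_pattern
#' @return A list with `pattern`, `pca`, and `profiles`.
#' @export
derive_pattern_pc1 <- function(vs, config = derive_config()) {
  st <- derive_stages(vs, config)
  fit1 <- stepwise_logistic_aic(
    st$pca$subject_scores[, 1, drop = FALSE], st$vs$group_labels)
  report_coef <- if (length(fit1$coefficients)) fit1$coefficients else NA_real_
  pattern <- combine_pattern(
    st$pca, 1L, 1, gmp = st$rp$gmp,
    mask = st$vs$mask, grid_shape = st$vs$grid_shape, affine = st$vs$affine,
    intercept = fit1$intercept,
    extra = list(pc1_logistic_coefficient = report_coef,
                 separation = fit1$separation, seed = config$seed,
                 mode = "pc1"))
  list(pattern = pattern, pca = st$pca, profiles = st$rp)
}
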