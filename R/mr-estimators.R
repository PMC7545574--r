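#' Inverse-variance-weighted MR estimate
#'
#' Meta-analyses the per-instrument ratio estimates with weights
#' \eqn{w_i = se_{y,i}^{-2}}:
#' \deqn{\hat\theta = \frac{\sum_i w_i \beta_{x,i}\beta_{y,i}}
#'   {\sum_i w_i \beta_{x,i}^2}.}
#' By default a multiplicative random-effects model is used: when Cochran's
#' Q exceeds its degrees of freedom the fixed-effect standard error is
#' inflated by \eqn{\sqrt{Q/(k-1)}}. With a single instrument the estimate
#' reduces to the Wald ratio \eqn{\beta_y/\beta_x} (flagged in the result).
#'
#' @param h A [harmonized_instruments()] set.
#' @param method `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return List of class `mr_estimate`: `estimate`, `se`, `p`, `k`, `Q`,
#'   `method`, `wald_ratio` flag.
#' @examples
#' h <- harmonized_instruments(c(0.1, 0.2, 0.3), rep(0.01, 3),
#'                             c(0.02, 0.04, 0.06), rep(0.01, 3))
#' mr_ivw(h)$estimate  # 0.2, all ratios equal
#' @export
mr_ivw <- function(h, method = c("random", "fixed")) {
  method <- match.arg(method)
  stopifnot(inherits(h, "harmonized_instruments"))
  if (any(h$se_outcome <= 0))
    stop_mm("invalid_argument", "outcome standard errors must be > 0")
  k <- nrow(h)
  if (k == 1L) {
    est <- h$beta_outcome / h$beta_exposure
    se <- abs(h$se_outcome / h$beta_exposure)
    return(structure(list(estimate = est, se = se,
                          p = 2 * stats::pnorm(-abs(est / se)),
                          k = 1L, Q = NA_real_, method = "wald",
                          wald_ratio = TRUE),
                     class = "mr_estimate"))
  }
  w <- 1 / h$se_outcome^2
  est <- sum(w * h$beta_exposure * h$beta_outcome) /
    sum(w * h$beta_exposure^2)
  se_fixed <- sqrt(1 / sum(w * h$beta_exposure^2))
  Q <- sum(w * (h$beta_outcome - est * h$beta_exposure)^2)
  se <- if (method == "random") se_fixed * sqrt(max(1, Q / (k - 1)))
        else se_fixed
  structure(list(estimate = est, se = se,
                 p = 2 * stats::pnorm(-abs(est / se)),
                 k = k, Q = Q, method = method, wald_ratio = FALSE),
            class = "mr_estimate")
}

# interpolated weighted median of `b` with weights `w` (cumulative
# normalized weight crossing 0.5)
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  cum <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] < 0.5) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median MR estimate
#'
#' Takes the weighted median of the per-instrument ratio estimates
#' \eqn{\beta_y/\beta_x}, weighting by the inverse squared delta-method
#' standard error of each ratio, with linear interpolation between order
#' statistics where the cumulative normalized weight crosses one half. The
#' estimator is consistent when instruments contributing at least half the
#' weight are valid. The standard error is obtained by parametric bootstrap
#' over the instrument effect estimates.
#'
#' @param h A [harmonized_instruments()] set with at least 3 instruments.
#' @param n_boot Bootstrap draws for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List of class `mr_estimate`: `estimate`, `se`, `p`, `k`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(h, "harmonized_instruments"))
  k <- nrow(h)
  if (k < 3L)
    stop_mm("insufficient_instruments",
            "weighted median needs >= 3 instruments (have %d)", k)
  ratio <- h$beta_outcome / h$beta_exposure
  se_ratio <- sqrt(h$se_outcome^2 / h$beta_exposure^2 +
                   h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  est <- weighted_median_point(ratio, 1 / se_ratio^2)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(s) {
    bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    r <- by / bx
    sr <- sqrt(h$se_outcome^2 / bx^2 + by^2 * h$se_exposure^2 / bx^4)
    weighted_median_point(r, 1 / sr^2)
  }, numeric(1))
  se <- stats::sd(boot)
  structure(list(estimate = est, se = se,
                 p = 2 * stats::pnorm(-abs(est / se)), k = k),
            class = "mr_estimate")
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept, weights \eqn{se_{y,i}^{-2}}, after
#' orienting all exposure effects non-negative (flipping the sign of both
#' betas where needed). The intercept estimates the average directional
#' pleiotropy; the slope is the pleiotropy-adjusted causal effect. Standard
#' errors use multiplicative overdispersion scaling with the residual
#' dispersion floored at 1; p-values use the t distribution with k - 2
#' degrees of freedom.
#'
#' @param h A [harmonized_instruments()] set with at least 3 instruments.
#' @return List of class `mr_egger_fit`: `estimate`, `se`, `p` (slope),
#'   `intercept`, `intercept_se`, `intercept_p`, `dispersion`, `k`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  k <- nrow(h)
  if (k < 3L)
    stop_mm("insufficient_instruments",
            "MR-Egger needs >= 3 instruments (have %d)", k)
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  if (stats::sd(bx) < 1e-12)
    stop_mm("collinear_instruments",
            "all exposure effects equal after orientation")
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # lm's se already scales by the residual dispersion; floor it at 1
  scale_fix <- 1 / min(sm$sigma, 1)
  cf <- sm$coefficients
  slope <- cf["bx", 1]
  slope_se <- cf["bx", 2] * scale_fix
  icpt <- cf["(Intercept)", 1]
  icpt_se <- cf["(Intercept)", 2] * scale_fix
  structure(list(
    estimate = slope, se = slope_se,
    p = 2 * stats::pt(-abs(slope / slope_se), df = k - 2),
    intercept = icpt, intercept_se = icpt_se,
    intercept_p = 2 * stats::pt(-abs(icpt / icpt_se), df = k - 2),
    dispersion = sm$sigma^2, k = k),
    class = c("mr_egger_fit", "mr_estimate"))
}

#' MR-PRESSO-style global pleiotropy test and outlier correction
#'
#' Measures the observed residual sum of squares of leave-one-out IVW
#' predictions, \eqn{RSS = \sum_i w_i (\beta_{y,i} -
#' \hat\theta_{(-i)}\beta_{x,i})^2}, and compares it with its parametric
#' null: `n_sim` datasets are drawn with
#' \eqn{\beta_{x,i}^* \sim N(\beta_{x,i}, se_{x,i})} and
#' \eqn{\beta_{y,i}^* \sim N(\hat\theta_{(-i)}\beta_{x,i}, se_{y,i})}, and
#' the empirical p-value uses add-one smoothing, so its minimum is
#' `1/(n_sim+1)`. Per-instrument outliers are flagged by comparing each
#' observed weighted squared residual with its simulated distribution at a
#' Bonferroni-corrected level, and the outlier-corrected estimate is the IVW
#' estimate after removing flagged instruments.
#'
#' @param h A [harmonized_instruments()] set with at least 4 instruments.
#' @param n_sim Number of parametric null simulations (default 1000; values
#'   below 100 trigger a warning).
#' @param seed Seed for the simulations.
#' @param alpha_outlier Outlier test level before Bonferroni correction
#'   (default 0.05).
#' @return List of class `mr_presso_fit`: `global_p`, `outliers` (ids),
#'   `estimate`, `se`, `p` (outlier-corrected IVW), `raw` (uncorrected IVW
#'   `mr_estimate`), `outlier_p` (per-instrument), `n_sim`.
#' @export
mr_presso <- function(h, n_sim = 1000L, seed = 1L, alpha_outlier = 0.05) {
  stopifnot(inherits(h, "harmonized_instruments"))
  k <- nrow(h)
  if (k < 4L)
    stop_mm("insufficient_instruments",
            "MR-PRESSO needs >= 4 instruments (have %d)", k)
  if (n_sim < 100L)
    warn_mm("low_n_sim", "n_sim = %d is small; p resolution is %.3g",
            n_sim, 1 / (n_sim + 1))
  w <- 1 / h$se_outcome^2
  loo_theta <- function(bx, by) {
    s1 <- sum(w * bx * by)
    s2 <- sum(w * bx^2)
    (s1 - w * bx * by) / (s2 - w * bx^2)
  }
  th_loo <- loo_theta(h$beta_exposure, h$beta_outcome)
  if (any(!is.finite(th_loo)))
    stop_mm("degenerate_model", "leave-one-out IVW undefined")
  res_obs <- w * (h$beta_outcome - th_loo * h$beta_exposure)^2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  bx_sim <- matrix(stats::rnorm(k * n_sim, h$beta_exposure, h$se_exposure),
                   k, n_sim)
  by_sim <- matrix(stats::rnorm(k * n_sim, th_loo * h$beta_exposure,
                                h$se_outcome), k, n_sim)
  res_sim <- matrix(0, k, n_sim)
  for (s in seq_len(n_sim)) {
    th_s <- loo_theta(bx_sim[, s], by_sim[, s])
    res_sim[, s] <- w * (by_sim[, s] - th_s * bx_sim[, s])^2
  }
  rss_sim <- colSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
  is_out <- outlier_p < alpha_outlier / k
  raw <- mr_ivw(h)
  corrected <- if (any(is_out) && sum(!is_out) >= 1L)
    mr_ivw(h[!is_out, , drop = FALSE]) else raw
  structure(list(global_p = global_p,
                 outliers = h$id[is_out],
                 estimate = corrected$estimate, se = corrected$se,
                 p = corrected$p, raw = raw,
                 outlier_p = stats::setNames(outlier_p, h$id),
                 n_sim = n_sim),
            class = c("mr_presso_fit", "mr_estimate"))
}

#' Run all four MR estimators
#'
#' Convenience wrapper applying IVW, weighted median, MR-Egger and the
#' MR-PRESSO-style test to one harmonized instrument set. Methods whose
#' instrument requirements are not met are returned as NULL (marked
#' unavailable for classification).
#'
#' @param h A [harmonized_instruments()] set.
#' @param n_boot Bootstrap draws for the weighted median.
#' @param n_sim Simulations for MR-PRESSO.
#' @param seed Seed shared by the stochastic methods.
#' @return List of class `mr_result` with elements `ivw`,
#'   `weighted_median`, `egger`, `presso` and `k`.
#' @export
run_mr <- function(h, n_boot = 1000L, n_sim = 1000L, seed = 1L) {
  k <- nrow(h)
  structure(list(
    ivw = mr_ivw(h),
    weighted_median = if (k >= 3L) mr_weighted_median(h, n_boot, seed) else NULL,
    egger = if (k >= 3L) tryCatch(mr_egger(h), error = function(e) NULL)
            else NULL,
    presso = if (k >= 4L) mr_presso(h, n_sim, seed) else NULL,
    k = k
  ), class = "mr_result")
}

#' Two-tier significance classification of an MR result
#'
#' Applies the study's decision rule. A result is `"significant"` when the
#' IVW p-value passes the direction-appropriate Bonferroni bound: 0.05
#' divided by the number of outcome traits tested in the forward
#' (microbiome-to-trait) direction, or 0.05 divided by the effective number
#' of independent taxa at the relevant taxonomic level in the reverse
#' direction. A result failing Bonferroni is `"potential_causal"` when all
#' four MR methods agree at p < 0.05, and `"null"` otherwise.
#'
#' @param results An `mr_result` from [run_mr()] (or a list with the same
#'   elements; missing methods count as unavailable).
#' @param direction `"forward"` or `"reverse"`.
#' @param n_tests_forward Number of forward outcome traits (default 62).
#' @param n_eff_taxa Effective number of independent taxa for the reverse
#'   bound; required when `direction = "reverse"`.
#' @return List of class `mr_classification`: `classification`
#'   (`"significant"`, `"potential_causal"` or `"null"`), `threshold`,
#'   `direction`, `method_p` (named vector).
#' @export
classify_mr_result <- function(results, direction = c("forward", "reverse"),
                               n_tests_forward = 62, n_eff_taxa = NULL) {
  direction <- match.arg(direction)
  if (is.null(results$ivw))
    stop_mm("invalid_argument", "IVW result is required")
  threshold <- if (direction == "forward") {
    0.05 / n_tests_forward
  } else {
    if (is.null(n_eff_taxa))
      stop_mm("configuration_error",
              "n_eff_taxa is required for the reverse direction")
    0.05 / n_eff_taxa
  }
  ps <- c(ivw = results$ivw$p,
          weighted_median = if (!is.null(results$weighted_median))
            results$weighted_median$p else NA_real_,
          egger = if (!is.null(results$egger)) results$egger$p else NA_real_,
          presso = if (!is.null(results$presso)) results$presso$p else NA_real_)
  classification <- if (ps[["ivw"]] < threshold) {
    "significant"
  } else if (!anyNA(ps) && all(ps < 0.05)) {
    "potential_causal"
  } else {
    "null"
  }
  structure(list(classification = classification, threshold = threshold,
                 direction = direction, method_p = ps),
            class = "mr_classification")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> estimate = %.4f (SE %.4f), p = %.3g, k = %d\n",
              x$estimate, x$se, x$p, x$k))
  invisible(x)
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %d instruments\n", x$k))
  for (m in c("ivw", "weighted_median", "egger", "presso")) {
    r <- x[[m]]
    if (is.null(r)) {
      cat(sprintf("  %-16s unavailable\n", m))
    } else {
      cat(sprintf("  %-16s %8.4f (SE %.4f)  p = %.3g\n",
                  m, r$estimate, r$se, r$p))
    }
  }
  if (!is.null(x$presso))
    cat(sprintf("  presso global p = %.3g; outliers: %s\n",
                x$presso$global_p,
                if (length(x$presso$outliers))
                  paste(x$presso$outliers, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
print.mr_classification <- function(x, ...) {
  cat(sprintf("<mr_classification> %s (%s, threshold %.3g)\n",
              x$classification, x$direction, x$threshold))
  invisible(x)
}
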