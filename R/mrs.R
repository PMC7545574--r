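#' Correlate pathway/disease features with taxa
#'
#' Spearman rank correlation of every pathway (predicted disease) feature
#' with every taxon, with a Bonferroni significance mask at
#' \eqn{0.05 / (n_{eff} \times n_{features})}, where \eqn{n_{eff}} is the
#' effective number of independent taxa at the relevant taxonomic level
#' (e.g. 5.6 at genus level with 22 diseases gives a threshold of about
#' 4e-4). Rows are additionally ordered by average-linkage hierarchical
#' clustering of the correlation profiles for heatmap export.
#'
#' @param P A `pathway_table` or numeric matrix (samples x features).
#' @param T A [taxon_table()] or numeric matrix (samples x taxa), on shared
#'   samples.
#' @param n_eff Effective number of independent taxa (see
#'   [effective_number_independent_taxa()]).
#' @param n_features Number of disease features for the Bonferroni product;
#'   defaults to `ncol(P)`.
#' @return List of class `feature_correlation`: `rho`, `p` (features x
#'   taxa), `mask` (logical, TRUE where Bonferroni-significant),
#'   `threshold`, `row_order` (feature ordering for plotting). Constant
#'   features or taxa yield NA entries.
#' @export
correlate_features <- function(P, T, n_eff, n_features = NULL) {
  pm <- if (inherits(P, "pathway_table")) P$values else as.matrix(P)
  tm <- if (inherits(T, "taxon_table"))
    relative_abundance_safe(T) else as.matrix(T)
  if (nrow(pm) != nrow(tm))
    stop_mm("invalid_argument", "P and T must share samples")
  check_scalar_number(n_eff, "n_eff", 0, strict_lower = TRUE)
  if (is.null(n_features)) n_features <- ncol(pm)
  nf <- ncol(pm); nt <- ncol(tm)
  rho <- p <- matrix(NA_real_, nf, nt,
                     dimnames = list(colnames(pm), colnames(tm)))
  for (i in seq_len(nf)) {
    if (stats::sd(pm[, i]) == 0) next
    for (j in seq_len(nt)) {
      if (stats::sd(tm[, j]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(pm[, i], tm[, j], method = "spearman",
                        exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  threshold <- 0.05 / (n_eff * n_features)
  mask <- !is.na(p) & p < threshold
  row_order <- seq_len(nf)
  if (nf > 2L && !anyNA(rho)) {
    hc <- stats::hclust(stats::dist(rho), method = "average")
    row_order <- hc$order
  }
  structure(list(rho = rho, p = p, mask = mask, threshold = threshold,
                 row_order = row_order),
            class = "feature_correlation")
}

#' Build a microbiome risk score model
#'
#' Selects taxa whose Spearman correlation with the target feature (e.g. a
#' predicted disease abundance) exceeds `rho_threshold` in absolute value
#' (strictly), and stores for each selected taxon its direction, the sign
#' of the training correlation, and its low-abundance cutoff, the empirical
#' `quantile` (type-7) of its training abundance. Cutoffs are learned on the
#' training table and frozen so the score can be applied to new samples.
#'
#' @param T A [taxon_table()] (converted to relative abundance internally).
#' @param target_feature Numeric vector over the same samples.
#' @param rho_threshold Absolute-correlation selection threshold (strict;
#'   default 0.2).
#' @param quantile Low-abundance zeroing quantile (default 0.05).
#' @return List of class `mrs_model`: `taxa` (data frame with `id`, `rho`,
#'   `direction`, `cutoff`), `rho_threshold`, `quantile`.
#' @export
build_mrs <- function(T, target_feature, rho_threshold = 0.2,
                      quantile = 0.05) {
  stopifnot(inherits(T, "taxon_table"))
  if (length(target_feature) != nrow(T$values))
    stop_mm("invalid_argument", "target_feature must cover the same samples")
  rel <- relative_abundance_safe(T)
  rho <- apply(rel, 2L, function(a)
    suppressWarnings(stats::cor(a, target_feature, method = "spearman")))
  sel <- which(!is.na(rho) & abs(rho) > rho_threshold)
  if (!length(sel))
    stop_mm("empty_model", "no taxon exceeds |rho| > %.2f", rho_threshold)
  cutoffs <- vapply(sel, function(j)
    stats::quantile(rel[, j], quantile, type = 7, names = FALSE), numeric(1))
  structure(list(
    taxa = data.frame(id = T$taxa$id[sel], rho = rho[sel],
                      direction = sign(rho[sel]), cutoff = cutoffs,
                      stringsAsFactors = FALSE, row.names = NULL),
    rho_threshold = rho_threshold, quantile = quantile),
    class = "mrs_model")
}

#' Score samples with an MRS model and test disease association
#'
#' Each selected taxon contributes 0 when the sample's relative abundance
#' falls below the taxon's stored low-abundance cutoff, and otherwise its
#' direction (+1 for positively, -1 for inversely associated taxa); the
#' per-sample score is the sum. The score is then tested against the binary
#' outcome by logistic regression with covariates (age, sex, dietary energy,
#' alcohol intake, BMI in the reference design), returning the odds ratio
#' per unit score with a 95 percent confidence interval.
#'
#' @param model An `mrs_model` from [build_mrs()].
#' @param T A [taxon_table()] containing every model taxon.
#' @param outcome Binary 0/1 outcome vector (optional; omit to just score).
#' @param X Optional covariate matrix/data frame.
#' @return List of class `mrs_result`: `scores` (named per-sample),
#'   `odds_ratio`, `ci` (length 2), `p`, `estimate`, `se` (log-odds scale);
#'   the test fields are NA when `outcome` is NULL.
#' @export
score_and_test_mrs <- function(model, T, outcome = NULL, X = NULL) {
  stopifnot(inherits(model, "mrs_model"), inherits(T, "taxon_table"))
  missing_taxa <- setdiff(model$taxa$id, T$taxa$id)
  if (length(missing_taxa))
    stop_mm("missing_taxa", "taxa absent from table: %s",
            paste(missing_taxa, collapse = ", "))
  rel <- relative_abundance_safe(T)
  idx <- match(model$taxa$id, T$taxa$id)
  contrib <- sweep(rel[, idx, drop = FALSE] >=
                     matrix(model$taxa$cutoff, nrow(rel), length(idx),
                            byrow = TRUE),
                   2L, model$taxa$direction, `*`)
  scores <- stats::setNames(rowSums(contrib), T$sample_ids)
  if (is.null(outcome))
    return(structure(list(scores = scores, odds_ratio = NA_real_,
                          ci = c(NA_real_, NA_real_), p = NA_real_,
                          estimate = NA_real_, se = NA_real_),
                     class = "mrs_result"))
  if (!all(outcome %in% c(0, 1)))
    stop_mm("invalid_argument", "outcome must be binary 0/1")
  dat <- data.frame(.y = outcome, .s = scores)
  if (!is.null(X)) dat <- cbind(dat, as.data.frame(X))
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  cf <- summary(fit)$coefficients
  est <- cf[".s", 1]; se <- cf[".s", 2]
  structure(list(scores = scores, odds_ratio = exp(est),
                 ci = exp(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = cf[".s", 4], estimate = est, se = se),
            class = "mrs_result")
}

#' @export
print.mrs_model <- function(x, ...) {
  cat(sprintf("<mrs_model> %d taxa (|rho| > %.2f), zeroing below the %.0f%% quantile\n",
              nrow(x$taxa), x$rho_threshold, 100 * x$quantile))
  invisible(x)
}

#' @export
print.mrs_result <- function(x, ...) {
  if (is.na(x$odds_ratio)) {
    cat(sprintf("<mrs_result> %d samples scored (no outcome test)\n",
                length(x$scores)))
  } else {
    cat(sprintf("<mrs_result> OR = %.3f [95%% CI %.3f, %.3f], p = %.3g\n",
                x$odds_ratio, x$ci[1], x$ci[2], x$p))
  }
  invisible(x)
}
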