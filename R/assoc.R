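#' Covariate-adjusted single-variant association scan
#'
#' Regresses the phenotype on each variant's effect-allele dosage with fixed
#' covariates. For `model = "linear"` the scan uses the exact OLS solution
#' via residualization (Frisch-Waugh): phenotype and dosages are projected
#' off the covariates (plus intercept) and the per-variant slope, standard
#' error and two-sided t-test are computed on the residuals, which matches a
#' full joint fit exactly. For `model = "logistic"` each variant is fitted by
#' IRLS (`glm.fit`, binomial); variants whose fit fails to converge or shows
#' separation-scale standard errors are reported as NA with a reason and the
#' scan continues.
#'
#' @param G A [genotype_matrix()].
#' @param y Phenotype vector (continuous, or 0/1 for logistic).
#' @param X Optional covariate matrix (e.g. ancestry PCs, age, sex, batch);
#'   the intercept is implicit.
#' @param model `"linear"` or `"logistic"`.
#' @return A `summary_stats` data frame (one row per variant) with `beta` on
#'   the analysis scale (log-odds for logistic), `se`, `p`, `n`, and a
#'   `model` column; failed logistic fits carry NA and a `note`.
#' @export
association_scan <- function(G, y, X = NULL,
                             model = c("linear", "logistic")) {
  stopifnot(inherits(G, "genotype_matrix"))
  model <- match.arg(model)
  n <- length(y)
  if (n != nrow(G$dosage))
    stop_mm("invalid_argument", "length(y) != number of samples")
  Xf <- cbind(rep(1, n), X)
  m <- ncol(G$dosage)
  note <- rep(NA_character_, m)
  if (model == "linear") {
    qx <- qr(Xf)
    ry <- qr.resid(qx, y)
    rg <- qr.resid(qx, G$dosage)
    gss <- colSums(rg^2)
    df <- n - ncol(Xf) - 1L
    beta <- as.vector(crossprod(rg, ry)) / gss
    rss <- sum(ry^2) - beta^2 * gss
    se <- sqrt(rss / df / gss)
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    bad <- gss < 1e-12
    beta[bad] <- se[bad] <- p[bad] <- NA_real_
    note[bad] <- "monomorphic after covariate adjustment"
  } else {
    if (!all(y %in% c(0, 1)))
      stop_mm("invalid_argument", "logistic model requires 0/1 phenotype")
    beta <- se <- p <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(Xf, G$dosage[, j]), y,
                                        family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        note[j] <- "did not converge"
        next
      }
      cf <- fit$coefficients
      k <- length(cf)
      covm <- tryCatch(chol2inv(fit$qr$qr[seq_len(k), seq_len(k), drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(covm) || !is.finite(covm[k, k]) || covm[k, k] <= 0 ||
          sqrt(covm[k, k]) > 20) {
        note[j] <- "separation"
        next
      }
      beta[j] <- cf[k]
      se[j] <- sqrt(covm[k, k])
      p[j] <- 2 * stats::pnorm(-abs(beta[j] / se[j]))
    }
  }
  out <- data.frame(
    id = G$variants$id, chrom = G$variants$chrom,
    pos_bp = G$variants$pos_bp, pos_cm = G$variants$pos_cm,
    effect_allele = G$variants$effect_allele,
    other_allele = G$variants$other_allele,
    eaf = colMeans(G$dosage) / 2,
    beta = beta, se = se, p = p, n = n, model = model, note = note,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(out$se)
  out$se[ok & out$se <= 0] <- NA_real_
  class(out) <- c("summary_stats", class(out))
  out
}

#' Genomic inflation factor
#'
#' Median-based lambda-GC: the median of the one-degree-of-freedom chi-square
#' quantiles implied by the p-values, divided by the null median
#' \eqn{\chi^2_{1,0.5} \approx 0.4549}. Equals 1 for well-calibrated null
#' statistics; values above 1 indicate inflation.
#'
#' @param p_values Numeric vector of p-values in (0, 1]; at least 100.
#' @return A single number, lambda.
#' @examples
#' genomic_inflation(runif(1e4))
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 100L)
    stop_mm("invalid_argument", "need >= 100 p-values")
  if (any(p_values <= 0 | p_values > 1))
    stop_mm("invalid_argument", "p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the smallest-p unclaimed variant passing `p_thresh` as a
#' lead and claims every variant on the same chromosome within `window_cm`
#' whose squared dosage correlation with the lead is at least `r2_thresh`.
#' Ties on p are broken by smaller genomic coordinate (chromosome, then
#' position), making the output deterministic.
#'
#' @param assoc A `summary_stats` data frame (e.g. from
#'   [association_scan()]).
#' @param G The [genotype_matrix()] providing the LD reference; must contain
#'   every association variant.
#' @param p_thresh Association p-value threshold for lead eligibility
#'   (default 5e-5).
#' @param r2_thresh Squared-correlation threshold at or above which a variant
#'   is claimed by a lead (default 0.1).
#' @param window_cm Half-width of the clumping window in centimorgans
#'   (default 0.1).
#' @return Character vector of lead variant ids, in selection order (may be
#'   empty).
#' @export
ld_clump <- function(assoc, G, p_thresh = 5e-5, r2_thresh = 0.1,
                     window_cm = 0.1) {
  stopifnot(inherits(G, "genotype_matrix"))
  idx_in_G <- match(assoc$id, G$variants$id)
  if (anyNA(idx_in_G))
    stop_mm("invalid_argument", "association variant(s) missing from G: %s",
            paste(utils::head(assoc$id[is.na(idx_in_G)], 5), collapse = ", "))
  cand <- which(!is.na(assoc$p) & assoc$p < p_thresh)
  if (!length(cand)) return(character(0))
  ord <- cand[order(assoc$p[cand], assoc$chrom[cand], assoc$pos_bp[cand])]
  claimed <- rep(FALSE, nrow(assoc))
  leads <- character(0)
  for (i in ord) {
    if (claimed[i]) next
    leads <- c(leads, assoc$id[i])
    claimed[i] <- TRUE
    near <- which(!claimed &
                    assoc$chrom == assoc$chrom[i] &
                    abs(assoc$pos_cm - assoc$pos_cm[i]) <= window_cm)
    if (length(near)) {
      g_lead <- G$dosage[, idx_in_G[i]]
      r2 <- suppressWarnings(
        as.vector(stats::cor(g_lead,
                             G$dosage[, idx_in_G[near], drop = FALSE]))^2)
      r2[is.na(r2)] <- 0
      claimed[near[r2 >= r2_thresh]] <- TRUE
    }
  }
  leads
}

#' Build a weighted polygenic score
#'
#' Scores each target-cohort sample as the sum of GWAS betas times
#' effect-allele dosages over the lead variants. Alleles are harmonized
#' against the target genotypes: when the target's effect/other alleles are
#' swapped relative to the discovery statistics, the complementary dosage
#' (2 - dosage) is used, so scores are invariant to allele-label flips.
#' Variants absent from the target, or with incompatible allele pairs, are
#' dropped with a warning and counted.
#'
#' @param leads Character vector of lead variant ids (e.g. from
#'   [ld_clump()]).
#' @param assoc Discovery `summary_stats` containing the leads.
#' @param G_target Target-cohort [genotype_matrix()].
#' @return List of class `polygenic_score`: `scores` (named per-sample
#'   vector), `weights` (data frame id/beta/effect_allele), `n_dropped`.
#' @export
build_polygenic_score <- function(leads, assoc, G_target) {
  stopifnot(inherits(G_target, "genotype_matrix"))
  rows <- match(leads, assoc$id)
  if (anyNA(rows))
    stop_mm("invalid_argument", "lead(s) missing from assoc: %s",
            paste(leads[is.na(rows)], collapse = ", "))
  scores <- rep(0, nrow(G_target$dosage))
  used <- list()
  n_dropped <- 0L
  for (r in rows) {
    tid <- match(assoc$id[r], G_target$variants$id)
    if (is.na(tid)) { n_dropped <- n_dropped + 1L; next }
    tv <- G_target$variants[tid, ]
    if (tv$effect_allele == assoc$effect_allele[r] &&
        tv$other_allele == assoc$other_allele[r]) {
      dos <- G_target$dosage[, tid]
    } else if (tv$effect_allele == assoc$other_allele[r] &&
               tv$other_allele == assoc$effect_allele[r]) {
      dos <- 2 - G_target$dosage[, tid]
    } else {
      n_dropped <- n_dropped + 1L
      next
    }
    scores <- scores + assoc$beta[r] * dos
    used[[length(used) + 1L]] <- data.frame(
      id = assoc$id[r], beta = assoc$beta[r],
      effect_allele = assoc$effect_allele[r], stringsAsFactors = FALSE)
  }
  if (n_dropped > 0)
    warn_mm("variants_dropped",
            "%d lead variant(s) dropped (missing or incompatible alleles)",
            n_dropped)
  structure(list(scores = stats::setNames(scores, G_target$sample_ids),
                 weights = if (length(used)) do.call(rbind, used)
                 else data.frame(id = character(0), beta = numeric(0),
                                 effect_allele = character(0)),
                 n_dropped = n_dropped),
            class = "polygenic_score")
}

#' Test a polygenic score against a taxon outcome
#'
#' Association between a polygenic score and a microbiome outcome in the
#' replication design. Continuous outcomes (Z-scored log abundance) are
#' fitted by a Gaussian linear model; binary presence/absence outcomes by
#' logistic regression; `"nb_counts"` fits a negative-binomial GLM to raw
#' counts as an alternative abundance model. Covariates (ancestry PCs, age,
#' sex, batch) enter as fixed effects.
#'
#' @param score Numeric per-sample score (or a `polygenic_score`).
#' @param outcome Outcome vector aligned with `score`.
#' @param X Optional covariate matrix.
#' @param outcome_kind `"continuous"`, `"binary"` or `"nb_counts"`.
#' @return List: `estimate` (slope; log-odds for binary), `se`, `p`,
#'   `odds_ratio` (binary only), `model`.
#' @export
test_polygenic_score <- function(score, outcome, X = NULL,
                                 outcome_kind = c("continuous", "binary",
                                                  "nb_counts")) {
  outcome_kind <- match.arg(outcome_kind)
  if (inherits(score, "polygenic_score")) score <- score$scores
  if (length(score) != length(outcome))
    stop_mm("invalid_argument", "score and outcome lengths differ")
  dat <- data.frame(.y = outcome, .s = score)
  if (!is.null(X)) dat <- cbind(dat, as.data.frame(X))
  form <- stats::as.formula(paste(".y ~", paste(setdiff(names(dat), ".y"),
                                                collapse = " + ")))
  fit <- switch(outcome_kind,
    continuous = stats::lm(form, data = dat),
    binary = stats::glm(form, data = dat, family = stats::binomial()),
    nb_counts = MASS::glm.nb(form, data = dat)
  )
  if (inherits(fit, "glm") && !fit$converged)
    stop_mm("nonconvergence", "score association model did not converge")
  cf <- summary(fit)$coefficients
  est <- cf[".s", 1]; se <- cf[".s", 2]; p <- cf[".s", 4]
  list(estimate = est, se = se, p = p,
       odds_ratio = if (outcome_kind == "binary") exp(est) else NA_real_,
       model = outcome_kind)
}
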