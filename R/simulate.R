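#' Simulate LD-structured biallelic genotypes
#'
#' Generates allele dosages for a cohort by thresholding a latent Gaussian
#' with AR(1) block correlation: within each block of `ld_block_size`
#' variants, adjacent latent variables correlate at `ld_rho`; each haplotype
#' carries the minor allele where its latent value falls below the
#' MAF-matched quantile, and the dosage is the sum over two independent
#' haplotypes. Thresholding attenuates the realized dosage correlation
#' relative to the latent `ld_rho` (the usual tetrachoric-to-Pearson gap),
#' so e.g. `ld_rho = 0.9` yields adjacent dosage r-squared around 0.6-0.9
#' depending on MAF.
#'
#' Variants are placed every 2 kb along a single chromosome; centimorgan
#' positions follow the configured constant map rate.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()].
#' @examples
#' G <- simulate_genotypes(sim_config(n_samples = 50, n_variants = 40, seed = 1))
#' dim(G)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_samples
  m <- config$n_variants
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thresh <- stats::qnorm(maf)
  rho <- config$ld_rho
  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]

  draw_haplotype <- function() {
    z <- matrix(0, n, m)
    for (j in seq_len(m)) {
      if (j == 1L || block[j] != block[j - 1L]) {
        z[, j] <- stats::rnorm(n)
      } else {
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
      }
    }
    z
  }
  dosage <- (draw_haplotype() < rep(thresh, each = n)) +
    (draw_haplotype() < rep(thresh, each = n))
  storage.mode(dosage) <- "double"

  # guarantee polymorphism: redraw any near-monomorphic variant marginally
  for (attempt in 1:25) {
    realized <- colMeans(dosage) / 2
    low <- pmin(realized, 1 - realized) < 0.01
    if (!any(low)) break
    for (j in which(low)) {
      dosage[, j] <- (stats::rnorm(n) < thresh[j]) + (stats::rnorm(n) < thresh[j])
    }
  }

  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, m, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
  pos_bp <- 2000L * seq_len(m)
  variants <- data.frame(
    id = sprintf("v%05d", seq_len(m)),
    chrom = "1",
    pos_bp = pos_bp,
    pos_cm = pos_bp * config$map_cm_per_mb / 1e6,
    effect_allele = ea,
    other_allele = unname(oa),
    maf = colMeans(dosage) / 2,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, variants,
                  sample_ids = sprintf("S%05d", seq_len(n)))
}

#' Simulate a taxon abundance table with known genetic architecture
#'
#' Common taxa follow a log-normal model: each taxon's latent log-abundance
#' is the sum of a genetic value (a weighted sum of `n_causal_per_taxon`
#' standardized dosages) and Gaussian noise, with the two parts empirically
#' scaled so the genetic fraction of the latent variance equals `taxon_h2`
#' exactly in-sample. Rare taxa are zero-inflated: presence follows a
#' liability-threshold (probit) model at a per-taxon target prevalence drawn
#' from `rare_prevalence_range`, and abundance conditional on presence is
#' log-normal. Observed counts are produced by multinomial sampling of
#' `config$depth` reads per sample from the latent relative abundances.
#'
#' @param G A [genotype_matrix()] for the cohort.
#' @param config A [sim_config()].
#' @param extra Optional list with element `values`, an n-samples by
#'   n-common-taxa matrix added to the latent log-abundances after the
#'   heritability partition (used to inject disease-on-taxon effects).
#' @return A list with elements `table` (a counts [taxon_table()]) and
#'   `truth` (a `ground_truth` list holding per-taxon causal variants and
#'   standardized effects, true heritabilities, the latent genetic values and
#'   log-abundances, and rare-taxon prevalence targets).
#' @export
simulate_taxon_table <- function(G, config, extra = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "sim_config"))
  if (nrow(G$dosage) == 0L)
    stop_mm("invalid_argument", "empty genotype matrix")
  if (config$taxon_h2 >= 1)
    stop_mm("invalid_config", "taxon_h2 must be < 1")
  set.seed(derive_seed(config$seed, 2L))
  n <- nrow(G$dosage)
  m <- ncol(G$dosage)
  nc <- config$n_taxa_common
  nr <- config$n_taxa_rare
  h2 <- config$taxon_h2
  Z <- scale(G$dosage)  # standardized dosages

  genetic <- matrix(0, n, nc)
  logab <- matrix(0, n, nc)
  causal <- vector("list", nc)
  mu_common <- stats::rnorm(nc, 0, 0.7)
  for (t in seq_len(nc)) {
    idx <- sample.int(m, config$n_causal_per_taxon)
    # equal-magnitude, random-sign causal effects: each causal variant
    # contributes h2 / n_causal of the latent variance, giving instruments
    # of comparable strength
    u <- sample(c(-1, 1), length(idx), replace = TRUE)
    g <- as.vector(Z[, idx, drop = FALSE] %*% u)
    scale_g <- if (h2 > 0 && stats::sd(g) > 0) sqrt(h2) / stats::sd(g) else 0
    g <- g * scale_g
    e <- stats::rnorm(n)
    e <- e * sqrt(1 - h2) / stats::sd(e)
    genetic[, t] <- g
    logab[, t] <- mu_common[t] + g + e
    causal[[t]] <- data.frame(id = G$variants$id[idx],
                              beta = u * scale_g,
                              stringsAsFactors = FALSE)
  }
  if (!is.null(extra)) {
    stopifnot(is.matrix(extra$values),
              all(dim(extra$values) == c(n, nc)))
    logab <- logab + extra$values
  }

  prev_target <- if (nr > 0)
    stats::runif(nr, config$rare_prevalence_range[1],
                 config$rare_prevalence_range[2]) else numeric(0)
  rare_logab <- matrix(-Inf, n, max(nr, 0))
  for (t in seq_len(nr)) {
    present <- stats::rnorm(n) < stats::qnorm(prev_target[t])
    ab <- stats::rnorm(n, -1.5, 0.5)
    rare_logab[present, t] <- ab[present]
  }

  weights <- cbind(exp(logab),
                   if (nr > 0) exp(rare_logab) else NULL)
  probs <- weights / rowSums(weights)
  counts <- vapply(seq_len(n),
                   function(i) stats::rmultinom(1L, config$depth, probs[i, ])[, 1L],
                   numeric(nc + nr))
  counts <- if (is.matrix(counts)) t(counts) else matrix(counts, ncol = 1L)
  ids <- c(sprintf("genus|Taxon%03d", seq_len(nc)),
           if (nr > 0) sprintf("genus|RareTaxon%03d", seq_len(nr)))
  names(causal) <- ids[seq_len(nc)]
  tt <- taxon_table(counts, ids, G$sample_ids, type = "counts")
  truth <- structure(list(
    causal_variants = causal,
    h2 = stats::setNames(rep(h2, nc), ids[seq_len(nc)]),
    genetic_values = `dimnames<-`(genetic, list(G$sample_ids, ids[seq_len(nc)])),
    latent_logabund = `dimnames<-`(logab, list(G$sample_ids, ids[seq_len(nc)])),
    rare_prevalence = if (nr > 0)
      stats::setNames(prev_target, ids[nc + seq_len(nr)]) else numeric(0)
  ), class = "ground_truth")
  list(table = tt, truth = truth)
}

#' Simulate external GWAS summary statistics for a disease
#'
#' Produces an instrument table in the standard summary-statistics dialect.
#' In the default (reverse-direction) mode the instruments carry true effects
#' on a latent disease liability, drawn uniformly from
#' `instrument_beta_range` with random signs (log-odds per effect allele).
#' When `exposure` is supplied (forward mode), the instruments are the
#' exposure's causal variants and their true outcome effects equal
#' `causal_effect` times the exposure effects, i.e. a purely mediated signal.
#' In both modes a fraction `pleiotropy_fraction` of instruments receive an
#' additional direct effect (directional, positive), violating the exclusion
#' restriction; these are recorded in the attached ground truth.
#'
#' Observed betas are the true effects plus sampling noise at the standard
#' error implied by an external GWAS of `config$gwas_n` samples.
#'
#' @param config A [sim_config()].
#' @param variants Optional data frame of variant metadata rows (the dialect
#'   of `genotype_matrix$variants`) to use as instruments; defaults to
#'   fabricated independent variants.
#' @param exposure Optional list with `variants` (metadata rows) and `beta`
#'   (true exposure effects per effect allele) switching to forward mode.
#' @return A `summary_stats` data frame with attribute `truth`: a list with
#'   `true_beta`, `pleiotropic` (logical) and `direct_effect` per instrument.
#' @export
simulate_outcome_summary_stats <- function(config, variants = NULL,
                                           exposure = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(exposure) && config$n_instruments < 3L)
    stop_mm("invalid_config", "n_instruments must be >= 3")
  set.seed(derive_seed(config$seed, 3L))
  if (!is.null(exposure)) {
    variants <- exposure$variants
    k <- nrow(variants)
    true_beta <- config$causal_effect * exposure$beta
  } else {
    k <- config$n_instruments
    if (is.null(variants)) {
      maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
      bases <- c("A", "C", "G", "T")
      ea <- sample(bases, k, replace = TRUE)
      oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
      pos <- 1000000L * seq_len(k)
      variants <- data.frame(id = sprintf("iv%04d", seq_len(k)), chrom = "2",
                             pos_bp = pos,
                             pos_cm = pos * config$map_cm_per_mb / 1e6,
                             effect_allele = ea, other_allele = unname(oa),
                             maf = maf, stringsAsFactors = FALSE)
    }
    k <- nrow(variants)
    true_beta <- sample(c(-1, 1), k, replace = TRUE) *
      stats::runif(k, config$instrument_beta_range[1],
                   config$instrument_beta_range[2])
  }
  n_pleio <- round(config$pleiotropy_fraction * k)
  pleio <- rep(FALSE, k)
  direct <- rep(0, k)
  if (n_pleio > 0) {
    pick <- sample.int(k, n_pleio)
    pleio[pick] <- TRUE
    direct[pick] <- stats::runif(n_pleio, config$instrument_beta_range[1],
                                 config$instrument_beta_range[2])
  }
  eaf <- variants$maf
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * config$gwas_n)
  beta_hat <- true_beta + stats::rnorm(k, 0, se)
  stats <- data.frame(
    id = variants$id, chrom = variants$chrom, pos_bp = variants$pos_bp,
    pos_cm = variants$pos_cm, effect_allele = variants$effect_allele,
    other_allele = variants$other_allele, eaf = eaf,
    beta = beta_hat, se = se,
    p = 2 * stats::pnorm(-abs(beta_hat / se)),
    n = config$gwas_n, stringsAsFactors = FALSE
  )
  out <- as_summary_stats(stats)
  attr(out, "truth") <- list(true_beta = stats::setNames(true_beta, stats$id),
                             pleiotropic = stats::setNames(pleio, stats$id),
                             direct_effect = stats::setNames(direct, stats$id))
  out
}

#' Simulate a pathway/disease abundance table from taxa
#'
#' Emulates the output of functional prediction from 16S profiles: each
#' pathway feature is a non-negative linear combination of a designated
#' disjoint subset of taxa plus Gaussian noise (its SD expressed as
#' `pathway_noise_sd` times the feature's signal SD, truncated at zero).
#' Features built from the same taxon subset share a ground-truth cluster
#' label, which downstream PAM clustering should recover at low noise.
#'
#' @param T A [taxon_table()] (counts or relative; converted internally).
#' @param config A [sim_config()].
#' @return List with `table` (a `pathway_table`: list of `values`,
#'   `feature_ids`, `sample_ids`) and `truth` (named integer vector of
#'   ground-truth cluster labels per feature).
#' @export
simulate_pathway_table <- function(T, config) {
  stopifnot(inherits(T, "taxon_table"), inherits(config, "sim_config"))
  if (nrow(T$values) == 0L)
    stop_mm("invalid_argument", "empty taxon table")
  set.seed(derive_seed(config$seed, 4L))
  rel <- relative_abundance(T)$values
  n_feat <- config$n_pathway_features
  n_clust <- config$n_pathway_clusters
  if (n_clust > ncol(rel))
    stop_mm("invalid_config", "more pathway clusters than taxa")
  subset_size <- max(1L, floor(ncol(rel) / n_clust))
  taxon_order <- sample.int(ncol(rel))
  subsets <- lapply(seq_len(n_clust), function(c)
    taxon_order[(c - 1L) * subset_size + seq_len(subset_size)])
  labels <- rep(seq_len(n_clust), length.out = n_feat)
  values <- matrix(0, nrow(rel), n_feat)
  for (f in seq_len(n_feat)) {
    s <- subsets[[labels[f]]]
    w <- stats::runif(length(s), 0.5, 1.5)
    signal <- as.vector(rel[, s, drop = FALSE] %*% w)
    noise_sd <- config$pathway_noise_sd * stats::sd(signal)
    values[, f] <- pmax(0, signal + stats::rnorm(length(signal), 0, noise_sd))
  }
  feature_ids <- sprintf("Disease%02d", seq_len(n_feat))
  colnames(values) <- feature_ids
  rownames(values) <- T$sample_ids
  tbl <- structure(list(values = values, feature_ids = feature_ids,
                        sample_ids = T$sample_ids),
                   class = "pathway_table")
  list(table = tbl, truth = stats::setNames(labels, feature_ids))
}

#' Simulate a complete synthetic cohort bundle
#'
#' Ties the generator operations together into the full study design:
#' genotypes; an external disease GWAS whose instruments are thinned cohort
#' variants (one per LD block) with true liability effects; a taxon table in
#' which a designated set of "reverse-target" common taxa receive the genetic
#' disease liability scaled by `causal_effect` (the reverse-causal channel)
#' plus any pleiotropic direct instrument effects; host covariates (age, sex,
#' dietary energy, alcohol intake, BMI, sequencing batch); a binary disease
#' status generated from a logistic model on the first `n_disease_taxa`
#' common taxa (coefficient `causal_effect` per 1-SD latent log-abundance,
#' intercept solved numerically for the target prevalence); and a pathway
#' table. When `out_dir` is given, every component is also written in the
#' package's TSV/JSON dialects.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory to write the bundle to.
#' @return A list of class `cohort_bundle` with elements `genotypes`,
#'   `taxa`, `covariates`, `disease`, `disease_stats`, `pathways`, `truth`
#'   and (if written) `files`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  G <- simulate_genotypes(config)
  n <- config$n_samples

  # external disease GWAS on thinned cohort variants (one per LD block)
  block_first <- seq(1L, config$n_variants, by = config$ld_block_size)
  set.seed(derive_seed(config$seed, 5L))
  iv_idx <- sort(sample(block_first, min(config$n_instruments,
                                         length(block_first))))
  disease_stats <- simulate_outcome_summary_stats(
    config, variants = G$variants[iv_idx, , drop = FALSE])
  iv_truth <- attr(disease_stats, "truth")

  # reverse-causal channel: genetic liability pushed into target taxa
  set.seed(derive_seed(config$seed, 6L))
  liab_g <- as.vector(G$dosage[, iv_idx, drop = FALSE] %*% iv_truth$true_beta)
  liab_g <- if (stats::sd(liab_g) > 0) scale(liab_g)[, 1] else liab_g
  n_rev <- min(4L, config$n_taxa_common)
  rev_targets <- seq_len(n_rev)
  extra <- matrix(0, n, config$n_taxa_common)
  extra[, rev_targets] <- config$causal_effect * liab_g
  # disease taxa share a latent community factor, mirroring the co-occurring
  # taxon groups that let one predicted disease feature correlate with many
  # taxa at once
  if (config$n_disease_taxa > 0) {
    community <- stats::rnorm(n)
    extra[, seq_len(config$n_disease_taxa)] <-
      extra[, seq_len(config$n_disease_taxa)] + 0.8 * community
  }
  if (any(iv_truth$pleiotropic)) {
    pleio_score <- as.vector(
      G$dosage[, iv_idx[iv_truth$pleiotropic], drop = FALSE] %*%
        iv_truth$direct_effect[iv_truth$pleiotropic])
    extra[, rev_targets] <- extra[, rev_targets] + scale(pleio_score)[, 1] * 0.2
  }
  sim_tt <- simulate_taxon_table(G, config, extra = list(values = extra))

  set.seed(derive_seed(config$seed, 7L))
  covariates <- data.frame(
    sample_id = G$sample_ids,
    age = round(stats::runif(n, 40, 75)),
    sex = stats::rbinom(n, 1L, 0.5),
    energy_intake = stats::rnorm(n, 2000, 400),
    alcohol_intake = exp(stats::rnorm(n, 1.5, 0.8)),
    bmi = stats::rnorm(n, 23.5, 3),
    batch = sample(1:2, n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # binary disease from a logistic model on designated taxa
  k <- config$n_disease_taxa
  disease_truth <- NULL
  lp <- rep(0, n)
  if (k > 0) {
    zl <- scale(sim_tt$truth$latent_logabund[, seq_len(k), drop = FALSE])
    lp <- as.vector(zl %*% rep(config$causal_effect, k))
    disease_truth <- stats::setNames(rep(config$causal_effect, k),
                                     colnames(zl))
  }
  target <- config$disease_prevalence
  icpt <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - target,
                         c(-20, 20))$root
  disease <- stats::rbinom(n, 1L, stats::plogis(icpt + lp))

  # external GWAS of a quantitative trait causally downstream of the focal
  # taxon (the last common taxon, outside the reverse-target set): the true
  # per-allele marginal effect on the trait is causal_effect times the
  # variant's empirical marginal effect on the taxon's latent log-abundance,
  # which propagates LD correctly so IVW should recover causal_effect.
  set.seed(derive_seed(config$seed, 8L))
  focal <- config$n_taxa_common
  z_focal <- scale(sim_tt$truth$latent_logabund[, focal])[, 1]
  Xc <- scale(G$dosage, scale = FALSE)
  beta_marg <- as.vector(crossprod(Xc, z_focal)) / (n - 1) /
    apply(G$dosage, 2L, stats::var)
  true_trait <- config$causal_effect * beta_marg
  eaf_all <- G$variants$maf
  se_all <- 1 / sqrt(2 * eaf_all * (1 - eaf_all) * config$gwas_n)
  bh <- true_trait + stats::rnorm(length(true_trait), 0, se_all)
  trait_stats <- as_summary_stats(data.frame(
    id = G$variants$id, chrom = G$variants$chrom,
    pos_bp = G$variants$pos_bp, pos_cm = G$variants$pos_cm,
    effect_allele = G$variants$effect_allele,
    other_allele = G$variants$other_allele,
    eaf = eaf_all, beta = bh, se = se_all,
    p = 2 * stats::pnorm(-abs(bh / se_all)),
    n = config$gwas_n, stringsAsFactors = FALSE))

  sim_pw <- simulate_pathway_table(sim_tt$table, config)

  # PICRUSt-style predicted disease abundance: a noisy combination of the
  # disease taxa, used to train the microbiome risk score
  set.seed(derive_seed(config$seed, 9L))
  predicted_disease <- NULL
  if (k > 0) {
    rel <- relative_abundance(sim_tt$table)$values[, seq_len(k), drop = FALSE]
    sig <- rowSums(rel)
    predicted_disease <- stats::setNames(
      pmax(0, sig + stats::rnorm(n, 0, 0.1 * stats::sd(sig))), G$sample_ids)
  }

  truth <- sim_tt$truth
  truth$instruments <- iv_truth
  truth$instrument_ids <- G$variants$id[iv_idx]
  truth$reverse_target_taxa <- colnames(sim_tt$truth$latent_logabund)[rev_targets]
  truth$reverse_effect <- config$causal_effect
  truth$disease_taxa_effects <- disease_truth
  truth$pathway_clusters <- sim_pw$truth
  truth$forward <- list(taxon = colnames(sim_tt$truth$latent_logabund)[focal],
                        effect = config$causal_effect,
                        true_marginal = stats::setNames(beta_marg,
                                                        G$variants$id))
  truth$config <- unclass(config)
  truth$seed <- config$seed

  bundle <- structure(list(
    genotypes = G, taxa = sim_tt$table, covariates = covariates,
    disease = stats::setNames(disease, G$sample_ids),
    disease_stats = disease_stats, trait_stats = trait_stats,
    pathways = sim_pw$table, predicted_disease = predicted_disease,
    truth = truth
  ), class = "cohort_bundle")
  if (!is.null(out_dir)) bundle$files <- write_cohort(bundle, out_dir)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d samples; %d variants; %d taxa; %d pathway features\n",
              length(x$disease), ncol(x$genotypes$dosage),
              ncol(x$taxa$values), ncol(x$pathways$values)))
  cat(sprintf("  disease cases: %d (%.1f%%); instruments: %d\n",
              sum(x$disease), 100 * mean(x$disease),
              length(x$truth$instrument_ids)))
  invisible(x)
}
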