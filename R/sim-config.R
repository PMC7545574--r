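#' Simulation configuration for the synthetic cohort generator
#'
#' Collects and validates every parameter of the synthetic-data module. The
#' generator emulates a genotyped cohort with 16S-style taxon profiles:
#' LD-structured biallelic genotypes, log-normal common taxa with a
#' controllable SNP-heritable component, zero-inflated rare taxa, an external
#' disease GWAS providing instruments, and pathway-abundance features that are
#' noisy linear functions of taxa.
#'
#' @param n_samples Number of cohort individuals.
#' @param n_variants Number of biallelic variants.
#' @param maf_range Length-2 numeric, sampling range of minor-allele
#'   frequencies; must lie within (0, 0.5].
#' @param ld_block_size Variants per LD block (AR(1) latent correlation).
#' @param ld_rho Within-block adjacent-variant latent correlation, in [0, 1).
#' @param map_cm_per_mb Genetic-map rate used to convert bp to cM. Default 1
#'   cM per Mb.
#' @param n_taxa_common,n_taxa_rare Numbers of common (log-normal) and rare
#'   (zero-inflated) taxa.
#' @param taxon_h2 SNP heritability of each common taxon's latent
#'   log-abundance, in [0, 1).
#' @param n_causal_per_taxon Causal variants per common taxon.
#' @param rare_prevalence_range Length-2 numeric in (0, 0.9); per-taxon
#'   presence prevalence targets are drawn uniformly from it.
#' @param n_instruments Number of disease instruments in the simulated
#'   external GWAS.
#' @param instrument_beta_range Length-2 positive numeric; absolute true
#'   instrument effects (log-odds per allele) are drawn uniformly from it.
#' @param pleiotropy_fraction Fraction of instruments that also receive a
#'   direct (horizontally pleiotropic) effect on downstream taxa.
#' @param causal_effect Structural effect size linking exposure and outcome
#'   (taxon on trait in forward simulations; disease liability on taxa in
#'   reverse simulations).
#' @param seed Integer master seed; fully determines all generator output.
#' @param depth Sequencing depth (reads per sample) for multinomial count
#'   sampling. Default 10,000, a typical rarefaction depth for 16S data.
#' @param gwas_n Sample size of the simulated external disease GWAS; controls
#'   instrument standard errors.
#' @param n_pathway_features,n_pathway_clusters Pathway-table dimensions:
#'   features are split evenly over ground-truth clusters.
#' @param pathway_noise_sd Noise standard deviation for pathway features,
#'   expressed relative to each feature's signal SD.
#' @param n_disease_taxa Number of common taxa given direct effects on the
#'   binary disease outcome in [simulate_cohort()]; defaults to 16 (as in a
#'   16-taxon microbiome risk score) capped at `n_taxa_common`.
#' @param disease_prevalence Approximate cohort disease prevalence.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_samples = 200, n_variants = 100, seed = 1)
#' cfg$ld_rho
#' @export
sim_config <- function(n_samples = 1000L,
                       n_variants = 2000L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 20L,
                       ld_rho = 0.8,
                       map_cm_per_mb = 1.0,
                       n_taxa_common = 20L,
                       n_taxa_rare = 10L,
                       taxon_h2 = 0.3,
                       n_causal_per_taxon = 10L,
                       rare_prevalence_range = c(0.1, 0.8),
                       n_instruments = 30L,
                       instrument_beta_range = c(0.05, 0.3),
                       pleiotropy_fraction = 0,
                       causal_effect = 0.1,
                       seed = 1L,
                       depth = 10000L,
                       gwas_n = 5000L,
                       n_pathway_features = 20L,
                       n_pathway_clusters = 5L,
                       pathway_noise_sd = 0.1,
                       n_disease_taxa = NULL,
                       disease_prevalence = 0.115) {
  if (is.null(n_disease_taxa))
    n_disease_taxa <- min(16L, n_taxa_common)
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    n_variants = check_count(n_variants, "n_variants"),
    maf_range = maf_range,
    ld_block_size = check_count(ld_block_size, "ld_block_size"),
    ld_rho = check_scalar_number(ld_rho, "ld_rho", 0, 1, strict_upper = TRUE),
    map_cm_per_mb = check_scalar_number(map_cm_per_mb, "map_cm_per_mb", 0,
                                        strict_lower = TRUE),
    n_taxa_common = check_count(n_taxa_common, "n_taxa_common"),
    n_taxa_rare = check_count(n_taxa_rare, "n_taxa_rare", min = 0L),
    taxon_h2 = check_scalar_number(taxon_h2, "taxon_h2", 0, 1,
                                   strict_upper = TRUE),
    n_causal_per_taxon = check_count(n_causal_per_taxon, "n_causal_per_taxon"),
    rare_prevalence_range = rare_prevalence_range,
    n_instruments = check_count(n_instruments, "n_instruments"),
    instrument_beta_range = instrument_beta_range,
    pleiotropy_fraction = check_scalar_number(pleiotropy_fraction,
                                              "pleiotropy_fraction", 0, 1),
    causal_effect = check_scalar_number(causal_effect, "causal_effect"),
    seed = check_count(seed, "seed", min = 0L),
    depth = check_count(depth, "depth"),
    gwas_n = check_count(gwas_n, "gwas_n"),
    n_pathway_features = check_count(n_pathway_features, "n_pathway_features"),
    n_pathway_clusters = check_count(n_pathway_clusters, "n_pathway_clusters"),
    pathway_noise_sd = check_scalar_number(pathway_noise_sd,
                                           "pathway_noise_sd", 0),
    n_disease_taxa = check_count(n_disease_taxa, "n_disease_taxa", min = 0L),
    disease_prevalence = check_scalar_number(disease_prevalence,
                                             "disease_prevalence", 0, 1,
                                             strict_lower = TRUE,
                                             strict_upper = TRUE)
  )
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_mm("invalid_config", "maf_range must be increasing within (0, 0.5]")
  if (length(rare_prevalence_range) != 2L ||
      any(rare_prevalence_range <= 0) || any(rare_prevalence_range >= 0.9) ||
      rare_prevalence_range[1] > rare_prevalence_range[2])
    stop_mm("invalid_config",
            "rare_prevalence_range must be increasing within (0, 0.9)")
  if (length(instrument_beta_range) != 2L || any(instrument_beta_range <= 0) ||
      instrument_beta_range[1] > instrument_beta_range[2])
    stop_mm("invalid_config", "instrument_beta_range must be increasing and positive")
  if (cfg$ld_block_size > cfg$n_variants)
    stop_mm("invalid_config",
            "ld_block_size (%d) exceeds n_variants (%d)",
            cfg$ld_block_size, cfg$n_variants)
  if (cfg$n_causal_per_taxon > cfg$n_variants)
    stop_mm("invalid_config", "n_causal_per_taxon exceeds n_variants")
  if (cfg$n_disease_taxa > cfg$n_taxa_common)
    stop_mm("invalid_config", "n_disease_taxa exceeds n_taxa_common")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d samples, %d variants (blocks of %d, rho = %.2f)\n",
              x$n_samples, x$n_variants, x$ld_block_size, x$ld_rho))
  cat(sprintf("  taxa: %d common (h2 = %.2f, %d causal each), %d rare\n",
              x$n_taxa_common, x$taxon_h2, x$n_causal_per_taxon, x$n_taxa_rare))
  cat(sprintf("  instruments: %d, pleiotropy fraction %.2f, causal effect %.2f\n",
              x$n_instruments, x$pleiotropy_fraction, x$causal_effect))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
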