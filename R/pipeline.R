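#' Validate a pipeline configuration
#'
#' Checks the configuration before any stage executes: the input must be
#' either a `simulate` block (arguments for [sim_config()]) or an existing
#' dataset directory; a global integer `seed` is mandatory (every stochastic
#' stage derives its own stream from it), and when the `mr` stage is enabled
#' the MR-PRESSO simulation count `params$n_sim` must be stated explicitly.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `input` (either `list(dir = ...)` or `list(simulate = list(...))`),
#'   `out_dir`, `seed`, optional `stages` (subset of `"features"`,
#'   `"heritability"`, `"gwas"`, `"mr"`, `"cluster"`, `"mrs"`; default all)
#'   and optional `params` overriding thresholds.
#' @return The normalized configuration, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop_mm("validation_error", "config must be a list or YAML path")
  all_stages <- c("features", "heritability", "gwas", "mr", "cluster", "mrs")
  if (is.null(config$stages)) config$stages <- all_stages
  bad <- setdiff(config$stages, all_stages)
  if (length(bad))
    stop_mm("validation_error", "unknown stage(s): %s",
            paste(bad, collapse = ", "))
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      config$seed != round(config$seed))
    stop_mm("validation_error", "config$seed (integer) is required")
  if (is.null(config$out_dir))
    stop_mm("validation_error", "config$out_dir is required")
  if (is.null(config$input) ||
      (is.null(config$input$dir) && is.null(config$input$simulate)))
    stop_mm("validation_error",
            "config$input must provide `dir` or `simulate`")
  if (!is.null(config$input$dir) && !dir.exists(config$input$dir))
    stop_mm("validation_error", "input dir does not exist: %s",
            config$input$dir)
  defaults <- list(p_thresh = 5e-5, r2_thresh = 0.1, window_cm = 0.1,
                   prevalence_threshold = 0.9, n_boot = 1000L,
                   n_tests_forward = 62, n_h2_taxa = 3L,
                   run_enterotypes = FALSE)
  config$params <- utils::modifyList(defaults,
                                     if (is.null(config$params)) list()
                                     else config$params)
  if ("mr" %in% config$stages && is.null(config$params$n_sim))
    stop_mm("validation_error",
            "params$n_sim (MR-PRESSO simulation count) must be set when the mr stage is enabled")
  invisible(config)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the stages in dependency order on a simulated or loaded cohort:
#' taxon-table processing (prevalence partition, Z-scored log abundances,
#' alpha diversity, effective number of independent taxa), GRM + GREML
#' heritability for the leading common taxa, a covariate-adjusted GWAS of
#' the focal taxon with genomic-inflation control, LD clumping and a
#' polygenic score, bidirectional Mendelian randomization with the two-tier
#' classification, pathway-feature clustering with silhouette-selected k,
#' and the microbiome risk score. Every output table is written under
#' `out_dir` with a provenance header (configuration hash and seed); rerun
#' with the same configuration is byte-identical.
#'
#' @param config See [validate_pipeline_config()].
#' @return List of class `pipeline_result` with per-stage results and
#'   `out_dir`; written files are listed in `$files`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # provenance hashes the scientific configuration, not the output location
  prov <- provenance_line(config[setdiff(names(config), "out_dir")],
                          config$seed)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_tsv_prov(df, path, prov)
    files <<- c(files, path)
  }
  res <- list()

  # ---- input ----
  if (!is.null(config$input$simulate)) {
    sim_args <- config$input$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    bundle <- simulate_cohort(do.call(sim_config, sim_args))
  } else {
    bundle <- load_dataset(config$input$dir)
  }
  res$bundle <- bundle
  n <- nrow(bundle$taxa$values)

  # ---- features ----
  part <- prevalence_partition(bundle$taxa, p$prevalence_threshold)
  z <- transform_common_abundance(part$common)
  alpha <- alpha_diversity(bundle$taxa)
  n_eff <- effective_number_independent_taxa(z)
  res$features <- list(partition = part, z = z, alpha = alpha, n_eff = n_eff)
  if ("features" %in% config$stages) {
    emit(alpha, "alpha_diversity.tsv")
    emit(data.frame(level = "genus", n_taxa = ncol(z), n_eff = n_eff),
         "effective_number.tsv")
    if (isTRUE(p$run_enterotypes)) {
      res$features$enterotypes <- assign_enterotypes(bundle$taxa)
      emit(data.frame(sample_id = bundle$taxa$sample_ids,
                      enterotype = res$features$enterotypes$labels),
           "enterotypes.tsv")
    }
  }

  covar_base <- as.matrix(bundle$covariates[, c("age", "sex")])

  # ---- heritability ----
  if ("heritability" %in% config$stages) {
    grm_fit <- compute_grm(bundle$genotypes)
    k_h2 <- min(p$n_h2_taxa, ncol(z))
    h2_rows <- lapply(seq_len(k_h2), function(t) {
      fit <- tryCatch(greml_heritability(grm_fit$grm, z[, t], covar_base),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(taxon = colnames(z)[t], h2 = fit$h2, se = fit$se,
                 converged = fit$converged, stringsAsFactors = FALSE)
    })
    res$heritability <- do.call(rbind, h2_rows)
    res$grm <- grm_fit
    emit(res$heritability, "heritability.tsv")
  }

  # ---- gwas + clump + prs ----
  if (any(c("gwas", "mr") %in% config$stages)) {
    if (is.null(res$grm)) res$grm <- compute_grm(bundle$genotypes)
    Xg <- cbind(res$grm$pcs,
                as.matrix(bundle$covariates[, c("age", "sex", "batch")]))
    focal <- if (!is.null(bundle$truth$forward$taxon) &&
                 bundle$truth$forward$taxon %in% colnames(z))
      bundle$truth$forward$taxon else colnames(z)[ncol(z)]
    scan <- association_scan(bundle$genotypes, z[, focal], Xg,
                             model = "linear")
    lambda <- genomic_inflation(scan$p)
    leads <- ld_clump(scan, bundle$genotypes, p_thresh = p$p_thresh,
                      r2_thresh = p$r2_thresh, window_cm = p$window_cm)
    res$gwas <- list(focal_taxon = focal, scan = scan, lambda = lambda,
                     leads = leads)
    if ("gwas" %in% config$stages) {
      emit(scan, sprintf("gwas_%s.tsv", gsub("[^A-Za-z0-9]", "_", focal)))
      emit(data.frame(focal_taxon = focal, lambda = lambda,
                      n_leads = length(leads)), "gwas_summary.tsv")
      if (length(leads)) {
        prs <- build_polygenic_score(leads, scan, bundle$genotypes)
        prs_test <- test_polygenic_score(prs, z[, focal], covar_base,
                                         outcome_kind = "continuous")
        res$gwas$prs <- prs
        res$gwas$prs_test <- prs_test
        emit(data.frame(sample_id = names(prs$scores), score = prs$scores),
             "polygenic_score.tsv")
      }
    }
  }

  # ---- mr ----
  if ("mr" %in% config$stages) {
    mr_rows <- list()
    seed_mr <- derive_seed(config$seed, 101L)
    # forward: focal taxon -> trait
    if (length(res$gwas$leads) && !is.null(bundle$trait_stats)) {
      iv <- tryCatch(
        select_instruments(res$gwas$scan[match(res$gwas$leads,
                                               res$gwas$scan$id), ],
                           bundle$trait_stats, direction = "forward"),
        error = function(e) character(0))
      if (length(iv)) {
        h_fwd <- harmonize_instruments(
          res$gwas$scan[match(iv, res$gwas$scan$id), ],
          bundle$trait_stats, direction = "microbiome_to_trait")
        fit_fwd <- run_mr(h_fwd, n_boot = p$n_boot, n_sim = p$n_sim,
                          seed = seed_mr)
        cls_fwd <- classify_mr_result(fit_fwd, "forward",
                                      n_tests_forward = p$n_tests_forward)
        res$mr_forward <- list(instruments = h_fwd, fit = fit_fwd,
                               classification = cls_fwd)
        mr_rows[[length(mr_rows) + 1L]] <-
          mr_result_rows(res$gwas$focal_taxon, "trait", "forward",
                         fit_fwd, cls_fwd)
      }
    }
    # reverse: disease -> first reverse-target taxon
    if (!is.null(bundle$disease_stats)) {
      iv_rev <- select_instruments(bundle$disease_stats,
                                   direction = "reverse",
                                   ld_ref = bundle$genotypes,
                                   r2_thresh = p$r2_thresh)
      rev_taxon <- if (!is.null(bundle$truth$reverse_target_taxa))
        bundle$truth$reverse_target_taxa[1] else colnames(z)[1]
      Xg <- cbind(res$grm$pcs,
                  as.matrix(bundle$covariates[, c("age", "sex", "batch")]))
      scan_rev <- association_scan(bundle$genotypes, z[, rev_taxon], Xg,
                                   model = "linear")
      h_rev <- harmonize_instruments(
        bundle$disease_stats[match(iv_rev, bundle$disease_stats$id), ],
        scan_rev, direction = "disease_to_microbiome")
      fit_rev <- run_mr(h_rev, n_boot = p$n_boot, n_sim = p$n_sim,
                        seed = seed_mr + 1L)
      cls_rev <- classify_mr_result(fit_rev, "reverse",
                                    n_eff_taxa = res$features$n_eff)
      res$mr_reverse <- list(instruments = h_rev, fit = fit_rev,
                             classification = cls_rev, taxon = rev_taxon)
      mr_rows[[length(mr_rows) + 1L]] <-
        mr_result_rows("disease", rev_taxon, "reverse", fit_rev, cls_rev)
    }
    if (length(mr_rows))
      emit(do.call(rbind, mr_rows), "mr_results.tsv")
  }

  # ---- cluster ----
  if ("cluster" %in% config$stages && !is.null(bundle$pathways)) {
    zf <- scale(bundle$pathways$values)
    keep <- !apply(zf, 2L, anyNA)
    sel <- choose_k_by_silhouette(t(zf[, keep, drop = FALSE]),
                                  k_range = 2:min(10, sum(keep) - 1L))
    res$cluster <- sel
    if (!is.null(bundle$truth$pathway_clusters)) {
      truth_lab <- unlist(bundle$truth$pathway_clusters)[names(sel$solution$labels)]
      res$cluster$jaccard_vs_truth <-
        jaccard_cluster_similarity(sel$solution$labels, truth_lab)
    }
    emit(data.frame(feature = names(sel$solution$labels),
                    cluster = sel$solution$labels,
                    silhouette = sel$solution$silhouette),
         "pathway_clusters.tsv")
  }

  # ---- mrs ----
  if ("mrs" %in% config$stages && !is.null(bundle$predicted_disease) &&
      !is.null(bundle$disease)) {
    model <- build_mrs(bundle$taxa, bundle$predicted_disease)
    covar_mrs <- as.matrix(bundle$covariates[, c("age", "sex",
                                                 "energy_intake",
                                                 "alcohol_intake", "bmi")])
    mrs <- score_and_test_mrs(model, bundle$taxa, bundle$disease, covar_mrs)
    res$mrs <- list(model = model, result = mrs)
    emit(data.frame(sample_id = names(mrs$scores), score = mrs$scores,
                    disease = as.integer(bundle$disease)),
         "mrs_scores.tsv")
    emit(data.frame(n_taxa = nrow(model$taxa), odds_ratio = mrs$odds_ratio,
                    ci_low = mrs$ci[1], ci_high = mrs$ci[2], p = mrs$p),
         "mrs_test.tsv")
  }

  res$files <- files
  res$out_dir <- config$out_dir
  res$config <- config
  class(res) <- "pipeline_result"
  res
}

mr_result_rows <- function(exposure, outcome, direction, fit, cls) {
  methods <- c("ivw", "weighted_median", "egger", "presso")
  do.call(rbind, lapply(methods, function(m) {
    r <- fit[[m]]
    data.frame(exposure = exposure, outcome = outcome, direction = direction,
               method = m,
               estimate = if (is.null(r)) NA_real_ else r$estimate,
               se = if (is.null(r)) NA_real_ else r$se,
               p = if (is.null(r)) NA_real_ else r$p,
               classification = cls$classification,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  stages run:", paste(x$config$stages, collapse = ", "), "\n")
  cat("  outputs:", length(x$files), "files in", x$out_dir, "\n")
  if (!is.null(x$mr_forward))
    cat("  forward MR:", x$mr_forward$classification$classification, "\n")
  if (!is.null(x$mr_reverse))
    cat("  reverse MR:", x$mr_reverse$classification$classification, "\n")
  invisible(x)
}
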