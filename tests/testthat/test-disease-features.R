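test_that("PAM solves the 1-D worked example and trivial cases", {
  d <- dist(c(0, 0.1, 10, 10.1))
  sol <- pam_cluster(d, 2)
  expect_equal(unname(sol$labels), c(1, 1, 2, 2))
  expect_equal(sol$objective, 0.2)
  # k = n: every object its own medoid, objective 0
  sol_n <- pam_cluster(d, 4)
  expect_equal(sol_n$objective, 0)
  expect_error(pam_cluster(matrix(c(0, 1, 2, 0), 2, 2), 1),
               class = "invalid_input")
})

test_that("PAM SWAP attains the exhaustive optimum on random instances", {
  hits <- vapply(1:100, function(s) {
    inst <- random_cluster_instance(s)
    sol <- pam_cluster(inst$d, inst$k)
    best <- pam_exhaustive(inst$d, inst$k)
    expect_gte(sol$objective, best - 1e-10)   # never below the optimum
    sol$objective <= best + 1e-10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("PAM agrees with the reference cluster implementation", {
  skip_if_not_installed("cluster")
  set.seed(81)
  x <- matrix(rnorm(60), 30, 2)
  d <- dist(x)
  for (k in 2:4) {
    ours <- pam_cluster(d, k)
    ref <- cluster::pam(d, k)
    expect_equal(ours$objective,
                 ref$objective[["swap"]] * 30, tolerance = 1e-6)
  }
})

test_that("silhouette widths follow the displayed formula", {
  # object equidistant to its own and the nearest foreign cluster: width 0
  d <- matrix(c(0, 2, 2,
                2, 0, 2,
                2, 2, 0), 3, 3)
  sw <- silhouette_widths(d, c(1, 1, 2))
  expect_equal(sw[1], 0)    # N = 2 (to obj 2), M = 2 (to obj 3)
  expect_true(all(sw >= -1 & sw <= 1))
  # singleton cluster convention: width 0
  expect_equal(sw[3], 0)
})

test_that("silhouette-based selection picks the generative k", {
  set.seed(82)
  blobs <- rbind(matrix(rnorm(40, 0), 20, 2),
                 matrix(rnorm(40, 8), 20, 2))
  sel <- choose_k_by_silhouette(blobs, 2:8)
  expect_equal(sel$k_opt, 2)
  expect_equal(max(sel$avg_widths), sel$solution$avg_silhouette)
  expect_true(all(sel$solution$avg_silhouette >= sel$avg_widths - 1e-12))
  expect_error(choose_k_by_silhouette(blobs, integer(0)),
               class = "invalid_argument")
})

test_that("silhouette selection recovers five pathway groups at low noise", {
  cfg <- sim_config(n_samples = 250, n_variants = 50, n_taxa_common = 20,
                    n_taxa_rare = 0, n_pathway_features = 20,
                    n_pathway_clusters = 5, pathway_noise_sd = 0.05,
                    seed = 83)
  G <- simulate_genotypes(cfg)
  sim <- simulate_taxon_table(G, cfg)
  pw <- simulate_pathway_table(sim$table, cfg)
  sel <- choose_k_by_silhouette(t(scale(pw$table$values)), 2:8)
  expect_equal(sel$k_opt, 5)
  expect_equal(jaccard_cluster_similarity(sel$solution$labels, pw$truth), 1)
})

test_that("Jaccard similarity matches pair enumeration on the worked partitions", {
  expect_equal(jaccard_cluster_similarity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(jaccard_cluster_similarity(c(1, 1, 2), c(1, 2, 2)), 0)
  expect_equal(jaccard_cluster_similarity(c(1, 1, 2, 2), c(1, 1, 1, 1)), 1 / 3)
  # random partitions agree with the enumeration oracle and are symmetric
  set.seed(84)
  for (i in 1:25) {
    la <- sample(1:3, 9, TRUE)
    lb <- sample(1:3, 9, TRUE)
    skip_if(all(table(la) == 1) && all(table(lb) == 1))
    expect_equal(jaccard_cluster_similarity(la, lb), jaccard_oracle(la, lb))
    expect_equal(jaccard_cluster_similarity(la, lb),
                 jaccard_cluster_similarity(lb, la))
    expect_equal(jaccard_cluster_similarity(la, lb),
                 jaccard_cluster_similarity(la, c(7, 2, 9)[lb]))
  }
  expect_error(jaccard_cluster_similarity(c(a = 1, b = 1), c(a = 1, x = 2)),
               class = "invalid_input")
  expect_warning(jaccard_cluster_similarity(1:4, 1:4),
                 class = "all_singletons")
})

test_that("feature-taxon correlation applies the effective-number Bonferroni", {
  set.seed(85)
  n <- 200
  taxa <- matrix(rexp(n * 3), n, 3,
                 dimnames = list(NULL, paste0("genus|t", 1:3)))
  feat <- cbind(D1 = taxa[, 1]^2 + 1,        # monotone transform: rho = 1
                D2 = rnorm(n))
  fc <- correlate_features(feat, taxa, n_eff = 5.6, n_features = 22)
  expect_equal(fc$rho["D1", 1], 1)
  # threshold 0.05 / (5.6 * 22) = 0.05 / 123.2
  expect_equal(fc$threshold, 0.05 / 123.2)
  expect_lt(fc$threshold, 0.00041)
  expect_true(fc$mask["D1", 1])
})

test_that("correlation mask has at most nominal false-positive rate", {
  set.seed(86)
  hits <- vapply(1:300, function(i) {
    x <- rnorm(100); y <- rnorm(100)
    fc <- correlate_features(matrix(x, 100, 1), matrix(y, 100, 1),
                             n_eff = 5, n_features = 20)
    fc$mask[1, 1]
  }, logical(1))
  expect_lte(mean(hits), 0.05 / 100 + 0.01)
})

test_that("MRS selection is strict at the correlation threshold", {
  set.seed(87)
  n <- 400
  target <- rnorm(n)
  # construct taxa with controlled Spearman association
  mk <- function(rho_target) {
    x <- rho_target * rank(target) / n + (1 - abs(rho_target)) * runif(n)
    exp(x)
  }
  vals <- cbind(mk(0.8), mk(-0.7), mk(0), mk(0.1), mk(-0.05))
  rel <- vals / rowSums(vals)
  tt <- taxon_table(rel, paste0("genus|t", 1:5), type = "relative")
  # in-test oracle: the selection rule on the relative-abundance scale
  rho_all <- apply(rel, 2, function(a) cor(a, target, method = "spearman"))
  model <- build_mrs(tt, target, rho_threshold = 0.2)
  expect_setequal(model$taxa$id, paste0("genus|t", 1:5)[abs(rho_all) > 0.2])
  expect_equal(model$taxa$direction,
               unname(sign(rho_all[abs(rho_all) > 0.2])))
  expect_true(all(c("genus|t1", "genus|t2") %in% model$taxa$id))
  # a correlation of exactly the threshold is excluded (strict rule)
  thr <- sort(abs(rho_all), decreasing = TRUE)[2]
  model2 <- build_mrs(tt, target, rho_threshold = thr)
  expect_false(paste0("genus|t", which(abs(rho_all) == thr)) %in%
                 model2$taxa$id)
  expect_error(build_mrs(tt, target, rho_threshold = 0.999),
               class = "empty_model")
})

test_that("MRS scoring zeroes low abundance and sums directions", {
  vals <- rbind(c(0.001, 0.001, 0.998),   # below both cutoffs
                c(0.400, 0.400, 0.200),   # above both
                c(0.400, 0.001, 0.599))   # above taxon1 only
  tt <- taxon_table(vals, paste0("genus|t", 1:3), type = "relative")
  model <- structure(list(
    taxa = data.frame(id = c("genus|t1", "genus|t2"), rho = c(0.5, -0.5),
                      direction = c(1, -1), cutoff = c(0.01, 0.01)),
    rho_threshold = 0.2, quantile = 0.05), class = "mrs_model")
  res <- score_and_test_mrs(model, tt)
  expect_equal(unname(res$scores), c(0, 0, 1))   # 0; +1-1; +1
  bad <- structure(list(taxa = data.frame(
    id = "genus|zzz", rho = 0.5, direction = 1, cutoff = 0.1),
    rho_threshold = 0.2, quantile = 0.05), class = "mrs_model")
  expect_error(score_and_test_mrs(bad, tt), class = "missing_taxa")
  expect_true(all(abs(res$scores) <= nrow(model$taxa)))
})

test_that("cohorts with taxon-driven disease yield MRS odds ratios above 1", {
  hits <- vapply(1:12, function(s) {
    cfg <- sim_config(n_samples = 1800, n_variants = 60, n_taxa_common = 20,
                      n_taxa_rare = 5, n_disease_taxa = 16,
                      n_instruments = 4, causal_effect = 0.15,
                      seed = 400 + s)
    b <- simulate_cohort(cfg)
    model <- build_mrs(b$taxa, b$predicted_disease)
    covars <- as.matrix(b$covariates[, c("age", "sex", "energy_intake",
                                         "alcohol_intake", "bmi")])
    res <- score_and_test_mrs(model, b$taxa, b$disease, covars)
    res$odds_ratio > 1 && res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null disease effects leave the MRS odds ratio centred on 1", {
  ors <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 600, n_variants = 60, n_taxa_common = 12,
                      n_taxa_rare = 0, n_disease_taxa = 8,
                      n_instruments = 4, causal_effect = 0, seed = 500 + s)
    b <- simulate_cohort(cfg)
    model <- tryCatch(build_mrs(b$taxa, b$predicted_disease),
                      error = function(e) NULL)
    if (is.null(model)) return(NA_real_)
    score_and_test_mrs(model, b$taxa, b$disease)$estimate
  }, numeric(1))
  ors <- ors[!is.na(ors)]
  expect_lt(abs(mean(ors)), 2 * sd(ors) / sqrt(length(ors)) + 0.05)
})
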