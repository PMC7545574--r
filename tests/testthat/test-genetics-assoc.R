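test_that("linear scan equals the normal-equations OLS oracle", {
  G <- toy_genotypes(80, 10, seed = 41)
  set.seed(42)
  X <- cbind(runif(80), rbinom(80, 1, 0.5))
  y <- rnorm(80) + 0.3 * G$dosage[, 4]
  scan <- association_scan(G, y, X, model = "linear")
  for (j in 1:10) {
    ora <- ols_oracle(y, G$dosage[, j], X)
    expect_equal(scan$beta[j], unname(ora["beta"]), tolerance = 1e-8)
    expect_equal(scan$se[j], unname(ora["se"]), tolerance = 1e-8)
  }
})

test_that("a strong causal variant attains the minimum p-value", {
  G <- toy_genotypes(1000, 200, seed = 43)
  set.seed(44)
  y <- 0.5 * scale(G$dosage[, 117])[, 1] + rnorm(1000)
  scan <- association_scan(G, y, model = "linear")
  expect_equal(which.min(scan$p), 117)
  # permutation destroys the signal
  set.seed(45)
  scan_perm <- association_scan(G, sample(y), model = "linear")
  expect_true(all(scan_perm$p > 5e-8, na.rm = TRUE))
})

test_that("null scans are calibrated (genomic inflation near 1)", {
  G <- toy_genotypes(400, 2000, seed = 46)
  set.seed(47)
  y <- rnorm(400)
  scan <- association_scan(G, y, model = "linear")
  lam <- genomic_inflation(scan$p)
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("logistic scan recovers a log-odds effect and survives separation", {
  G <- toy_genotypes(800, 30, seed = 48)
  set.seed(49)
  lp <- -1 + 0.8 * G$dosage[, 7]
  y <- rbinom(800, 1, plogis(lp))
  scan <- association_scan(G, y, model = "logistic")
  expect_equal(which.min(scan$p), 7)
  expect_lt(abs(scan$beta[7] - 0.8), 3 * scan$se[7])
  # a variant perfectly aligned with the outcome separates; scan continues
  G$dosage[, 3] <- y * 2
  scan2 <- association_scan(G, y, model = "logistic")
  expect_true(is.na(scan2$p[3]) || scan2$se[3] < 20)
  expect_false(anyNA(scan2$p[7]))
})

test_that("genomic inflation matches its definition", {
  set.seed(50)
  p <- runif(1e5)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.02)
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  # chi-square statistics scaled by 1.3 inflate lambda to about 1.3
  chi <- rchisq(5e4, 1) * 1.3
  expect_equal(genomic_inflation(pchisq(chi, 1, lower.tail = FALSE)),
               1.3, tolerance = 0.05)
  expect_error(genomic_inflation(c(runif(200), 0)), class = "invalid_argument")
  expect_error(genomic_inflation(runif(50)), class = "invalid_argument")
})

test_that("clumping reproduces the three-variant worked example", {
  # p = {1e-6, 1e-5, 1e-4}, all pairwise r2 above the clump threshold, one
  # window: the 1e-4 variant fails the p threshold, the 1e-5 one is claimed
  set.seed(51)
  base <- rbinom(400, 2, 0.4)
  mutate <- function(rate) ifelse(runif(400) < rate,
                                  sample(0:2, 400, TRUE), base)
  dos <- cbind(base, mutate(0.3), mutate(0.3))
  storage.mode(dos) <- "double"
  r2 <- cor(dos)^2
  expect_true(min(r2[upper.tri(r2)]) > 0.1)  # construction check
  G <- genotype_matrix(dos, data.frame(
    id = c("a", "b", "c"), chrom = "1",
    pos_bp = c(1000L, 2000L, 3000L), pos_cm = c(0.001, 0.002, 0.003),
    effect_allele = "A", other_allele = "G", maf = colMeans(dos) / 2))
  assoc <- data.frame(id = c("a", "b", "c"), chrom = "1",
                      pos_bp = c(1000, 2000, 3000),
                      pos_cm = c(0.001, 0.002, 0.003),
                      p = c(1e-6, 1e-5, 1e-4))
  expect_identical(ld_clump(assoc, G), "a")
})

test_that("clumping degenerate cases: no LD and perfect LD", {
  G <- toy_genotypes(500, 6, seed = 52)
  assoc <- data.frame(id = G$variants$id, chrom = "1",
                      pos_bp = G$variants$pos_bp,
                      pos_cm = G$variants$pos_cm,
                      p = c(1e-6, 1e-7, 1e-9, 2e-5, 0.5, 1e-3))
  # independent variants: every variant below 5e-5 is its own lead
  expect_setequal(ld_clump(assoc, G, window_cm = 10),
                  G$variants$id[c(1, 2, 3, 4)])
  # duplicate variant (r2 = 1) collapses to a single lead
  G$dosage[, 2] <- G$dosage[, 1]
  assoc$p[2] <- assoc$p[1]
  leads <- ld_clump(assoc, G, window_cm = 10)
  expect_equal(sum(leads %in% G$variants$id[1:2]), 1)
})

test_that("clumping matches the brute-force oracle on random instances", {
  for (s in 1:100) {
    set.seed(700 + s)
    m <- 20
    G <- toy_genotypes(150, m, seed = 700 + s)
    # compress positions so windows overlap
    G$variants$pos_cm <- sort(runif(m, 0, 0.5))
    G$variants$pos_bp <- as.integer(G$variants$pos_cm * 1e6)
    assoc <- data.frame(id = G$variants$id, chrom = "1",
                        pos_bp = G$variants$pos_bp,
                        pos_cm = G$variants$pos_cm,
                        p = 10^runif(m, -8, -2))
    r2 <- suppressWarnings(cor(G$dosage))^2
    r2[is.na(r2)] <- 0
    got <- ld_clump(assoc, G, p_thresh = 5e-4, r2_thresh = 0.05,
                    window_cm = 0.1)
    want <- assoc$id[clump_oracle(assoc$p, assoc$pos_cm, r2,
                                  5e-4, 0.05, 0.1)]
    expect_identical(got, want)
  }
})

test_that("polygenic scores harmonize alleles and predict in a split design", {
  G <- toy_genotypes(60, 3, seed = 53)
  assoc <- data.frame(id = G$variants$id, chrom = "1",
                      pos_bp = G$variants$pos_bp, pos_cm = G$variants$pos_cm,
                      effect_allele = "A", other_allele = "G",
                      beta = c(0.5, -0.2, 0.1))
  prs <- build_polygenic_score("s001", assoc, G)
  expect_equal(unname(prs$scores), unname(0.5 * G$dosage[, 1]))
  # flipping the target's allele labels leaves scores unchanged
  G_fl <- G
  G_fl$variants$effect_allele[1] <- "G"
  G_fl$variants$other_allele[1] <- "A"
  G_fl$dosage[, 1] <- 2 - G_fl$dosage[, 1]
  prs_fl <- build_polygenic_score("s001", assoc, G_fl)
  expect_equal(prs$scores, prs_fl$scores)
  # missing variants are dropped with a warning
  assoc2 <- rbind(assoc, data.frame(id = "zzz", chrom = "1", pos_bp = 9e6,
                                    pos_cm = 9, effect_allele = "A",
                                    other_allele = "G", beta = 1))
  expect_warning(build_polygenic_score(c("s001", "zzz"), assoc2, G),
                 class = "variants_dropped")
})

test_that("discovery/target split recovers a heritable taxon's score signal", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 700, n_variants = 800, n_taxa_common = 1,
                      n_taxa_rare = 0, taxon_h2 = 0.5,
                      n_causal_per_taxon = 8, ld_rho = 0.3, seed = 300 + s)
    G <- simulate_genotypes(cfg)
    sim <- simulate_taxon_table(G, cfg)
    z <- scale(sim$truth$latent_logabund[, 1])[, 1]
    disc <- 1:350; targ <- 351:700
    Gd <- genotype_matrix(G$dosage[disc, ], G$variants, G$sample_ids[disc])
    Gt <- genotype_matrix(G$dosage[targ, ], G$variants, G$sample_ids[targ])
    scan <- association_scan(Gd, z[disc], model = "linear")
    leads <- ld_clump(scan, Gd, p_thresh = 5e-4)
    if (!length(leads)) return(FALSE)
    prs <- suppressWarnings(build_polygenic_score(leads, scan, Gt))
    tst <- test_polygenic_score(prs, z[targ], outcome_kind = "continuous")
    tst$p < 0.05 && tst$estimate > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("score association models behave on null, exact and binary outcomes", {
  set.seed(54)
  score <- rnorm(300)
  # exact identity: slope 1, p ~ 0
  t1 <- suppressWarnings(test_polygenic_score(score, score, outcome_kind = "continuous"))
  expect_equal(t1$estimate, 1, tolerance = 1e-10)
  expect_lt(t1$p, 1e-100)
  # null: no association
  t0 <- test_polygenic_score(score, rnorm(300), outcome_kind = "continuous")
  expect_gt(t0$p, 1e-4)
  # binary outcome caused by the score yields OR > 1
  y <- rbinom(300, 1, plogis(-0.5 + score))
  tb <- test_polygenic_score(score, y, outcome_kind = "binary")
  expect_gt(tb$odds_ratio, 1)
  expect_lt(tb$p, 0.05)
})

test_that("score association p-values are uniform under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    test_polygenic_score(rnorm(60), rnorm(60),
                         outcome_kind = "continuous")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
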