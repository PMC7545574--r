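test_that("instrument selection applies the outcome-exclusion rule", {
  expo <- data.frame(id = sprintf("iv%d", 1:10), p = rep(1e-6, 10))
  outc <- data.frame(id = sprintf("iv%d", 1:10),
                     p = c(0.001, rep(0.5, 9)))
  kept <- select_instruments(expo, outc, direction = "forward")
  expect_length(kept, 9)
  expect_false("iv1" %in% kept)
  # nothing associated with the outcome: all retained
  outc$p <- 0.5
  expect_length(select_instruments(expo, outc, "forward"), 10)
})

test_that("reverse selection thins correlated variants keeping smaller p", {
  G <- toy_genotypes(400, 2, seed = 61)
  G$dosage[, 2] <- ifelse(runif(400) < 0.85, G$dosage[, 1],
                          sample(0:2, 400, TRUE))
  stats <- data.frame(id = G$variants$id, chrom = "1",
                      pos_bp = G$variants$pos_bp,
                      pos_cm = G$variants$pos_cm, p = c(1e-8, 1e-4))
  r2 <- cor(G$dosage[, 1], G$dosage[, 2])^2
  skip_if(r2 < 0.5)   # construction check, not the property under test
  kept <- select_instruments(stats, direction = "reverse", ld_ref = G)
  expect_identical(kept, "s001")
})

test_that("proxy search honours the r2 threshold strictly", {
  G <- toy_genotypes(500, 4, seed = 62)
  G$dosage[, 2] <- G$dosage[, 1]                      # perfect proxy
  noisy <- G$dosage[, 3]
  flip <- runif(500) < 0.3
  G$dosage[, 4] <- ifelse(flip, sample(0:2, 500, TRUE), noisy)  # weak proxy
  out_ids <- G$variants$id[c(2, 4)]
  best <- find_proxy("s001", G, out_ids)
  expect_equal(best$id, "s002")
  expect_equal(best$r2, 1)
  weak <- find_proxy("s003", G, out_ids)
  if (!is.null(weak)) expect_gt(weak$r2, 0.9)
  expect_warning(find_proxy("nope", G, out_ids),
                 class = "proxy_query_missing")
})

test_that("proxy search returns the highest-r2 candidate", {
  set.seed(63)
  n <- 800
  base <- rbinom(n, 2, 0.4)
  mut <- function(rate) ifelse(runif(n) < rate, sample(0:2, n, TRUE), base)
  dos <- cbind(base, mut(0.02), mut(0.005))
  storage.mode(dos) <- "double"
  pos <- c(1e5, 2e5, 3e5)
  G <- genotype_matrix(dos, data.frame(
    id = c("q", "p1", "p2"), chrom = "1", pos_bp = as.integer(pos),
    pos_cm = pos / 1e6, effect_allele = "A", other_allele = "G",
    maf = colMeans(dos) / 2))
  r2s <- cor(dos)[1, 2:3]^2
  skip_if(any(r2s < 0.9))
  best <- find_proxy("q", G, c("p1", "p2"))
  expect_equal(best$id, c("p1", "p2")[which.max(r2s)])
})

test_that("harmonization aligns, flips and drops as specified", {
  expo <- as_summary_stats(data.frame(
    id = c("v1", "v2", "v3", "v4"), chrom = "1", pos_bp = 1:4, pos_cm = 1:4,
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "T", "C"),
    eaf = c(0.3, 0.3, 0.5, 0.3), beta = c(0.1, 0.1, 0.1, 0.1),
    se = 0.01, p = 1e-5, n = 1000))
  outc <- as_summary_stats(data.frame(
    id = c("v1", "v2", "v3", "v4"), chrom = "1", pos_bp = 1:4, pos_cm = 1:4,
    effect_allele = c("G", "A", "A", "A"),
    other_allele = c("A", "G", "T", "T"),
    eaf = c(0.7, 0.3, 0.5, 0.3), beta = c(0.05, 0.04, 0.02, 0.09),
    se = 0.01, p = 0.01, n = 5000))
  h <- harmonize_instruments(expo, outc)
  # v1: swapped orientation -> sign flip; v2: same orientation -> unchanged
  expect_equal(h$beta_outcome[h$id == "v1"], -0.05)
  expect_equal(h$beta_outcome[h$id == "v2"], 0.04)
  # v3: palindromic A/T with EAF 0.5 -> dropped; v4: incompatible alleles
  expect_false("v3" %in% h$id)
  expect_false("v4" %in% h$id)
  dropped <- attr(h, "dropped")
  expect_setequal(dropped$id, c("v3", "v4"))
})

test_that("IVW reproduces closed forms and the Wald-ratio fallback", {
  h <- harmonized_instruments(c(0.1, 0.2, 0.3), rep(0.01, 3),
                              c(0.02, 0.04, 0.06), rep(0.01, 3))
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.2)          # all ratios equal: exact
  h1 <- harmonized_instruments(0.1, 0.01, 0.05, 0.02)
  f1 <- mr_ivw(h1)
  expect_true(f1$wald_ratio)
  expect_equal(f1$estimate, 0.5)
  # simultaneous sign flip of one instrument leaves the estimate unchanged
  h2 <- h
  h2$beta_exposure[2] <- -h2$beta_exposure[2]
  h2$beta_outcome[2] <- -h2$beta_outcome[2]
  expect_equal(mr_ivw(h2)$estimate, fit$estimate)
})

test_that("IVW is unbiased with near-nominal coverage over replicates", {
  res <- t(vapply(1:100, function(s) {
    h <- sim_instruments(30, 0.3, seed = s)
    f <- mr_ivw(h)
    c(est = f$estimate,
      cover = abs(f$estimate - 0.3) <= qnorm(0.975) * f$se)
  }, numeric(2)))
  expect_lt(abs(mean(res[, "est"]) - 0.3), 0.02)
  expect_gte(mean(res[, "cover"]), 0.90)
  expect_lte(mean(res[, "cover"]), 0.99)
})

test_that("weighted median interpolates the 0.5 crossing", {
  # equal weights on ratios {0.1, 0.2, 0.9}: crossing lands exactly on 0.2
  # (negligible exposure SE keeps the delta-method weights equal)
  h <- harmonized_instruments(c(1, 1, 1), rep(1e-8, 3),
                              c(0.1, 0.2, 0.9), rep(0.05, 3))
  fit <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(fit$estimate, 0.2)
  # all ratios equal c
  hc <- harmonized_instruments(c(0.1, 0.2, 0.4), rep(0.01, 3),
                               c(0.05, 0.1, 0.2), rep(0.01, 3))
  expect_equal(mr_weighted_median(hc, n_boot = 100, seed = 1)$estimate, 0.5)
  expect_error(mr_weighted_median(harmonized_instruments(
    c(1, 1), c(0.1, 0.1), c(1, 1), c(0.1, 0.1))),
    class = "insufficient_instruments")
})

test_that("equal-weight weighted median equals the ordinary median (odd k)", {
  set.seed(64)
  for (i in 1:20) {
    r <- rnorm(7)
    expect_equal(micromendr:::weighted_median_point(r, rep(1, 7)),
                 median(r))
  }
})

test_that("weighted median resists 50% directional pleiotropy better than IVW", {
  bias <- t(vapply(1:100, function(s) {
    h <- sim_instruments(20, 0.3, seed = 5000 + s, n_pleio = 10,
                         pleio_effect = 0.08)
    c(ivw = mr_ivw(h)$estimate - 0.3,
      med = mr_weighted_median(h, n_boot = 60, seed = s)$estimate - 0.3)
  }, numeric(2)))
  expect_lt(abs(mean(bias[, "med"])), abs(mean(bias[, "ivw"])))
})

test_that("Egger regression recovers exact linear pleiotropy structure", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.2 * bx
  h <- harmonized_instruments(bx, rep(0.01, 4), by, rep(0.01, 4))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-10)
  expect_equal(fit$estimate, 0.2, tolerance = 1e-10)
  expect_error(mr_egger(harmonized_instruments(
    c(0.2, 0.2, 0.2), rep(0.01, 3), c(0.1, 0.1, 0.1), rep(0.01, 3))),
    class = "collinear_instruments")
})

test_that("Egger constrained through the origin reduces to fixed-effect IVW", {
  set.seed(65)
  h <- sim_instruments(15, 0.25, seed = 66)
  flip <- sign(h$beta_exposure)
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  slope0 <- coef(lm(by ~ bx - 1, weights = w))[[1]]
  expect_equal(slope0, mr_ivw(h, method = "fixed")$estimate,
               tolerance = 1e-10)
})

test_that("Egger intercept p is uniform under no pleiotropy and detects it", {
  ps <- vapply(1:200, function(s)
    mr_egger(sim_instruments(25, 0.2, seed = 2000 + s))$intercept_p,
    numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  hits <- vapply(1:50, function(s) {
    h <- sim_instruments(25, 0.2, seed = 3000 + s, n_pleio = 25,
                         pleio_effect = 0.05)
    f <- mr_egger(h)
    f$intercept_p < 0.05 && f$intercept > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the pleiotropy global test is calibrated and flags gross outliers", {
  # calibration under no pleiotropy
  gp <- vapply(1:60, function(s)
    mr_presso(sim_instruments(20, 0.3, seed = 4000 + s),
              n_sim = 300, seed = s)$global_p, numeric(1))
  expect_lte(mean(gp < 0.05), 0.12)
  # a planted gross outlier (direct effect 10x the outcome SE)
  res <- vapply(1:30, function(s) {
    h <- sim_instruments(20, 0.3, seed = 6000 + s)
    h$beta_outcome[7] <- h$beta_outcome[7] + 10 * h$se_outcome[7]
    f <- mr_presso(h, n_sim = 400, seed = s)
    raw_err <- abs(f$raw$estimate - 0.3)
    c(flagged = "iv7" %in% f$outliers,
      improved = abs(f$estimate - 0.3) <= raw_err)
  }, logical(2))
  expect_gte(mean(res["flagged", ]), 0.9)
  expect_gte(mean(res["improved", ]), 0.9)
})

test_that("pleiotropy test smoothing bounds the minimum p", {
  h <- sim_instruments(8, 0.3, seed = 70)
  h$beta_outcome <- h$beta_outcome + c(rep(0, 7), 1)
  f <- mr_presso(h, n_sim = 200, seed = 1)
  expect_gte(f$global_p, 1 / 201)
  expect_warning(mr_presso(h, n_sim = 50, seed = 1), class = "low_n_sim")
})

test_that("strong directional pleiotropy triggers the global test", {
  hits <- vapply(1:50, function(s) {
    h <- sim_instruments(20, 0.3, seed = 7000 + s, n_pleio = 6,
                         pleio_effect = 0.15)
    mr_presso(h, n_sim = 300, seed = s)$global_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("two-tier classification follows the decision rules", {
  mk <- function(pi, pm, pe, pp) list(
    ivw = list(p = pi), weighted_median = list(p = pm),
    egger = list(p = pe), presso = list(p = pp))
  # forward Bonferroni bound is 0.05/62
  expect_equal(classify_mr_result(mk(5e-4, 0.5, 0.5, 0.5),
                                  "forward")$classification, "significant")
  expect_equal(classify_mr_result(mk(0.03, 0.04, 0.02, 0.049),
                                  "forward")$classification,
               "potential_causal")
  expect_equal(classify_mr_result(mk(0.03, 0.04, 0.2, 0.01),
                                  "forward")$classification, "null")
  expect_equal(classify_mr_result(mk(9e-4, 0.5, 0.5, 0.5),
                                  "forward")$classification, "null")
  # reverse bound uses the effective number of independent taxa
  expect_equal(classify_mr_result(mk(0.008, 0.5, 0.5, 0.5), "reverse",
                                  n_eff_taxa = 5.6)$classification,
               "significant")
  expect_equal(classify_mr_result(mk(0.01, 0.5, 0.5, 0.5), "reverse",
                                  n_eff_taxa = 5.6)$classification, "null")
  expect_error(classify_mr_result(mk(0.01, 0.5, 0.5, 0.5), "reverse"),
               class = "configuration_error")
  # an unavailable method blocks the all-four tier but not significance
  partial <- list(ivw = list(p = 0.01), weighted_median = list(p = 0.01),
                  egger = NULL, presso = NULL)
  expect_equal(classify_mr_result(partial, "forward")$classification, "null")
})

test_that("estimators are unbiased across the effect grid with valid instruments", {
  for (theta in c(0, 0.1, 0.3)) {
    ests <- t(vapply(1:60, function(s) {
      h <- sim_instruments(30, theta, seed = 8000 + 100 * theta * 10 + s)
      c(ivw = mr_ivw(h)$estimate,
        med = mr_weighted_median(h, n_boot = 50, seed = s)$estimate,
        egg = mr_egger(h)$estimate)
    }, numeric(3)))
    mc_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
    for (m in colnames(ests))
      expect_lt(abs(mean(ests[, m]) - theta), 4 * mc_se[m] + 0.005)
  }
})
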