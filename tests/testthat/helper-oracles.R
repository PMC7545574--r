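# Independent oracles and small simulators shared across the test files.
# These deliberately use naive, direct implementations (dense algebra, pair
# enumeration, exhaustive search) so they stay independent of the package's
# optimized code paths.

# two-sample MR instrument simulator with known causal effect
sim_instruments <- function(k, theta, seed, se_x = 0.02, se_y = 0.02,
                            n_pleio = 0, pleio_effect = 0) {
  set.seed(seed)
  bx <- sample(c(-1, 1), k, TRUE) * runif(k, 0.1, 0.4)
  alpha <- rep(0, k)
  if (n_pleio > 0) {
    # directional pleiotropy: direct effects aligned with the instrument's
    # exposure direction, so Wald ratios are biased coherently upward
    idx <- sample.int(k, n_pleio)
    alpha[idx] <- pleio_effect * sign(bx[idx])
  }
  by <- theta * bx + alpha
  harmonized_instruments(
    beta_exposure = bx + rnorm(k, 0, se_x),
    se_exposure = rep(se_x, k),
    beta_outcome = by + rnorm(k, 0, se_y),
    se_outcome = rep(se_y, k)
  )
}

# dense-matrix REML log-likelihood, the direct evaluation of
# -0.5 (log|V| + log|X'V^-1 X| + y'Py)
dense_reml_loglik <- function(K, y, X, sg2, se2) {
  n <- length(y)
  X <- cbind(1, X)
  V <- sg2 * K + se2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(y) %*% P %*% y))
}

# per-variant OLS via explicit normal equations on the full design
ols_oracle <- function(y, g, X) {
  D <- cbind(1, X, g)
  ct <- solve(t(D) %*% D, t(D) %*% y)
  r <- y - D %*% ct
  s2 <- sum(r^2) / (length(y) - ncol(D))
  covb <- s2 * solve(t(D) %*% D)
  j <- ncol(D)
  c(beta = ct[j], se = sqrt(covb[j, j]))
}

# greedy clumping re-implemented naively over a plain correlation matrix
clump_oracle <- function(p, pos_cm, r2mat, p_thresh, r2_thresh, window_cm) {
  claimed <- rep(FALSE, length(p))
  leads <- integer(0)
  repeat {
    cand <- which(!claimed & !is.na(p) & p < p_thresh)
    if (!length(cand)) break
    i <- cand[order(p[cand], pos_cm[cand])][1]
    leads <- c(leads, i)
    claimed[i] <- TRUE
    for (j in seq_along(p)) {
      if (!claimed[j] && abs(pos_cm[j] - pos_cm[i]) <= window_cm &&
          r2mat[i, j] >= r2_thresh)
        claimed[j] <- TRUE
    }
  }
  leads
}

# exhaustive k-medoids optimum over all medoid subsets
pam_exhaustive <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (obj < best) best <- obj
  }
  best
}

# Jaccard cluster similarity by direct enumeration of object pairs
jaccard_oracle <- function(la, lb) {
  n <- length(la)
  a <- b <- c_ <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) a <- a + 1
      else if (sa) b <- b + 1
      else if (sb) c_ <- c_ + 1
    }
  }
  a / (a + b + c_)
}

# random clustered 12-object distance instance (points near k centres),
# the regime disease-feature clustering operates in
random_cluster_instance <- function(seed) {
  set.seed(seed)
  k <- sample(2:4, 1)
  centres <- matrix(rnorm(k * 2, sd = 4), k, 2)
  x <- centres[sample(k, 12, TRUE), , drop = FALSE] + matrix(rnorm(24), 12, 2)
  list(d = as.matrix(dist(x)), k = k)
}

# tiny genotype fixture without LD structure
toy_genotypes <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  dos <- sapply(maf, function(p) rbinom(n, 2, p))
  storage.mode(dos) <- "double"
  pos <- as.integer(seq(1e5, by = 2e5, length.out = m))
  genotype_matrix(
    dos,
    data.frame(id = sprintf("s%03d", seq_len(m)), chrom = "1",
               pos_bp = pos, pos_cm = pos / 1e6,
               effect_allele = "A", other_allele = "G",
               maf = colMeans(dos) / 2, stringsAsFactors = FALSE),
    sample_ids = sprintf("I%04d", seq_len(n))
  )
}
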