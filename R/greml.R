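#' Genetic relationship matrix and leading principal components
#'
#' Computes the standard SNP-based GRM
#' \deqn{GRM_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2 p_i (1-p_i)}}
#' over the m polymorphic variants, and returns its leading eigenvectors as
#' ancestry principal components. Monomorphic variants are excluded with a
#' warning. Under Hardy-Weinberg equilibrium the diagonal averages 1.
#'
#' @param G A [genotype_matrix()].
#' @param n_pcs Number of principal components to return (default 5).
#' @return List with `grm` (n x n symmetric matrix), `pcs` (n x n_pcs
#'   matrix of eigenvectors scaled by sqrt of eigenvalue), `n_variants_used`.
#' @export
compute_grm <- function(G, n_pcs = 5L) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosage
  if (nrow(X) < 2L || ncol(X) < 1L)
    stop_mm("invalid_argument", "need >= 2 samples and >= 1 variant")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warn_mm("monomorphic_excluded", "%d monomorphic variant(s) excluded",
            sum(!poly))
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- ncol(X)
  W <- sweep(X, 2L, 2 * p, `-`)
  W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), `/`)
  grm <- tcrossprod(W) / m
  dimnames(grm) <- list(G$sample_ids, G$sample_ids)
  n_pcs <- min(n_pcs, nrow(grm) - 1L)
  eig <- eigen(grm, symmetric = TRUE)
  pcs <- eig$vectors[, seq_len(n_pcs), drop = FALSE]
  pcs <- sweep(pcs, 2L, sqrt(pmax(eig$values[seq_len(n_pcs)], 0)), `*`)
  dimnames(pcs) <- list(G$sample_ids, paste0("PC", seq_len(n_pcs)))
  list(grm = grm, pcs = pcs, n_variants_used = m)
}

#' Restricted log-likelihood of the single-GRM variance-component model
#'
#' Evaluates the REML log-likelihood of \eqn{y = Xb + g + e},
#' \eqn{g \sim N(0, \sigma_g^2 K)}, \eqn{e \sim N(0, \sigma_e^2 I)} at given
#' variance components:
#' \deqn{\ell_R = -\tfrac12\left(\log|V| + \log|X'V^{-1}X| + y'Py\right)}
#' (constants omitted), with \eqn{V = \sigma_g^2 K + \sigma_e^2 I} and P the
#' REML projection matrix. Used internally by [greml_heritability()] and
#' exposed for validation against direct dense-matrix evaluation.
#'
#' @param grm Symmetric GRM matrix K.
#' @param y Numeric phenotype vector.
#' @param X Covariate matrix (an intercept is appended automatically), or
#'   NULL for intercept only.
#' @param sigma_g2,sigma_e2 Variance components (>= 0, not both 0).
#' @return The restricted log-likelihood (a single number).
#' @export
reml_loglik <- function(grm, y, X = NULL, sigma_g2, sigma_e2) {
  prep <- reml_prepare(grm, y, X)
  reml_loglik_t(prep, sigma_g2, sigma_e2)
}

# rotate the model to the GRM eigenbasis once; every REML iteration is then
# O(n p^2) with diagonal V
reml_prepare <- function(grm, y, X) {
  n <- length(y)
  if (!is.matrix(grm) || nrow(grm) != n || ncol(grm) != n)
    stop_mm("invalid_argument", "grm must be n x n matching y")
  X <- cbind(`(Intercept)` = rep(1, n), X)
  eig <- eigen(grm, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  list(d = d, ys = as.vector(crossprod(U, y)), Xs = crossprod(U, X),
       n = n, p = ncol(X),
       identity_like = stats::sd(d) < 1e-8)
}

reml_loglik_t <- function(prep, sigma_g2, sigma_e2) {
  v <- sigma_g2 * prep$d + sigma_e2
  if (any(v <= 0)) return(-Inf)
  vi <- 1 / v
  XtVX <- crossprod(prep$Xs * vi, prep$Xs)
  cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cXtVX)) return(-Inf)
  beta <- backsolve(cXtVX, forwardsolve(t(cXtVX),
                                        crossprod(prep$Xs, prep$ys * vi)))
  r <- prep$ys - prep$Xs %*% beta
  yPy <- sum(r * vi * r)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(cXtVX))) + yPy)
}

# P y and the traces needed by AI-REML, all with diagonal V in the eigenbasis
reml_quantities <- function(prep, sigma_g2, sigma_e2) {
  v <- sigma_g2 * prep$d + sigma_e2
  vi <- 1 / v
  Xv <- prep$Xs * vi                      # V^-1 X
  XtVX <- crossprod(prep$Xs, Xv)
  XtVXi <- solve(XtVX)
  py_part <- Xv %*% (XtVXi %*% crossprod(Xv, prep$ys))
  Py <- prep$ys * vi - py_part
  # tr(P A) for A = diag(d) (GRM) and A = I
  trP_d <- sum(prep$d * vi) - sum((Xv %*% XtVXi) * (Xv * prep$d))
  trP_i <- sum(vi) - sum((Xv %*% XtVXi) * Xv)
  list(v = v, vi = vi, Py = Py, trP_d = trP_d, trP_i = trP_i)
}

#' Single-component GREML heritability
#'
#' Estimates the proportion of phenotypic variance captured by all SNPs by
#' restricted maximum likelihood for the model \eqn{y = Xb + g + e} with
#' \eqn{g \sim N(0, \sigma_g^2 K)} and \eqn{e \sim N(0, \sigma_e^2 I)}.
#' Optimisation uses average-information (AI) updates with an expectation-
#' maximisation first step and EM fallback whenever an AI step leaves the
#' parameter space or decreases the restricted likelihood. Components are
#' constrained non-negative; estimates hitting the lower bound are truncated
#' at a small positive value and flagged. The standard error of
#' \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)} comes from the inverse AI
#' matrix by the delta method.
#'
#' Convergence: relative change in restricted log-likelihood below 1e-6, at
#' most 100 iterations; non-convergence raises an error carrying the
#' likelihood trace.
#'
#' @param grm GRM matrix from [compute_grm()].
#' @param y Numeric phenotype (e.g. a Z-scored log abundance).
#' @param X Optional covariate matrix (age, sex, ...); an intercept is always
#'   included.
#' @return List of class `greml_fit`: `h2`, `se`, `sigma_g2`, `sigma_e2`,
#'   `loglik` (trace), `iterations`, `converged`, `boundary`,
#'   `non_identifiable` (TRUE when the GRM is numerically an identity matrix
#'   and the two components are not separable).
#' @export
greml_heritability <- function(grm, y, X = NULL) {
  prep <- reml_prepare(grm, y, X)
  vp <- stats::var(y)
  floor_v <- 1e-8 * vp
  sg <- se_ <- vp / 2
  trace <- reml_loglik_t(prep, sg, se_)
  boundary <- FALSE
  converged <- FALSE
  AI <- NULL
  for (it in seq_len(100L)) {
    q <- reml_quantities(prep, sg, se_)
    dPy <- prep$d * q$Py
    PdPy <- proj_apply(prep, q, dPy)
    PiPy <- proj_apply(prep, q, q$Py)
    score <- c(g = -0.5 * (q$trP_d - sum(q$Py * dPy)),
               e = -0.5 * (q$trP_i - sum(q$Py * q$Py)))
    AI <- 0.5 * matrix(c(sum(dPy * PdPy), sum(dPy * PiPy),
                         sum(dPy * PiPy), sum(q$Py * PiPy)), 2L, 2L)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    ll_old <- trace[length(trace)]
    new <- NULL
    if (!is.null(step) && it > 1L) {
      # AI proposal, clamped at the lower bound, with step-halving if it
      # overshoots the likelihood
      frac <- 1
      for (half in 1:8) {
        cand <- pmax(c(sg, se_) + frac * step, floor_v)
        if (reml_loglik_t(prep, cand[1], cand[2]) >= ll_old - 1e-10) {
          new <- cand
          break
        }
        frac <- frac / 2
      }
    }
    if (is.null(new)) {
      # EM update: sigma_i^2 <- (sigma_i^4 y'P A_i P y + n sigma_i^2
      #            - sigma_i^4 tr(P A_i)) / n
      new <- pmax(c(
        (sg^2 * sum(q$Py * dPy) + prep$n * sg - sg^2 * q$trP_d) / prep$n,
        (se_^2 * sum(q$Py * q$Py) + prep$n * se_ - se_^2 * q$trP_i) / prep$n
      ), floor_v)
    }
    if (any(new <= floor_v)) boundary <- TRUE
    sg <- new[1]; se_ <- new[2]
    ll <- reml_loglik_t(prep, sg, se_)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < 1e-6 * (abs(ll_old) + 1e-6)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop_mm("greml_nonconvergence",
            "REML did not converge in 100 iterations (last loglik %.6f)",
            trace[length(trace)])
  h2 <- sg / (sg + se_)
  # delta-method SE from the inverse AI matrix
  se_h2 <- tryCatch({
    Vc <- solve(AI)
    grad <- c(se_, -sg) / (sg + se_)^2
    sqrt(max(drop(t(grad) %*% Vc %*% grad), 0))
  }, error = function(e) NA_real_)
  if (prep$identity_like)
    warn_mm("non_identifiable",
            "GRM is numerically identity: sigma_g2 and sigma_e2 are not separable")
  structure(list(h2 = h2, se = se_h2, sigma_g2 = sg, sigma_e2 = se_,
                 loglik = trace, iterations = length(trace) - 1L,
                 converged = converged, boundary = boundary,
                 non_identifiable = prep$identity_like),
            class = "greml_fit")
}

# apply the REML projection P to a vector already in the eigenbasis
proj_apply <- function(prep, q, x) {
  Xv <- prep$Xs * q$vi
  XtVXi <- solve(crossprod(prep$Xs, Xv))
  x * q$vi - Xv %*% (XtVXi %*% crossprod(Xv, x))
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("<greml_fit> h2 = %.3f (SE %.3f); sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              x$h2, x$se, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  %d iterations, converged = %s%s\n", x$iterations,
              x$converged, if (x$boundary) " (boundary)" else ""))
  invisible(x)
}
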