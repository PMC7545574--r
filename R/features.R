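#' Rarefy a count table to fixed depth
#'
#' Randomly subsamples each sample's reads to exactly `depth` without
#' replacement (multivariate hypergeometric). Samples whose total count is
#' below `depth` are dropped and reported via the `"dropped"` attribute and a
#' warning. This mirrors the common practice of rarefying 16S OTU counts to
#' a fixed depth (e.g. 10,000 reads) before computing alpha diversity.
#'
#' @param T A counts [taxon_table()].
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer seed for the subsampling.
#' @return A counts `taxon_table` in which every retained sample sums to
#'   exactly `depth`; attribute `"dropped"` lists removed sample ids.
#' @examples
#' tt <- taxon_table(matrix(c(600, 400, 50, 50), 2, byrow = TRUE,
#'                   dimnames = list(c("a", "b"), c("genus|x", "genus|y"))))
#' rarefy(tt, depth = 100, seed = 1)
#' @export
rarefy <- function(T, depth, seed = 1L) {
  stopifnot(inherits(T, "taxon_table"))
  if (T$type != "counts")
    stop_mm("invalid_argument", "rarefy requires a counts table")
  depth <- check_count(depth, "depth")
  set.seed(seed)
  totals <- rowSums(T$values)
  keep <- totals >= depth
  if (!any(keep))
    stop_mm("invalid_argument", "no sample reaches depth %d", depth)
  out <- matrix(0, sum(keep), ncol(T$values))
  rows <- which(keep)
  for (r in seq_along(rows)) {
    cnt <- T$values[rows[r], ]
    if (totals[rows[r]] == depth) {
      out[r, ] <- cnt
    } else {
      reads <- rep.int(seq_along(cnt), cnt)
      out[r, ] <- tabulate(sample(reads, depth), nbins = length(cnt))
    }
  }
  dropped <- T$sample_ids[!keep]
  if (length(dropped))
    warn_mm("samples_dropped", "%d sample(s) below depth %d dropped: %s",
            length(dropped), depth,
            paste(utils::head(dropped, 5), collapse = ", "))
  res <- taxon_table(out, T$taxa$id, T$sample_ids[keep], type = "counts")
  attr(res, "dropped") <- dropped
  res
}

#' Per-sample alpha diversity
#'
#' Computes the Shannon diversity index (base-2 logarithm, the QIIME 1
#' convention, so units are bits), the observed taxon count, and the Chao1
#' richness estimator \eqn{S_{obs} + F_1^2 / (2 F_2)} with the bias-corrected
#' form \eqn{S_{obs} + F_1 (F_1 - 1) / 2} when no doubletons are present.
#'
#' @param T A counts [taxon_table()], typically rarefied first.
#' @return Data frame with columns `sample_id`, `shannon`, `observed`,
#'   `chao1`.
#' @export
alpha_diversity <- function(T) {
  stopifnot(inherits(T, "taxon_table"))
  if (T$type != "counts")
    stop_mm("invalid_argument", "alpha_diversity requires counts")
  totals <- rowSums(T$values)
  if (any(totals == 0))
    stop_mm("undefined_diversity", "empty sample(s): %s",
            paste(T$sample_ids[totals == 0], collapse = ", "))
  res <- t(apply(T$values, 1L, function(cnt) {
    p <- cnt[cnt > 0] / sum(cnt)
    shannon <- -sum(p * log2(p))
    s_obs <- sum(cnt > 0)
    f1 <- sum(cnt == 1)
    f2 <- sum(cnt == 2)
    chao1 <- if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
    c(shannon = shannon, observed = s_obs, chao1 = chao1)
  }))
  data.frame(sample_id = T$sample_ids, res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Partition taxa by prevalence
#'
#' Splits a taxon table into "common" taxa, present in at least
#' `threshold` of samples and analysed on the (log-normal) abundance scale,
#' and "rare" taxa, returned as presence/absence indicators for logistic
#' modelling. The boundary is inclusive: a taxon present in exactly
#' `threshold` of samples is common.
#'
#' @param T A [taxon_table()].
#' @param threshold Prevalence cutoff in (0, 1]; default 0.9.
#' @return List with `common` (a `taxon_table` restricted to common taxa, on
#'   the input scale) and `rare` (a samples-by-taxa 0/1 matrix), plus
#'   `prevalence`, the per-taxon prevalence vector.
#' @export
prevalence_partition <- function(T, threshold = 0.9) {
  stopifnot(inherits(T, "taxon_table"))
  check_scalar_number(threshold, "threshold", 0, 1, strict_lower = TRUE)
  prev <- colMeans(T$values > 0)
  is_common <- prev >= threshold
  common <- if (any(is_common))
    taxon_table(T$values[, is_common, drop = FALSE],
                T$taxa$id[is_common], T$sample_ids, type = T$type)
  else NULL
  rare <- (T$values[, !is_common, drop = FALSE] > 0) * 1L
  colnames(rare) <- T$taxa$id[!is_common]
  rownames(rare) <- T$sample_ids
  list(common = common, rare = rare,
       prevalence = stats::setNames(prev, T$taxa$id))
}

#' Z-score the log abundances of common taxa
#'
#' For each taxon, takes the natural log of relative abundance and
#' standardizes to mean 0, SD 1. Zeros are replaced beforehand by a
#' per-taxon pseudocount, by default half the smallest nonzero relative
#' abundance of that taxon.
#'
#' @param common A [taxon_table()] of common taxa (counts are converted to
#'   relative abundance internally).
#' @param pseudocount Either `"half_min_nonzero"` (default) or a single
#'   positive number used for every taxon.
#' @return Numeric matrix of Z-scores (samples x taxa).
#' @export
transform_common_abundance <- function(common,
                                       pseudocount = "half_min_nonzero") {
  stopifnot(inherits(common, "taxon_table"))
  rel <- relative_abundance_safe(common)
  for (j in seq_len(ncol(rel))) {
    zeros <- rel[, j] == 0
    if (any(zeros)) {
      pc <- if (identical(pseudocount, "half_min_nonzero")) {
        nz <- rel[rel[, j] > 0, j]
        if (!length(nz))
          stop_mm("degenerate_taxon", "taxon %s is absent everywhere",
                  common$taxa$id[j])
        min(nz) / 2
      } else {
        check_scalar_number(pseudocount, "pseudocount", 0, strict_lower = TRUE)
      }
      rel[zeros, j] <- pc
    }
  }
  lg <- log(rel)
  sds <- apply(lg, 2L, stats::sd)
  if (any(sds == 0))
    stop_mm("degenerate_taxon", "zero-variance taxon: %s",
            paste(common$taxa$id[sds == 0], collapse = ", "))
  z <- scale(lg)
  dimnames(z) <- list(common$sample_ids, common$taxa$id)
  z[, , drop = FALSE]
}

# relative abundance, tolerating tables whose rare columns were removed (row
# sums then renormalized over the remaining taxa)
relative_abundance_safe <- function(T) {
  tot <- rowSums(T$values)
  if (any(tot == 0))
    stop_mm("undefined_diversity", "sample(s) with zero total: %s",
            paste(T$sample_ids[tot == 0], collapse = ", "))
  T$values / tot
}

#' Effective number of independent taxa
#'
#' Eigenvalue-based count of independent tests among correlated taxa:
#' \eqn{(\sum_i \lambda_i)^2 / \sum_i \lambda_i^2}, where \eqn{\lambda_i}
#' are the eigenvalues of the taxa-by-taxa variance-covariance matrix of the
#' abundance matrix. With `scale = "zscore"` (default) the columns are
#' standardized first, making the statistic scale-free (the covariance is
#' then the correlation matrix); `"raw"` uses the columns as given. The value
#' always lies in [1, n_taxa]: it equals n_taxa for mutually independent
#' taxa and 1 when all taxa are perfectly correlated.
#'
#' @param M Numeric matrix, samples in rows, taxa in columns, or a
#'   [taxon_table()].
#' @param scale One of `"zscore"`, `"raw"`.
#' @return A single number in [1, n_taxa].
#' @examples
#' effective_number_independent_taxa(matrix(rnorm(600), 200, 3))
#' @export
effective_number_independent_taxa <- function(M, scale = c("zscore", "raw")) {
  scale <- match.arg(scale)
  if (inherits(M, "taxon_table")) M <- M$values
  if (!is.matrix(M) || ncol(M) < 2L || nrow(M) < 2L)
    stop_mm("invalid_argument", "need a matrix with >= 2 samples and >= 2 taxa")
  sds <- apply(M, 2L, stats::sd)
  if (all(sds == 0))
    stop_mm("degenerate_input", "constant matrix")
  if (scale == "zscore") {
    if (any(sds == 0))
      stop_mm("degenerate_input", "zero-variance column(s): %s",
              paste(utils::head(colnames(M)[sds == 0], 5), collapse = ", "))
    A <- stats::cor(M)
  } else {
    A <- stats::cov(M)
  }
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  sum(lambda)^2 / sum(lambda^2)
}

#' Pairwise Jensen-Shannon divergence distance
#'
#' Root Jensen-Shannon divergence between the rows of a relative-abundance
#' matrix (natural-log divergence; the square root is a metric). Zeros are
#' handled by the convention \eqn{0 \log 0 = 0}.
#'
#' @param P Numeric matrix of compositions (rows sum to 1), or a relative
#'   [taxon_table()].
#' @return A `dist` object of \eqn{\sqrt{JSD}} values.
#' @export
jsd_distance <- function(P) {
  if (inherits(P, "taxon_table")) P <- relative_abundance(P)$values
  n <- nrow(P)
  ent <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  h <- apply(P, 1L, ent)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      jsd <- ent((P[i, ] + P[j, ]) / 2) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  rownames(d) <- colnames(d) <- rownames(P)
  stats::as.dist(d)
}

# Calinski-Harabasz pseudo-F from a distance matrix and hard labels,
# using the standard sum-of-squares identity on pairwise distances.
calinski_harabasz <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  k <- length(unique(labels))
  total_ss <- sum(d^2) / (2 * n)
  within_ss <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1L)
      within_ss <- within_ss + sum(d[idx, idx]^2) / (2 * length(idx))
  }
  between_ss <- total_ss - within_ss
  if (k == 1L || within_ss == 0) return(Inf)
  (between_ss / (k - 1)) / (within_ss / (n - k))
}

#' Assign enterotypes by JSD + PAM clustering
#'
#' Clusters samples on genus-level relative abundance using the root
#' Jensen-Shannon divergence distance and partitioning around medoids,
#' choosing the number of clusters by the maximal Calinski-Harabasz
#' pseudo-F over `k_candidates`. With the default candidate set this
#' reproduces the common two-enterotype (e.g. Prevotella- vs
#' Bacteroides-dominated) partition when the data support it.
#'
#' @param T A relative or counts [taxon_table()] at genus level.
#' @param k_candidates Integer vector of candidate cluster numbers.
#' @return List of class `enterotype_assignment`: `labels` (per-sample
#'   integer), `k`, `ch_scores` (named over candidates), `medoids` (sample
#'   ids), `distance` (the `dist` used).
#' @export
assign_enterotypes <- function(T, k_candidates = 2:10) {
  stopifnot(inherits(T, "taxon_table"))
  if (nrow(T$values) < 3L)
    stop_mm("insufficient_data", "need at least 3 samples")
  rel <- relative_abundance(T)
  d <- jsd_distance(rel)
  k_candidates <- k_candidates[k_candidates < nrow(rel$values)]
  if (!length(k_candidates))
    stop_mm("invalid_argument", "no feasible k in k_candidates")
  sols <- lapply(k_candidates, function(k) pam_cluster(d, k))
  ch <- vapply(sols, function(s) calinski_harabasz(d, s$labels), numeric(1))
  best <- which.max(ch)
  sol <- sols[[best]]
  structure(list(labels = sol$labels, k = k_candidates[best],
                 ch_scores = stats::setNames(ch, k_candidates),
                 medoids = sol$medoids, distance = d),
            class = "enterotype_assignment")
}

#' @export
print.enterotype_assignment <- function(x, ...) {
  cat(sprintf("<enterotype_assignment> k = %d (CH = %.2f)\n",
              x$k, max(x$ch_scores)))
  print(table(x$labels))
  invisible(x)
}
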