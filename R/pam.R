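# ---- distance handling -----------------------------------------------------

# Accepts a dist, a square symmetric distance matrix (zero diagonal), or a
# feature matrix (rows = objects) converted to Euclidean distances.
as_dissimilarity <- function(D) {
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D) && nrow(D) == ncol(D) && all(abs(diag(D)) < 1e-12)) {
    if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
      stop_mm("invalid_input", "asymmetric square matrix is not a distance")
    return(D)
  }
  if (is.matrix(D) || is.data.frame(D))
    return(as.matrix(stats::dist(as.matrix(D))))
  stop_mm("invalid_input", "D must be a dist, distance matrix or feature matrix")
}

#' Partitioning around medoids (PAM)
#'
#' k-medoids clustering minimizing the total dissimilarity of every object
#' to its assigned medoid, \eqn{\sum_i \sum_j d(i,j) z_{ij}}. Uses the
#' classic two-phase algorithm: BUILD greedily seeds k medoids (first the
#' object minimizing total dissimilarity, then the object giving the largest
#' objective decrease), and SWAP repeatedly evaluates every
#' (medoid, non-medoid) exchange, applying the best improving swap until
#' none remains. Ties are broken by lowest object index, so the result is
#' deterministic.
#'
#' @param D A `dist`, a square symmetric distance matrix with zero
#'   diagonal, or a numeric feature matrix (rows are objects; Euclidean
#'   distances are used).
#' @param k Number of clusters, 1 <= k <= n.
#' @return List of class `cluster_solution`: `labels` (1..k per object,
#'   named), `medoids` (object names or indices), `medoid_idx`, `objective`,
#'   `silhouette` (per-object widths), `avg_silhouette`, `k`.
#' @examples
#' d <- dist(c(0, 0.1, 10, 10.1))
#' pam_cluster(d, 2)$labels
#' @export
pam_cluster <- function(D, k) {
  d <- as_dissimilarity(D)
  n <- nrow(d)
  k <- check_count(k, "k")
  if (k > n)
    stop_mm("invalid_argument", "k = %d exceeds number of objects (%d)", k, n)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD
  medoids <- which.min(rowSums(d))
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(o) {
      if (o %in% medoids) return(-Inf)
      sum(pmax(nearest - d[, o], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gain))
    nearest <- pmin(nearest, d[, medoids[length(medoids)]])
  }

  # SWAP: best improving (medoid, non-medoid) exchange per pass
  repeat {
    dm <- d[, medoids, drop = FALSE]
    ord <- apply(dm, 1L, order)
    nearest_i <- ord[1L, ]
    nearest_d <- dm[cbind(seq_len(n), nearest_i)]
    second_d <- if (length(medoids) > 1L)
      dm[cbind(seq_len(n), ord[2L, ])] else rep(Inf, n)
    objective <- sum(nearest_d)
    best_delta <- 0
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      affected <- nearest_i == mi
      for (o in seq_len(n)) {
        if (o %in% medoids) next
        new_d <- ifelse(affected, pmin(second_d, d[, o]),
                        pmin(nearest_d, d[, o]))
        delta <- sum(new_d) - objective
        if (delta < best_delta - 1e-12) {
          best_delta <- delta
          best_swap <- c(mi, o)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
  }

  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  labels <- apply(dm, 1L, which.min)
  objective <- sum(dm[cbind(seq_len(n), labels)])
  sil <- silhouette_widths(d, labels)
  structure(list(labels = stats::setNames(labels, ids),
                 medoids = ids[medoids], medoid_idx = medoids,
                 objective = objective,
                 silhouette = stats::setNames(sil, ids),
                 avg_silhouette = mean(sil), k = k),
            class = "cluster_solution")
}

#' Per-object silhouette widths
#'
#' For object i with within-cluster mean dissimilarity \eqn{N_i} (excluding
#' itself) and \eqn{M_i} the minimum over other clusters of the mean
#' dissimilarity to that cluster's objects, the silhouette width is
#' \eqn{(M_i - N_i) / \max(M_i, N_i)}. Objects in singleton clusters get
#' width 0.
#'
#' @param d Square distance matrix.
#' @param labels Integer cluster labels.
#' @return Numeric vector of widths in [-1, 1].
#' @export
silhouette_widths <- function(d, labels) {
  d <- as_dissimilarity(d)
  n <- nrow(d)
  cl <- sort(unique(labels))
  if (length(cl) == 1L) return(rep(0, n))
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    N <- sum(d[i, own]) / (length(own) - 1L)
    M <- min(vapply(setdiff(cl, labels[i]), function(w)
      mean(d[i, labels == w]), numeric(1)))
    if (max(M, N) == 0) 0 else (M - N) / max(M, N)
  }, numeric(1))
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for every candidate k and returns the solution with
#' the maximal average silhouette width (the `pamk`-style selection rule).
#'
#' @param D Distance or feature input as in [pam_cluster()].
#' @param k_range Candidate cluster numbers (default 2:10); candidates not
#'   below the number of objects are skipped.
#' @return List: `k_opt`, `solution` (the winning `cluster_solution`),
#'   `avg_widths` (named over candidates), `solutions` (all candidates).
#' @export
choose_k_by_silhouette <- function(D, k_range = 2:10) {
  d <- as_dissimilarity(D)
  k_range <- k_range[k_range >= 2L & k_range < nrow(d)]
  if (!length(k_range))
    stop_mm("invalid_argument", "no feasible k in k_range")
  sols <- lapply(k_range, function(k) pam_cluster(d, k))
  widths <- vapply(sols, `[[`, numeric(1), "avg_silhouette")
  best <- which.max(widths)
  list(k_opt = k_range[best], solution = sols[[best]],
       avg_widths = stats::setNames(widths, k_range), solutions = sols)
}

#' Jaccard similarity between two clusterings
#'
#' Over all unordered object pairs, counts pairs co-clustered in both
#' solutions (a), in the first only (b), and in the second only (c), and
#' returns \eqn{J = a / (a + b + c)}. Invariant to cluster relabeling and
#' symmetric in its arguments. When both clusterings are all singletons
#' (a + b + c = 0) the similarity is defined as 1, with a warning.
#'
#' @param A,B `cluster_solution` objects or label vectors over the same
#'   object set (matched by names when present).
#' @return A number in [0, 1].
#' @examples
#' jaccard_cluster_similarity(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
jaccard_cluster_similarity <- function(A, B) {
  la <- if (inherits(A, "cluster_solution")) A$labels else A
  lb <- if (inherits(B, "cluster_solution")) B$labels else B
  if (!is.null(names(la)) && !is.null(names(lb))) {
    if (!setequal(names(la), names(lb)))
      stop_mm("invalid_input", "clusterings label different object sets")
    lb <- lb[names(la)]
  } else if (length(la) != length(lb)) {
    stop_mm("invalid_input", "clusterings label different object sets")
  }
  tab <- table(la, lb)
  pairs2 <- function(x) sum(x * (x - 1) / 2)
  a <- pairs2(tab)
  b <- pairs2(rowSums(tab)) - a
  c_ <- pairs2(colSums(tab)) - a
  if (a + b + c_ == 0) {
    warn_mm("all_singletons",
            "both clusterings are all singletons; similarity defined as 1")
    return(1)
  }
  a / (a + b + c_)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d, objective = %.4f, avg silhouette = %.3f\n",
              x$k, x$objective, x$avg_silhouette))
  cat("  medoids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}
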