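#' Select MR instruments with the study's exclusion rules
#'
#' Forward direction (microbiome exposure, trait outcome): starts from the
#' clumped exposure leads and drops any instrument whose association with
#' the outcome trait is itself significant at `0.05 / n` (n = number of
#' instruments), removing variants with plausible direct trait effects.
#' Reverse direction (disease exposure, taxon outcome): thins the replicated
#' disease variants to mutual independence (pairwise r-squared below
#' `r2_thresh` in the cohort LD reference), keeping the smaller-p member of
#' each correlated set.
#'
#' @param exposure_assoc `summary_stats` for the exposure instruments
#'   (forward: already LD-clumped leads).
#' @param outcome_stats `summary_stats` for the outcome, matched by id
#'   (forward direction only; may omit instruments).
#' @param direction `"forward"` or `"reverse"`.
#' @param alpha_exclude Exclusion level before division by the instrument
#'   count (default 0.05).
#' @param ld_ref [genotype_matrix()] LD reference (reverse direction).
#' @param r2_thresh Independence threshold for reverse thinning.
#' @return Character vector of retained instrument ids.
#' @export
select_instruments <- function(exposure_assoc, outcome_stats = NULL,
                               direction = c("forward", "reverse"),
                               alpha_exclude = 0.05, ld_ref = NULL,
                               r2_thresh = 0.1) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    ids <- exposure_assoc$id
    n_iv <- length(ids)
    if (!is.null(outcome_stats)) {
      op <- outcome_stats$p[match(ids, outcome_stats$id)]
      drop <- !is.na(op) & op < alpha_exclude / n_iv
      ids <- ids[!drop]
    }
  } else {
    if (is.null(ld_ref))
      stop_mm("invalid_argument", "reverse selection needs an LD reference")
    keep <- ld_clump(exposure_assoc, ld_ref, p_thresh = 1.1,
                     r2_thresh = r2_thresh, window_cm = Inf)
    ids <- keep
  }
  if (!length(ids))
    stop_mm("empty_instruments", "no instruments survive selection (%s)",
            direction)
  ids
}

#' Find the best LD proxy for a missing variant
#'
#' Scans the LD reference for the candidate with the highest squared dosage
#' correlation with the query variant, restricted to candidates present in
#' the outcome statistics, and returns it if its r-squared exceeds `r2_min`
#' (strictly). Returns NULL (with a warning when the query itself is absent
#' from the reference) when no adequate proxy exists.
#'
#' @param variant Query variant id.
#' @param ld_reference A [genotype_matrix()].
#' @param outcome_ids Character vector of variant ids available in the
#'   outcome statistics.
#' @param r2_min Proxy threshold, default 0.9 (exclusive).
#' @return List with `id` and `r2`, or NULL.
#' @export
find_proxy <- function(variant, ld_reference, outcome_ids, r2_min = 0.9) {
  stopifnot(inherits(ld_reference, "genotype_matrix"))
  qi <- match(variant, ld_reference$variants$id)
  if (is.na(qi)) {
    warn_mm("proxy_query_missing", "variant %s absent from LD reference",
            variant)
    return(NULL)
  }
  cand <- setdiff(intersect(outcome_ids, ld_reference$variants$id), variant)
  if (!length(cand)) return(NULL)
  ci <- match(cand, ld_reference$variants$id)
  r2 <- suppressWarnings(
    as.vector(stats::cor(ld_reference$dosage[, qi],
                         ld_reference$dosage[, ci, drop = FALSE]))^2)
  r2[is.na(r2)] <- 0
  best <- which.max(r2)
  if (r2[best] > r2_min) list(id = cand[best], r2 = r2[best]) else NULL
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for every shared
#' variant. When the outcome's effect allele equals the exposure's other
#' allele the outcome beta is sign-flipped and its allele frequency
#' complemented. Palindromic variants (A/T or C/G) cannot be aligned by
#' allele labels alone: they are resolved by allele frequency when both
#' frequencies are clearly away from 0.5 (below 0.42 or above 0.58), and
#' dropped otherwise. Variants with incompatible allele pairs are dropped
#' with a reason.
#'
#' @param exposure,outcome `summary_stats` data frames.
#' @param direction Label stored on the result, e.g. `"microbiome_to_trait"`.
#' @param eaf_window Palindromic ambiguity zone half-open bounds, default
#'   `c(0.42, 0.58)`.
#' @return A `harmonized_instruments` data frame with columns `id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `effect_allele`; attributes `dropped` (data frame id/reason) and
#'   `direction`.
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  direction = "microbiome_to_trait",
                                  eaf_window = c(0.42, 0.58)) {
  shared <- intersect(exposure$id, outcome$id)
  ei <- match(shared, exposure$id)
  oi <- match(shared, outcome$id)
  dropped <- list()
  rows <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (s in seq_along(shared)) {
    e <- exposure[ei[s], ]; o <- outcome[oi[s], ]
    palindromic <- comp[[e$effect_allele]] == e$other_allele
    flip <- NA
    if (o$effect_allele == e$effect_allele && o$other_allele == e$other_allele) {
      flip <- FALSE
    } else if (o$effect_allele == e$other_allele &&
               o$other_allele == e$effect_allele) {
      flip <- TRUE
    } else if (!palindromic &&
               o$effect_allele == comp[[e$effect_allele]] &&
               o$other_allele == comp[[e$other_allele]]) {
      flip <- FALSE   # same orientation, opposite strand
    } else if (!palindromic &&
               o$effect_allele == comp[[e$other_allele]] &&
               o$other_allele == comp[[e$effect_allele]]) {
      flip <- TRUE
    } else {
      dropped[[length(dropped) + 1L]] <-
        data.frame(id = e$id, reason = "incompatible alleles")
      next
    }
    if (palindromic) {
      inferable <- !is.na(e$eaf) && !is.na(o$eaf) &&
        (e$eaf < eaf_window[1] || e$eaf > eaf_window[2]) &&
        (o$eaf < eaf_window[1] || o$eaf > eaf_window[2])
      if (!inferable) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(id = e$id, reason = "palindromic, ambiguous EAF")
        next
      }
      # align by frequency: same side of 0.5 means same allele
      flip <- (e$eaf < 0.5) != (o$eaf < 0.5)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = e$id,
      beta_exposure = e$beta, se_exposure = e$se,
      beta_outcome = if (flip) -o$beta else o$beta,
      se_outcome = o$se,
      eaf = e$eaf,
      effect_allele = e$effect_allele,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    stop_mm("empty_instruments", "no harmonizable instruments")
  h <- do.call(rbind, rows)
  harmonized_instruments(h$beta_exposure, h$se_exposure, h$beta_outcome,
                         h$se_outcome, id = h$id,
                         effect_allele = h$effect_allele, eaf = h$eaf,
                         direction = direction,
                         dropped = if (length(dropped)) do.call(rbind, dropped)
                         else NULL)
}

#' Construct a harmonized instrument set directly
#'
#' Low-level constructor used by [harmonize_instruments()] and by
#' simulation studies where allele-aligned effects are generated directly.
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors
#'   of equal length (>= 1); standard errors strictly positive.
#' @param id Instrument ids (defaults to `iv1..ivk`).
#' @param effect_allele,eaf Optional allele metadata.
#' @param direction Direction label.
#' @param dropped Optional data frame of dropped variants with reasons.
#' @return A data frame of class `harmonized_instruments`.
#' @export
harmonized_instruments <- function(beta_exposure, se_exposure, beta_outcome,
                                   se_outcome,
                                   id = paste0("iv", seq_along(beta_exposure)),
                                   effect_allele = NA_character_,
                                   eaf = NA_real_,
                                   direction = "microbiome_to_trait",
                                   dropped = NULL) {
  k <- length(beta_exposure)
  if (k < 1L)
    stop_mm("empty_instruments", "need at least one instrument")
  if (length(se_exposure) != k || length(beta_outcome) != k ||
      length(se_outcome) != k)
    stop_mm("invalid_argument", "instrument vectors must have equal length")
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop_mm("invalid_argument", "standard errors must be > 0")
  h <- data.frame(id = id, beta_exposure = beta_exposure,
                  se_exposure = se_exposure, beta_outcome = beta_outcome,
                  se_outcome = se_outcome, eaf = eaf,
                  effect_allele = effect_allele, stringsAsFactors = FALSE)
  attr(h, "direction") <- direction
  attr(h, "dropped") <- dropped
  class(h) <- c("harmonized_instruments", class(h))
  h
}
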