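#' Construct a genotype matrix object
#'
#' Container for sample-by-variant allele dosages plus per-variant metadata.
#' Dosages count copies of the effect allele, so values lie in [0, 2].
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns.
#' @param variants Data frame with one row per variant and columns
#'   `id`, `chrom`, `pos_bp`, `pos_cm`, `effect_allele`, `other_allele`,
#'   `maf`.
#' @param sample_ids Character vector of sample identifiers (defaults to the
#'   matrix rownames).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants` and `sample_ids`.
#' @export
genotype_matrix <- function(dosage, variants, sample_ids = rownames(dosage)) {
  if (!is.matrix(dosage) || !is.numeric(dosage))
    stop_mm("invalid_argument", "dosage must be a numeric matrix")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  required <- c("id", "chrom", "pos_bp", "pos_cm",
                "effect_allele", "other_allele", "maf")
  if (!all(required %in% names(variants)))
    stop_mm("invalid_argument", "variants is missing columns: %s",
            paste(setdiff(required, names(variants)), collapse = ", "))
  if (nrow(variants) != ncol(dosage))
    stop_mm("invalid_argument",
            "variants has %d rows but dosage has %d columns",
            nrow(variants), ncol(dosage))
  if (anyDuplicated(variants$id))
    stop_mm("invalid_argument", "duplicate variant ids")
  if (anyDuplicated(sample_ids))
    stop_mm("invalid_argument", "duplicate sample ids")
  rng <- range(dosage)
  if (rng[1] < 0 || rng[2] > 2)
    stop_mm("invalid_argument", "dosages must lie in [0, 2]")
  # positions must be sorted within each chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos_bp[variants$chrom == ch]
    if (is.unsorted(p))
      stop_mm("invalid_argument",
              "variant positions are not non-decreasing on chrom %s", ch)
  }
  dimnames(dosage) <- list(sample_ids, variants$id)
  structure(list(dosage = dosage,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chrom(s): %s; MAF range %.3f-%.3f\n",
              paste(unique(x$variants$chrom), collapse = ","),
              min(x$variants$maf), max(x$variants$maf)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Construct a taxon abundance table
#'
#' Container for a samples-by-taxa matrix of counts or relative abundances.
#' Taxon identifiers carry their taxonomic level in the conventional
#' `"level|name"` form (e.g. `"genus|Bacteroides"`).
#'
#' @param values Non-negative numeric matrix, samples in rows, taxa in
#'   columns. Column names are taken as taxon ids when `taxon_ids` is NULL.
#' @param taxon_ids Character vector of `"level|name"` taxon labels.
#' @param sample_ids Character vector of sample identifiers.
#' @param type Either `"counts"` or `"relative"`. Relative tables must have
#'   rows summing to 1 (tolerance 1e-8); all-zero rows are rejected.
#'
#' @return An object of class `taxon_table`: list with elements `values`,
#'   `taxa` (data frame of `id`, `level`, `name`), `sample_ids`, `type`.
#' @export
taxon_table <- function(values, taxon_ids = colnames(values),
                        sample_ids = rownames(values),
                        type = c("counts", "relative")) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop_mm("invalid_argument", "values must be a numeric matrix")
  if (is.null(taxon_ids))
    stop_mm("invalid_argument", "taxon ids are required")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(taxon_ids))
    stop_mm("invalid_argument", "taxon ids must be unique")
  if (anyDuplicated(sample_ids))
    stop_mm("invalid_argument", "duplicate sample id: %s",
            sample_ids[duplicated(sample_ids)][1])
  if (min(values) < 0)
    stop_mm("invalid_argument", "negative abundance values")
  if (type == "relative") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-8))
      stop_mm("invalid_argument",
              "relative-abundance rows must sum to 1 (max deviation %.3g)",
              max(abs(rs - 1)))
  }
  lv <- sub("\\|.*$", "", taxon_ids)
  nm <- sub("^[^|]*\\|", "", taxon_ids)
  known <- c("phylum", "class", "order", "family", "genus", "species")
  lv[!lv %in% known | lv == taxon_ids] <- NA_character_
  dimnames(values) <- list(sample_ids, taxon_ids)
  structure(list(values = values,
                 taxa = data.frame(id = as.character(taxon_ids), level = lv,
                                   name = nm, stringsAsFactors = FALSE),
                 sample_ids = as.character(sample_ids),
                 type = type),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table> %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values), x$type))
  lvl <- table(x$taxa$level, useNA = "ifany")
  cat("  levels:", paste(names(lvl), lvl, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$values)

#' Convert a count table to relative abundances
#'
#' @param T A `taxon_table` of counts.
#' @return A `taxon_table` with `type = "relative"`.
#' @export
relative_abundance <- function(T) {
  stopifnot(inherits(T, "taxon_table"))
  if (T$type == "relative") return(T)
  tot <- rowSums(T$values)
  if (any(tot == 0))
    stop_mm("undefined_diversity", "sample(s) with zero total count: %s",
            paste(T$sample_ids[tot == 0], collapse = ", "))
  taxon_table(T$values / tot, T$taxa$id, T$sample_ids, type = "relative")
}

#' Validate a GWAS summary-statistics table
#'
#' Checks the column contract shared by the simulated external GWAS, the
#' association-scan output and all Mendelian-randomization inputs. Alleles
#' must be single bases in A/C/G/T; standard errors strictly positive.
#'
#' @param stats Data frame with columns `id`, `chrom`, `pos_bp`, `pos_cm`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @return The validated data frame, invisibly classed `summary_stats`.
#' @export
as_summary_stats <- function(stats) {
  required <- c("id", "chrom", "pos_bp", "pos_cm", "effect_allele",
                "other_allele", "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols))
    stop_mm("invalid_argument", "summary stats missing columns: %s",
            paste(missing_cols, collapse = ", "))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- !ok_allele(stats$effect_allele) | !ok_allele(stats$other_allele)
  if (any(bad))
    stop_mm("invalid_argument",
            "non single-base alleles for variant(s): %s",
            paste(utils::head(stats$id[bad], 5), collapse = ", "))
  if (any(stats$se <= 0, na.rm = TRUE))
    stop_mm("invalid_argument", "standard errors must be > 0")
  class(stats) <- unique(c("summary_stats", class(stats)))
  stats
}
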