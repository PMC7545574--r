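# ---- provenance ------------------------------------------------------------

# FNV-1a hash of a character representation; used to stamp outputs with the
# configuration that produced them.
config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_line <- function(config = NULL, seed = NULL) {
  sprintf("# provenance: micromendr config=%s seed=%s",
          if (is.null(config)) "none" else config_hash(config),
          if (is.null(seed)) "none" else as.character(seed))
}

write_tsv_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path, ...) {
  if (!file.exists(path))
    stop_mm("io_error", "file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

# ---- taxon tables ----------------------------------------------------------

#' Write / read a taxon table TSV
#'
#' The dialect has samples as rows, a first column `sample_id`, and taxon
#' labels (`"level|name"`) as the remaining headers. A `# provenance:`
#' comment line may precede the header. BIOM-style tables with taxa as rows
#' are read via `taxa_as_rows = TRUE`.
#'
#' @param T A [taxon_table()].
#' @param path Output/input file path.
#' @param provenance Optional provenance comment line.
#' @param type Value type stored in the file (`"counts"` or `"relative"`).
#' @param taxa_as_rows Set TRUE when reading a transposed (taxa x samples)
#'   table.
#' @return `write_taxon_table` returns the path; `read_taxon_table` a
#'   [taxon_table()].
#' @export
write_taxon_table <- function(T, path, provenance = NULL) {
  stopifnot(inherits(T, "taxon_table"))
  df <- data.frame(sample_id = T$sample_ids, T$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, provenance)
}

#' @rdname write_taxon_table
#' @export
read_taxon_table <- function(path, type = c("counts", "relative"),
                             taxa_as_rows = FALSE) {
  type <- match.arg(type)
  df <- read_tsv_prov(path)
  if (taxa_as_rows) {
    taxon_ids <- as.character(df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    sample_ids <- colnames(df)[-1]
  } else {
    sample_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    taxon_ids <- colnames(df)[-1]
  }
  if (anyDuplicated(sample_ids))
    stop_mm("parse_error", "duplicated sample id in %s: %s", path,
            sample_ids[duplicated(sample_ids)][1])
  if (!is.numeric(m))
    stop_mm("parse_error", "non-numeric abundance cells in %s", path)
  rownames(m) <- sample_ids
  taxon_table(m, taxon_ids, sample_ids, type = type)
}

# ---- genotypes -------------------------------------------------------------

#' Write / read genotype dosages
#'
#' The TSV dialect stores dosages as samples x variants with a `sample_id`
#' first column, and the variant metadata (id, chrom, positions, alleles,
#' MAF) in a sidecar file `<stem>_variants.tsv`. The VCF dialect writes a
#' minimal VCF 4.2 with a `DS` FORMAT field and the centimorgan position in
#' the INFO field (`CM=`); reading VCF uses the vcfR package.
#'
#' @param G A [genotype_matrix()].
#' @param path File path (`.tsv` stem or `.vcf`).
#' @param format `"tsv"` or `"vcf"`.
#' @param provenance Optional provenance comment (TSV only).
#' @return `write_genotypes` the main path; `read_genotypes` a
#'   [genotype_matrix()].
#' @export
write_genotypes <- function(G, path, format = c("tsv", "vcf"),
                            provenance = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = G$sample_ids, G$dosage, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_prov(df, path, provenance)
    write_tsv_prov(G$variants, variants_sidecar(path), provenance)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in cM\">",
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", G$sample_ids), collapse = "\t")), con)
    for (j in seq_len(ncol(G$dosage))) {
      v <- G$variants[j, ]
      writeLines(paste(c(v$chrom, v$pos_bp, v$id, v$other_allele,
                         v$effect_allele, ".", "PASS",
                         sprintf("CM=%.6g", v$pos_cm), "DS",
                         formatC(G$dosage[, j], format = "g")),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

variants_sidecar <- function(path) {
  sub("\\.tsv$", "_variants.tsv", path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_prov(path)
    sample_ids <- as.character(df[[1]])
    dos <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(dos))
      stop_mm("parse_error", "non-numeric dosage cells in %s", path)
    storage.mode(dos) <- "double"
    rownames(dos) <- sample_ids
    variants <- read_tsv_prov(variants_sidecar(path))
    variants$chrom <- as.character(variants$chrom)
    return(genotype_matrix(dos, variants, sample_ids))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_mm("io_error", "reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  dos <- t(ds)
  cm <- as.numeric(sub("^.*CM=([0-9.eE+-]+).*$", "\\1",
                       vcfR::getINFO(v)))
  variants <- data.frame(
    id = fix$ID, chrom = as.character(fix$CHROM),
    pos_bp = as.numeric(fix$POS), pos_cm = cm,
    effect_allele = fix$ALT, other_allele = fix$REF,
    maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, rownames(dos))
}

# ---- summary stats, covariates, pathways -----------------------------------

#' Write / read a GWAS summary-statistics TSV
#'
#' Columns: `id`, `chrom`, `pos_bp`, `pos_cm`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `p`, `n` (extra columns such as
#' `model` are preserved).
#'
#' @param stats A `summary_stats` data frame.
#' @param path File path.
#' @param provenance Optional provenance comment line.
#' @return The path / the validated `summary_stats`.
#' @export
write_summary_stats <- function(stats, path, provenance = NULL) {
  write_tsv_prov(as.data.frame(stats), path, provenance)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv_prov(path)
  df$chrom <- as.character(df$chrom)
  as_summary_stats(df)
}

#' Write / read a covariate table TSV (first column `sample_id`)
#' @param covariates Data frame with a `sample_id` column.
#' @param path File path.
#' @param provenance Optional provenance comment line.
#' @return The path / the data frame.
#' @export
write_covariates <- function(covariates, path, provenance = NULL) {
  write_tsv_prov(covariates, path, provenance)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  df <- read_tsv_prov(path)
  if (anyDuplicated(df$sample_id))
    stop_mm("parse_error", "duplicated sample id in %s: %s", path,
            df$sample_id[duplicated(df$sample_id)][1])
  df
}

#' Write / read a pathway (predicted disease) abundance TSV
#' @param P A `pathway_table`.
#' @param path File path.
#' @param provenance Optional provenance comment line.
#' @return The path / a `pathway_table`.
#' @export
write_pathway_table <- function(P, path, provenance = NULL) {
  df <- data.frame(sample_id = P$sample_ids, P$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_prov(df, path, provenance)
}

#' @rdname write_pathway_table
#' @export
read_pathway_table <- function(path) {
  df <- read_tsv_prov(path)
  sample_ids <- as.character(df[[1]])
  if (anyDuplicated(sample_ids))
    stop_mm("parse_error", "duplicated sample id in %s: %s", path,
            sample_ids[duplicated(sample_ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || min(m) < 0)
    stop_mm("parse_error", "pathway values must be non-negative numbers (%s)",
            path)
  rownames(m) <- sample_ids
  structure(list(values = m, feature_ids = colnames(m),
                 sample_ids = sample_ids),
            class = "pathway_table")
}

# ---- cohort bundle ---------------------------------------------------------

#' Write a simulated cohort bundle to a directory
#'
#' Writes every component in the package's dialects: `genotypes.tsv` (+
#' variants sidecar), `taxa.tsv`, `covariates.tsv`, `disease.tsv`,
#' `disease_stats.tsv`, `trait_stats.tsv`, `pathways.tsv`,
#' `predicted_disease.tsv` and `ground_truth.json`, each TSV stamped with a
#' provenance comment.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_line(bundle$truth$config, bundle$truth$seed)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    taxa = file.path(dir, "taxa.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    disease = file.path(dir, "disease.tsv"),
    disease_stats = file.path(dir, "disease_stats.tsv"),
    trait_stats = file.path(dir, "trait_stats.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    predicted_disease = file.path(dir, "predicted_disease.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_genotypes(bundle$genotypes, paths[["genotypes"]], provenance = prov)
  write_taxon_table(bundle$taxa, paths[["taxa"]], provenance = prov)
  write_covariates(bundle$covariates, paths[["covariates"]], provenance = prov)
  write_tsv_prov(data.frame(sample_id = names(bundle$disease),
                            disease = as.integer(bundle$disease)),
                 paths[["disease"]], prov)
  write_summary_stats(bundle$disease_stats, paths[["disease_stats"]], prov)
  if (!is.null(bundle$trait_stats))
    write_summary_stats(bundle$trait_stats, paths[["trait_stats"]], prov)
  write_pathway_table(bundle$pathways, paths[["pathways"]], prov)
  if (!is.null(bundle$predicted_disease))
    write_tsv_prov(data.frame(sample_id = names(bundle$predicted_disease),
                              predicted_disease = bundle$predicted_disease),
                   paths[["predicted_disease"]], prov)
  truth_json <- bundle$truth
  truth_json$genetic_values <- NULL   # large latent matrices stay in memory
  truth_json$latent_logabund <- NULL
  jsonlite::write_json(truth_json, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  paths
}

#' Load a dataset directory into a validated bundle
#'
#' Reads whichever of the conventional files are present (see
#' [write_cohort()]), enforces cross-file sample-id consistency, and emits a
#' validation report. Descriptive parse errors carry the offending file and
#' identifier.
#'
#' @param dir Directory holding the dataset files.
#' @return List of class `dataset_bundle` with the available components and
#'   a `validation` character vector of notes.
#' @export
load_dataset <- function(dir) {
  if (!dir.exists(dir))
    stop_mm("io_error", "dataset directory not found: %s", dir)
  notes <- character(0)
  path <- function(f) file.path(dir, f)
  out <- list()
  if (file.exists(path("genotypes.tsv")))
    out$genotypes <- read_genotypes(path("genotypes.tsv"))
  else if (file.exists(path("genotypes.vcf")))
    out$genotypes <- read_genotypes(path("genotypes.vcf"), format = "vcf")
  if (file.exists(path("taxa.tsv")))
    out$taxa <- read_taxon_table(path("taxa.tsv"))
  if (file.exists(path("covariates.tsv")))
    out$covariates <- read_covariates(path("covariates.tsv"))
  if (file.exists(path("disease.tsv"))) {
    d <- read_tsv_prov(path("disease.tsv"))
    out$disease <- stats::setNames(d$disease, d$sample_id)
  }
  if (file.exists(path("disease_stats.tsv")))
    out$disease_stats <- read_summary_stats(path("disease_stats.tsv"))
  if (file.exists(path("trait_stats.tsv")))
    out$trait_stats <- read_summary_stats(path("trait_stats.tsv"))
  if (file.exists(path("pathways.tsv")))
    out$pathways <- read_pathway_table(path("pathways.tsv"))
  if (file.exists(path("predicted_disease.tsv"))) {
    pd <- read_tsv_prov(path("predicted_disease.tsv"))
    out$predicted_disease <- stats::setNames(pd$predicted_disease,
                                             pd$sample_id)
  }
  if (file.exists(path("ground_truth.json")))
    out$truth <- jsonlite::read_json(path("ground_truth.json"),
                                     simplifyVector = TRUE)
  # cross-file sample consistency
  id_sets <- list(
    genotypes = if (!is.null(out$genotypes)) out$genotypes$sample_ids,
    taxa = if (!is.null(out$taxa)) out$taxa$sample_ids,
    covariates = if (!is.null(out$covariates)) out$covariates$sample_id,
    disease = if (!is.null(out$disease)) names(out$disease),
    pathways = if (!is.null(out$pathways)) out$pathways$sample_ids
  )
  id_sets <- Filter(Negate(is.null), id_sets)
  if (length(id_sets) > 1L) {
    ref <- id_sets[[1]]
    for (nm in names(id_sets)[-1]) {
      if (!identical(id_sets[[nm]], ref))
        stop_mm("validation_error",
                "sample ids in %s do not match %s", nm, names(id_sets)[1])
    }
    notes <- c(notes, sprintf("%d samples consistent across %d files",
                              length(ref), length(id_sets)))
  }
  out$validation <- notes
  structure(out, class = "dataset_bundle")
}
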