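#' Write a genotype matrix as a VCF 4.2 file with dosage field
#'
#' One variant per row, FORMAT `DS` (estimated alternate allele dosage,
#' rounded to 4 decimals; missing as `.`), with the imputation info score
#' stored in the INFO column as `IMPINFO`.
#'
#' @param genos A [genotype_matrix()].
#' @param path Output path (plain text; `.vcf`).
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_matrix"))
  V <- genos$variants
  G <- t(genos$dosages)                      # variants x samples
  if (nrow(G) == 0L) {
    body <- character(0)
  } else {
    ds <- matrix(sprintf("%.4f", G), nrow(G), ncol(G))
    ds[is.na(G)] <- "."
    body <- paste(V$chrom, V$pos, V$id, V$ref, V$alt, ".", "PASS",
                  sprintf("IMPINFO=%.4g", V$info), "DS",
                  apply(ds, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=IMPINFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genos$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a dosage VCF into a genotype matrix
#'
#' Parses the FORMAT `DS` field of a VCF (plain or bgzipped) and the
#' `IMPINFO` INFO key if present; minor allele frequency, call rate and
#' Hardy-Weinberg exact p are recomputed from the dosages.
#'
#' @param path VCF path.
#' @return A [genotype_matrix()].
#' @export
read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS")
  G <- t(matrix(suppressWarnings(as.numeric(ds)), nrow(ds), ncol(ds)))
  info <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "IMPINFO")))
  info[is.na(info)] <- 1
  af <- colMeans(G, na.rm = TRUE) / 2
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID,
    ref = fix$REF, alt = fix$ALT,
    maf = pmin(af, 1 - af), info = info,
    call_rate = colMeans(!is.na(G)),
    hwe_p = hwe_from_dosages(G),
    stringsAsFactors = FALSE)
  genotype_matrix(G, variants, colnames(ds))
}

#' Write / read the phenotype table
#'
#' Tab-delimited with header; one row per sample. Factor columns are
#' stored as their labels and restored as factors on read.
#'
#' @param cohort Cohort data frame.
#' @param path TSV path.
#' @return `path` invisibly (write); the cohort data frame (read).
#' @export
write_phenotypes <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  factor_levels <- list(
    smoking = c("never", "previous", "current"),
    alcohol = c("non", "moderate", "heavy"),
    diet_oily_fish = c("low", "medium", "high"),
    diet_fruit = c("low", "medium", "high"),
    diet_vegetable = c("low", "medium", "high"),
    diet_processed_meat = c("low", "high"),
    diet_red_meat = c("low", "high"))
  for (nm in intersect(names(factor_levels), names(df))) {
    df[[nm]] <- factor(df[[nm]], levels = factor_levels[[nm]])
  }
  df
}

#' Write / read a plain dosage-matrix text file
#'
#' Tab-delimited dialect: metadata columns `chrom`, `pos`, `id`, `ref`,
#' `alt`, `info` followed by one dosage column per sample.
#'
#' @param genos A [genotype_matrix()].
#' @param path TSV path.
#' @return `path` invisibly (write); a [genotype_matrix()] (read).
#' @export
write_dosage_tsv <- function(genos, path) {
  V <- genos$variants
  df <- cbind(V[, c("chrom", "pos", "id", "ref", "alt", "info")],
              as.data.frame(t(round(genos$dosages, 4))))
  names(df)[-(1:6)] <- genos$sample_ids
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  meta <- df[, 1:6]
  G <- t(as.matrix(df[, -(1:6), drop = FALSE]))
  af <- colMeans(G, na.rm = TRUE) / 2
  variants <- data.frame(
    chrom = as.character(meta$chrom), pos = as.integer(meta$pos),
    id = meta$id, ref = meta$ref, alt = meta$alt,
    maf = pmin(af, 1 - af), info = meta$info,
    call_rate = colMeans(!is.na(G)),
    hwe_p = hwe_from_dosages(G), stringsAsFactors = FALSE)
  genotype_matrix(G, variants, rownames(G))
}

#' Write a simulated data set as an analysis-ready fixture
#'
#' Emits `genotypes.vcf` (dosage VCF), `phenotypes.tsv` and `truth.tsv`
#' (the planted per-variant main and interaction log hazard ratios) into
#' a directory; the files round-trip losslessly through
#' [read_dosage_vcf()] and [read_phenotypes()] up to the 4-decimal dosage
#' precision.
#'
#' @param genos A [genotype_matrix()].
#' @param cohort The matching cohort data frame.
#' @param dir Output directory (created if needed).
#' @param causal_effects Optional data frame of planted effects
#'   (`variant`, `beta_main`, `beta_gxe`); taken from a
#'   [simulation_spec()] via `spec$causal_effects`.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(genos, cohort, dir, causal_effects = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"),
            nrow(cohort) == nrow(genos$dosages))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             pheno = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_dosage_vcf(genos, paths["vcf"])
  write_phenotypes(cohort, paths["pheno"])
  truth <- if (is.null(causal_effects) || nrow(causal_effects) == 0L) {
    data.frame(variant_id = character(), beta_main = numeric(),
               beta_gxe = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = genos$variants$id[causal_effects$variant],
               beta_main = causal_effects$beta_main,
               beta_gxe = causal_effects$beta_gxe, stringsAsFactors = FALSE)
  }
  data.table::fwrite(truth, paths["truth"], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Read a BED interval file into 1-based inclusive coordinates
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so starts are shifted by +1.
#'
#' @param path BED path (first three columns used; optional 4th = name).
#' @return Data frame: `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = FALSE))
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  out
}

#' Read a gene annotation table
#'
#' Tab-delimited with header columns `chrom`, `start`, `end`, `strand`,
#' `symbol`, `biotype` (1-based inclusive coordinates).
#'
#' @param path TSV path.
#' @return Data frame of gene intervals.
#' @export
read_gene_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("chrom", "start", "end", "symbol")
  if (!all(need %in% names(df))) {
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  }
  df$chrom <- as.character(df$chrom)
  df
}

#' Write GWAS summary statistics as TSV
#'
#' @param results Data frame from [run_gwas()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
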