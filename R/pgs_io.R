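#' Write a PGS model in PGS Catalog scoring format
#'
#' Tab-separated scoring file with `#`-prefixed header lines carrying the
#' model id, method and hyperparameters, followed by the columns `rsID`,
#' `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight`. Weights are written with 17 significant digits so a
#' write/read round trip is lossless.
#'
#' @param model A `pgs_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgs_model <- function(model, path) {
  hp <- vapply(model$hyperparams, function(v) format(v, digits = 17), character(1))
  header <- c(
    "### PGS scoring file",
    sprintf("#model_id=%s", model$model_id),
    sprintf("#method=%s", model$method),
    sprintf("#hyperparams=%s", paste(names(hp), hp, sep = "=", collapse = ";"))
  )
  w <- model$weights
  body <- sprintf("%s\t%s\t%d\t%s\t%s\t%.17g",
                  w$variant_id, as.character(w$chromosome), as.integer(w$position),
                  w$effect_allele, w$other_allele, w$weight)
  writeLines(c(header,
               "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               body), path)
  invisible(path)
}

#' Read a PGS Catalog scoring file
#'
#' Parses `#`-prefixed metadata headers (if present) and the standard scoring
#' columns. Files written by other tools without the metadata headers are
#' accepted; the method then defaults to `"pt"` and hyperparameters are left
#' empty.
#'
#' @param path Scoring file path.
#' @return A `pgs_model`.
#' @export
read_pgs_model <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  if (!all(need %in% names(tab))) {
    stop("not a PGS scoring file: missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  get_meta <- function(key, default) {
    hit <- grep(sprintf("^#%s=", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^#%s=", key), "", hit[1]) else default
  }
  hp_str <- get_meta("hyperparams", "")
  hyperparams <- list()
  if (nzchar(hp_str)) {
    kv <- strsplit(strsplit(hp_str, ";")[[1]], "=")
    hyperparams <- lapply(kv, function(x) {
      v <- suppressWarnings(as.numeric(x[2]))
      if (is.na(v)) x[2] else v
    })
    names(hyperparams) <- vapply(kv, `[[`, character(1), 1)
  }
  weights <- data.frame(
    variant_id = tab$rsID,
    chromosome = tab$chr_name,
    position = tab$chr_position,
    effect_allele = tab$effect_allele,
    other_allele = tab$other_allele,
    weight = tab$effect_weight,
    stringsAsFactors = FALSE
  )
  method <- get_meta("method", "pt")
  new_pgs_model(get_meta("model_id", basename(path)), method, hyperparams, weights)
}

#' Write a dosage matrix as TSV
#'
#' Samples in rows, variants in columns; first column `sample_id`, header row
#' of variant ids, missing dosages written as `NA`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path) {
  df <- data.frame(sample_id = panel$samples$sample_id,
                   panel$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a dosage-matrix TSV into a genotype panel
#'
#' Inverse of [write_dosage_tsv()]. Variant metadata (alleles, positions,
#' frequencies) can be supplied; otherwise minimal metadata is reconstructed
#' with MAF from the observed dosages and placeholder alleles.
#'
#' @param path TSV path (first column `sample_id`, one column per variant).
#' @param variants Optional variant metadata data.frame matching
#'   `genotype_panel` conventions.
#' @return A `genotype_panel`.
#' @export
read_dosage_tsv <- function(path, variants = NULL) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$sample_id
  dos <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(dos) <- "numeric"
  rownames(dos) <- ids
  if (is.null(variants)) {
    af <- colMeans(dos, na.rm = TRUE) / 2
    variants <- data.frame(
      id = colnames(dos),
      chromosome = 1L,
      position = seq_len(ncol(dos)) * 5000L,
      effect_allele = "A", other_allele = "C",
      maf = pmin(af, 1 - af),
      imputation_r2 = 1,
      stringsAsFactors = FALSE
    )
  }
  samples <- data.frame(sample_id = ids, ancestry_ok = TRUE,
                        sex_consistent = TRUE, stringsAsFactors = FALSE)
  new_genotype_panel(dos, variants, samples)
}

#' Write a genotype panel as a dosage VCF
#'
#' Minimal VCFv4.2 with a `DS` (dosage) FORMAT field, one sample column per
#' individual, 1-based positions, REF = other allele, ALT = effect allele
#' (so `DS` counts the effect allele). Missing dosages are written as `.`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  ds <- t(panel$dosages)
  ds_chr <- matrix(sprintf("%.3f", ds), nrow(ds), ncol(ds))
  ds_chr[is.na(ds)] <- "."
  rows <- paste(v$chromosome, v$position, v$id, v$other_allele, v$effect_allele,
                ".", "PASS", ".", "DS",
                apply(ds_chr, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a dosage VCF into a genotype panel
#'
#' Uses the vcfR package to parse the VCF and extracts the `DS` FORMAT field
#' (falling back to hard genotypes from `GT` if `DS` is absent).
#'
#' @param path VCF path.
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- matrix(vapply(strsplit(gt, "[/|]"), function(a)
      sum(as.numeric(a)), numeric(1)), nrow(gt), ncol(gt))
    dimnames(fmt) <- dimnames(gt)
  }
  dos <- t(fmt)
  af <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(
    id = fix$ID,
    chromosome = as.integer(fix$CHROM),
    position = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF,
    maf = pmin(af, 1 - af),
    imputation_r2 = 1,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(sample_id = rownames(dos), ancestry_ok = TRUE,
                        sex_consistent = TRUE, stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  new_genotype_panel(dos, variants, samples)
}
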