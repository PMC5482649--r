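#' Write a cohort to disk
#'
#' Writes a VCF v4.2 (FORMAT GT:GQ:AD), a TSV sample sheet, a TSV annotation
#' table, and a JSON truth log. The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort an `rv_cohort`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "rv_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_vcf(cohort, paths$vcf)
  write.table(cohort$samples, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$annotations, paths$annotations, sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_maf <- as.list(truth$true_maf)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

write_vcf <- function(cohort, path) {
  v <- cohort$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(cohort$geno)), collapse = "\t")), con)
  if (nrow(v) > 0) {
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(nrow(v))) {
      key <- v$variant_key[j]
      g <- cohort$geno[, key]
      gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
      gq <- ifelse(is.na(cohort$gq[, key]), ".", cohort$gq[, key])
      ad <- paste(ifelse(is.na(cohort$ad_ref[, key]), ".", cohort$ad_ref[, key]),
                  ifelse(is.na(cohort$ad_alt[, key]), ".", cohort$ad_alt[, key]),
                  sep = ",")
      writeLines(paste(c(v$chrom[j], v$pos[j], key, v$ref[j], v$alt[j], ".",
                         "PASS", ".", "GT:GQ:AD",
                         paste(gt, gq, ad, sep = ":")), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Accepts plain or gzipped VCF v4.x with a GT FORMAT field; GQ and AD are
#' extracted when present (required downstream for genotype-level QC).
#' Multi-allelic records are rejected: split and normalize them upstream
#' (e.g. `bcftools norm -m-`) so that the (chrom, pos, ref, alt) key joins
#' unambiguously against the annotation table.
#'
#' @param path VCF file.
#' @return list with `geno` (samples x variants, 0/1/2/NA), `gq`, `ad_ref`,
#'   `ad_alt` (NULL when the field is absent), and `variants` (data.frame
#'   with chrom, pos, ref, alt, variant_key).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm)))  # single-record VCFs come back as a bare vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) > 0 && any(grepl(",", fix$ALT)))
    stop("multi-allelic records present (ALT with comma); split and ",
         "normalize to biallelic records first")
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  variants$variant_key <- variant_key(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)
  if (nrow(fix) == 0) {
    smp <- colnames(v@gt)[-1] %||% character(0)
    geno <- matrix(NA_integer_, nrow = length(smp), ncol = 0,
                   dimnames = list(smp, character(0)))
    return(list(geno = geno, gq = NULL, ad_ref = NULL, ad_alt = NULL,
                variants = variants))
  }
  gt <- vcfR::extract.gt(v)   # variants x samples
  parse_gt <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), variants$variant_key))
  for (i in seq_len(ncol(gt))) geno[i, ] <- parse_gt(gt[, i])
  gq <- ad_ref <- ad_alt <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("GQ", fmt))) {
    gqm <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    gq <- t(gqm)
    dimnames(gq) <- dimnames(geno)
  }
  if (any(grepl("AD", fmt))) {
    adm <- vcfR::extract.gt(v, element = "AD")
    refm <- suppressWarnings(apply(adm, 2, function(x)
      as.integer(vapply(strsplit(x, ","), function(p) p[1] %||% NA_character_,
                        character(1)))))
    altm <- suppressWarnings(apply(adm, 2, function(x)
      as.integer(vapply(strsplit(x, ","), function(p)
        if (length(p) >= 2) p[2] else NA_character_, character(1)))))
    ad_ref <- matrix(t(refm), nrow = nrow(geno), dimnames = dimnames(geno))
    ad_alt <- matrix(t(altm), nrow = nrow(geno), dimnames = dimnames(geno))
  }
  list(geno = geno, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt,
       variants = variants)
}

#' Read a sample sheet
#'
#' TSV with required columns `sample_id`, `status` (case/control),
#' `reported_sex` (M/F/unknown). Duplicate sample ids are an error.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "status", "reported_sex")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ids in sample sheet: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(tab$status), c("case", "control"))
  if (length(bad)) stop("invalid status values: ", paste(bad, collapse = ", "))
  tab$reported_sex[!tab$reported_sex %in% c("M", "F")] <- "unknown"
  tab
}

#' Read a per-variant annotation table
#'
#' TSV keyed by `variant_key` with columns `gene`, `consequence`,
#' `condel_label`, `alignability`, `repeat_distance`, `tranche`, `is_indel`.
#' Rows for variants absent from `known_keys` (when given) are dropped with
#' a warning.
#'
#' @param path TSV file.
#' @param known_keys optional character vector of VCF variant keys.
#' @return data.frame.
#' @export
read_annotation_table <- function(path, known_keys = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_key", "gene", "consequence", "condel_label",
            "alignability", "repeat_distance", "tranche", "is_indel")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(known_keys)) {
    unknown <- !(tab$variant_key %in% known_keys)
    if (any(unknown)) {
      warning(sum(unknown), " annotation rows refer to variants absent from ",
              "the VCF and were dropped")
      tab <- tab[!unknown, , drop = FALSE]
    }
  }
  tab
}

#' Read a gene-list file (one symbol per line)
#'
#' @param path text file.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `cohort.vcf`, `samples.tsv`,
#'   `annotations.tsv` and optionally `truth.json`.
#' @return an `rv_cohort`-like list (without the generator config).
#' @export
read_cohort <- function(dir) {
  vcf <- read_vcf(file.path(dir, "cohort.vcf"))
  samples <- read_sample_sheet(file.path(dir, "samples.tsv"))
  ann <- read_annotation_table(file.path(dir, "annotations.tsv"),
                               known_keys = vcf$variants$variant_key)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out <- list(geno = vcf$geno[samples$sample_id, , drop = FALSE],
              gq = vcf$gq, ad_ref = vcf$ad_ref, ad_alt = vcf$ad_alt,
              samples = samples, variants = vcf$variants,
              annotations = ann, truth = truth)
  class(out) <- "rv_cohort"
  out
}
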