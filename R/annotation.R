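# Consequence severity hierarchy (most severe first); splice acceptor and
# donor rank equally, as do the two inframe indel terms.
CONSEQUENCE_RANK <- c(
  stop_gained = 1L, frameshift = 2L,
  splice_acceptor = 3L, splice_donor = 3L,
  inframe_insertion = 4L, inframe_deletion = 4L,
  missense = 5L, synonymous = 6L, other = 7L
)

#' Select the worst consequence for a variant-gene pair
#'
#' When a variant carries several consequence annotations for one gene, keep
#' the single most severe under the hierarchy: stop gained > frameshift >
#' splice acceptor/donor > inframe insertion/deletion > missense >
#' synonymous > other. Ties are broken by input order.
#'
#' @param annotations data.frame of annotations for one variant-gene pair
#'   with columns `consequence` and (for missense) `condel_label`.
#' @return the single worst-consequence row.
#' @export
select_worst_consequence <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("no annotations supplied")
  r <- consequence_rank(annotations$consequence)
  annotations[which.min(r), , drop = FALSE]
}

consequence_rank <- function(consequence, strict = FALSE) {
  r <- CONSEQUENCE_RANK[consequence]
  if (anyNA(r)) {
    if (strict)
      stop("unknown consequence term(s): ",
           paste(unique(consequence[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- CONSEQUENCE_RANK["other"]
  }
  unname(r)
}

#' Assign a variant to the nested severity classes
#'
#' Class 1 "disruptive": stop gained and frameshift. Class 2 "predicted
#' damaging": Class 1 plus splice acceptor/donor and missense predicted
#' damaging. Class 3 "all non-synonymous": Class 2 plus remaining
#' non-synonymous variants (benign or unscored missense, inframe indels).
#' Synonymous and other variants belong to no class. The classes are
#' cumulative: the returned value is the *smallest* (most severe) class the
#' variant belongs to, and the variant is a member of every larger class.
#'
#' @param consequence consequence term(s).
#' @param condel_label `{damaging, benign, not_applicable}`; consulted only
#'   for missense.
#' @param strict error on unknown consequence terms instead of mapping them
#'   to `other`.
#' @return integer vector: 1, 2, 3, or NA (no class).
#' @export
assign_class <- function(consequence, condel_label = "not_applicable",
                         strict = FALSE) {
  consequence_rank(consequence, strict = strict)  # validates terms
  n <- max(length(consequence), length(condel_label))
  consequence <- rep_len(consequence, n)
  condel_label <- rep_len(condel_label, n)
  out <- rep(NA_integer_, n)
  out[consequence %in% c("stop_gained", "frameshift")] <- 1L
  out[consequence %in% c("splice_acceptor", "splice_donor")] <- 2L
  out[consequence == "missense" & condel_label == "damaging"] <- 2L
  out[consequence == "missense" & condel_label != "damaging"] <- 3L
  out[consequence %in% c("inframe_insertion", "inframe_deletion")] <- 3L
  out
}

#' Build per-gene nested qualifying-variant sets
#'
#' For each gene, the qualifying variants of Class c are the variants whose
#' assigned class is <= c and whose combined-cohort MAF (over called alleles
#' of cases and controls together) is strictly below `maf_threshold`. When
#' the annotation table carries a `ref_maf` column, an external reference
#' frequency below the same threshold is additionally required.
#'
#' @param geno samples x variants genotype matrix, QC-passed variants only.
#' @param annotations data.frame with `variant_key`, `gene`, `consequence`,
#'   `condel_label`, optionally `ref_maf`.
#' @param maf_threshold rare-variant frequency cap (default 1%).
#' @return data.frame with one row per (gene, class, variant):
#'   `gene`, `class_id`, `variant_key`.
#' @export
build_gene_class_sets <- function(geno, annotations, maf_threshold = 0.01) {
  ann <- annotations[annotations$variant_key %in% colnames(geno), , drop = FALSE]
  if (nrow(ann) == 0L)
    return(data.frame(gene = character(0), class_id = integer(0),
                      variant_key = character(0)))
  sub <- geno[, ann$variant_key, drop = FALSE]
  alt <- colSums(sub, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(sub))
  af <- alt / pmax(tot, 1L)
  maf <- pmin(af, 1 - af)
  rare <- maf < maf_threshold & tot > 0L
  if (!is.null(ann$ref_maf))
    rare <- rare & (is.na(ann$ref_maf) | ann$ref_maf < maf_threshold)
  cls <- assign_class(ann$consequence, ann$condel_label)
  keep <- rare & !is.na(cls)
  ann <- ann[keep, , drop = FALSE]
  cls <- cls[keep]
  if (nrow(ann) == 0L)
    return(data.frame(gene = character(0), class_id = integer(0),
                      variant_key = character(0)))
  rows <- lapply(1:3, function(cl) {
    sel <- cls <= cl
    if (!any(sel)) return(NULL)
    data.frame(gene = ann$gene[sel], class_id = cl,
               variant_key = ann$variant_key[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$class_id, out$variant_key), ]
  rownames(out) <- NULL
  out
}
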