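#' @include AllClasses.R
NULL

# ---- constructors ----------------------------------------------------------

#' Construct a Pedigree
#'
#' @param families data.frame with columns family_id, proband_id, father_id,
#'   mother_id, sex, affected.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(families) {
  families$affected <- as.character(families$affected)
  new("Pedigree", families = as.data.frame(families, stringsAsFactors = FALSE))
}

#' Construct a TrioVariantTable
#'
#' Missing annotation columns are added as NA; absent is explicit missingness,
#' never zero.
#'
#' @param records data.frame; required columns are family_id, chrom, pos, ref,
#'   alt, gt_proband, gt_father, gt_mother. Annotation columns are optional.
#' @return A \linkS4class{TrioVariantTable}.
#' @export
TrioVariantTable <- function(records = NULL) {
  if (is.null(records))
    records <- data.frame(matrix(nrow = 0L, ncol = 0L))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in .VARIANT_COLUMNS) {
    if (!col %in% names(records))
      records[[col]] <- if (col %in% c("pos")) integer(nrow(records))
        else if (grepl("^(maf_|cadd|sift_score|polyphen_score|ds_)", col))
          rep(NA_real_, nrow(records))
        else rep(NA_character_, nrow(records))
  }
  records <- records[, .VARIANT_COLUMNS]
  records$pos <- as.integer(records$pos)
  new("TrioVariantTable", records = records)
}

#' Construct an ExpressionMatrix from a TPM matrix
#'
#' @param tpm numeric matrix, genes x samples, with dimnames.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(tpm) {
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(tpm = tpm))
  new("ExpressionMatrix", se)
}

#' Construct a JunctionTable
#'
#' @param counts integer matrix, junctions x samples.
#' @param junctions \link[GenomicRanges]{GRanges} of introns (1-based
#'   inclusive, stranded), parallel to the rows of \code{counts}.
#' @return A \linkS4class{JunctionTable}.
#' @export
JunctionTable <- function(counts, junctions) {
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = junctions)
  new("JunctionTable", se)
}

#' Construct a GeneSetCollection
#'
#' Member lists are deduplicated; set sizes count unique symbols.
#'
#' @param sets named list of character vectors.
#' @param description optional character vector of per-set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (is.null(description)) description <- rep("", length(sets))
  description <- as.character(description)
  names(description) <- names(sets)
  new("GeneSetCollection", sets = sets, description = description)
}

GsvaScoreMatrix <- function(es, provenance) {
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(es = es))
  metadata(se)$provenance <- provenance
  new("GsvaScoreMatrix", se)
}

SyntheticTruth <- function(planted_denovo, planted_expr_outliers,
                           planted_splicing_shifts, planted_pathway_shifts) {
  new("SyntheticTruth",
      planted_denovo = planted_denovo,
      planted_expr_outliers = planted_expr_outliers,
      planted_splicing_shifts = planted_splicing_shifts,
      planted_pathway_shifts = planted_pathway_shifts)
}

# ---- accessors -------------------------------------------------------------

#' @rdname Pedigree-class
#' @param object,x a package object.
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname Pedigree-class
#' @export
setMethod("families", "Pedigree", function(x) x@families)

#' @rdname Pedigree-class
#' @export
setMethod("families", "TrioCohort", function(x) x@pedigree@families)

#' @rdname TrioVariantTable-class
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname TrioVariantTable-class
#' @export
setMethod("variantRecords", "TrioVariantTable", function(x) x@records)

#' @rdname TrioVariantTable-class
#' @export
setMethod("variantRecords", "TrioCohort", function(x) x@variants@records)

#' @rdname ExpressionMatrix-class
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("tpm", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "tpm"))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("tpm", "TrioCohort",
          function(x) SummarizedExperiment::assay(x@expression, "tpm"))

#' @rdname JunctionTable-class
#' @export
setGeneric("junctionCounts", function(x) standardGeneric("junctionCounts"))

#' @rdname JunctionTable-class
#' @export
setMethod("junctionCounts", "JunctionTable",
          function(x) SummarizedExperiment::assay(x, "counts"))

#' @rdname JunctionTable-class
#' @export
setMethod("junctionCounts", "TrioCohort",
          function(x) SummarizedExperiment::assay(x@junctions, "counts"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "TrioCohort", function(x) x@gene_sets@sets)

#' @rdname GsvaScoreMatrix-class
#' @export
setGeneric("esMatrix", function(x) standardGeneric("esMatrix"))

#' @rdname GsvaScoreMatrix-class
#' @export
setMethod("esMatrix", "GsvaScoreMatrix",
          function(x) SummarizedExperiment::assay(x, "es"))

#' @rdname GsvaScoreMatrix-class
#' @export
setGeneric("scoreProvenance", function(x) standardGeneric("scoreProvenance"))

#' @rdname GsvaScoreMatrix-class
#' @export
setMethod("scoreProvenance", "GsvaScoreMatrix",
          function(x) metadata(x)$provenance)

#' @rdname TrioCohort-class
#' @export
setGeneric("cpGenes", function(x) standardGeneric("cpGenes"))

#' @rdname TrioCohort-class
#' @export
setMethod("cpGenes", "TrioCohort", function(x) x@cp_genes)

#' @rdname TrioCohort-class
#' @export
setGeneric("truthRegistry", function(x) standardGeneric("truthRegistry"))

#' @rdname TrioCohort-class
#' @export
setMethod("truthRegistry", "TrioCohort", function(x) x@truth)

#' @rdname TrioCohort-class
#' @export
setGeneric("cohortExpression", function(x) standardGeneric("cohortExpression"))

#' @rdname TrioCohort-class
#' @export
setMethod("cohortExpression", "TrioCohort", function(x) x@expression)

#' @rdname TrioCohort-class
#' @export
setGeneric("cohortJunctions", function(x) standardGeneric("cohortJunctions"))

#' @rdname TrioCohort-class
#' @export
setMethod("cohortJunctions", "TrioCohort", function(x) x@junctions)

# ---- show ------------------------------------------------------------------

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", nrow(object@families), "trio families\n")
})

setMethod("show", "TrioVariantTable", function(object) {
  rec <- object@records
  cat("TrioVariantTable:", nrow(rec), "records across",
      length(unique(rec$family_id)), "families\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets",
      sprintf("(sizes %s)", if (length(object@sets))
        paste(range(lengths(object@sets)), collapse = "-") else "-"), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth registry:\n",
      " planted de novo variants:  ", nrow(object@planted_denovo), "\n",
      " planted expression outliers:", nrow(object@planted_expr_outliers), "\n",
      " planted splicing shifts:   ", nrow(object@planted_splicing_shifts), "\n",
      " planted pathway shifts:    ", nrow(object@planted_pathway_shifts), "\n")
})

setMethod("show", "TrioCohort", function(object) {
  cat("TrioCohort:", nrow(object@pedigree@families), "trios,",
      nrow(object@variants@records), "variant records,",
      nrow(object@expression), "genes,",
      nrow(object@junctions), "junctions,",
      length(object@gene_sets@sets), "gene sets",
      if (!is.null(object@truth)) "(synthetic, truth attached)" else "", "\n")
})
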