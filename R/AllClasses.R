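#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
NULL

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

FUNC_CLASSES <- c("missense", "frameshift", "stop_gain", "stop_loss",
                  "start_loss", "splice", "synonymous", "intronic", "other")

MAF_DATABASES <- c("thousand_genomes", "chinamap", "exac", "gnomad")

.VARIANT_COLUMNS <- c(
  "family_id", "chrom", "pos", "ref", "alt",
  "gt_proband", "gt_father", "gt_mother",
  "gene", "func_class",
  "maf_thousand_genomes", "maf_chinamap", "maf_exac", "maf_gnomad",
  "cadd_phred", "sift_score", "sift_call", "polyphen_score", "polyphen_call",
  "ds_ag", "ds_al", "ds_dg", "ds_dl", "clinvar")

.in01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))

#' Pedigree of trio families
#'
#' One row per family: an affected proband and two unaffected parents.
#' Sample ids must be distinct within a family.
#'
#' @slot families data.frame with columns family_id, proband_id, father_id,
#'   mother_id, sex ("male"/"female"), affected ("yes"/"no").
#' @export
setClass("Pedigree", representation(families = "data.frame"))

setValidity("Pedigree", function(object) {
  fam <- object@families
  need <- c("family_id", "proband_id", "father_id", "mother_id", "sex", "affected")
  if (!all(need %in% names(fam)))
    return(paste("missing pedigree columns:",
                 paste(setdiff(need, names(fam)), collapse = ", ")))
  if (anyDuplicated(fam$family_id))
    return("duplicate family ids")
  distinct <- apply(fam[, c("proband_id", "father_id", "mother_id")], 1L,
                    function(x) length(unique(x)) == 3L)
  if (!all(distinct))
    return("proband/father/mother ids must be distinct within a family")
  if (!all(fam$sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  if (!all(fam$affected == "yes"))
    return("exactly one affected proband per family: 'affected' must be 'yes' for every proband row")
  TRUE
})

#' Table of trio variant records
#'
#' One row per (family, variant): proband/father/mother genotypes plus the
#' variant's annotation bundle (gene, functional class, population MAFs,
#' CADD/SIFT/PolyPhen, optional SpliceAI deltas, optional ClinVar assertion).
#' Absent annotation values are NA; NA never means zero.
#'
#' @slot records data.frame, see \code{variantRecords}.
#' @export
setClass("TrioVariantTable", representation(records = "data.frame"))

setValidity("TrioVariantTable", function(object) {
  rec <- object@records
  miss <- setdiff(.VARIANT_COLUMNS, names(rec))
  if (length(miss))
    return(paste("missing variant columns:", paste(miss, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (any(rec$pos < 1L)) return("pos must be >= 1")
  if (any(rec$ref == rec$alt)) return("alt allele must differ from ref")
  for (g in c("gt_proband", "gt_father", "gt_mother"))
    if (!all(rec[[g]] %in% GT_LEVELS))
      return(paste(g, "contains values outside", paste(GT_LEVELS, collapse = "/")))
  if (!all(is.na(rec$func_class) | rec$func_class %in% FUNC_CLASSES))
    return("unknown functional class")
  bounded <- c(paste0("maf_", MAF_DATABASES), "sift_score", "polyphen_score",
               "ds_ag", "ds_al", "ds_dg", "ds_dl")
  for (b in bounded)
    if (!.in01(rec[[b]])) return(paste(b, "must lie in [0, 1] or be NA"))
  if (!all(is.na(rec$cadd_phred) | rec$cadd_phred >= 0))
    return("cadd_phred must be non-negative or NA")
  TRUE
})

#' Cohort TPM expression matrix
#'
#' A \linkS4class{SummarizedExperiment} with a single "tpm" assay
#' (genes x samples, non-negative).
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!"tpm" %in% SummarizedExperiment::assayNames(object))
    return("assay 'tpm' is required")
  m <- SummarizedExperiment::assay(object, "tpm")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("gene and sample names are required")
  if (anyDuplicated(rownames(m))) return("duplicate gene symbols")
  if (anyDuplicated(colnames(m))) return("duplicate sample ids")
  if (any(!is.finite(m)) || any(m < 0)) return("TPM values must be finite and non-negative")
  TRUE
})

#' Split-read junction count table
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rowRanges are introns
#' (1-based inclusive; start = first intronic base = donor side, end = last
#' intronic base = acceptor side, stranded) and whose single "counts" assay
#' holds non-negative integer split-read counts per sample.
#' @export
setClass("JunctionTable", contains = "RangedSummarizedExperiment")

setValidity("JunctionTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    return("junction counts must be non-negative integers")
  rr <- SummarizedExperiment::rowRanges(object)
  if (any(GenomicRanges::start(rr) >= GenomicRanges::end(rr)))
    return("donor position must precede acceptor position")
  key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr),
               GenomicRanges::end(rr), GenomicRanges::strand(rr))
  if (anyDuplicated(key)) return("duplicate junction keys")
  if (is.null(colnames(m))) return("sample ids are required")
  if (anyDuplicated(colnames(m))) return("duplicate sample ids")
  TRUE
})

#' Named collection of gene sets
#'
#' @slot sets named list of character vectors of gene symbols (unique per set).
#' @slot description named character vector, one (possibly empty) description
#'   per set.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets) == 0L) return(TRUE)
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    return("every gene set must be named")
  if (anyDuplicated(names(object@sets))) return("duplicate gene-set names")
  if (any(lengths(object@sets) == 0L)) return("empty gene set")
  if (!identical(names(object@sets), names(object@description)))
    return("description names must match set names")
  TRUE
})

#' Gene-set x sample GSVA score matrix
#'
#' A \linkS4class{SummarizedExperiment} with a single "es" assay of
#' enrichment scores bounded in [-1, 1], carrying the scoring provenance
#' (kernel, tau, scoring mode, gene filter) in \code{metadata()$provenance}.
#' @export
setClass("GsvaScoreMatrix", contains = "SummarizedExperiment")

setValidity("GsvaScoreMatrix", function(object) {
  if (!"es" %in% SummarizedExperiment::assayNames(object))
    return("assay 'es' is required")
  m <- SummarizedExperiment::assay(object, "es")
  if (any(!is.finite(m))) return("scores must be finite")
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12))
    return("maxdiff-normalized scores must lie in [-1, 1]")
  if (is.null(metadata(object)$provenance))
    return("metadata()$provenance is required")
  TRUE
})

#' Registry of planted causal events in a synthetic cohort
#'
#' @slot planted_denovo data.frame: family_id, chrom, pos, ref, alt, gene,
#'   is_damaging.
#' @slot planted_expr_outliers data.frame: sample, gene, direction,
#'   magnitude (robust-z units).
#' @slot planted_splicing_shifts data.frame: sample, cluster_id, gene,
#'   usage_shift.
#' @slot planted_pathway_shifts data.frame: sample, set_name, direction.
#' @export
setClass("SyntheticTruth",
         representation(planted_denovo = "data.frame",
                        planted_expr_outliers = "data.frame",
                        planted_splicing_shifts = "data.frame",
                        planted_pathway_shifts = "data.frame"))

#' Synthetic cohort configuration
#'
#' Defaults are the study conditions the pipeline is exercised under:
#' 27 trios, sparse de novo variants, log-normal TPM noise, and
#' Dirichlet-multinomial junction counts. The seed is mandatory.
#' @export
setClass("CohortConfig", representation(
  n_trios = "integer",
  n_genes = "integer",
  n_gene_sets = "integer",
  genes_per_set = "integer",
  n_background_variants_per_trio = "integer",
  denovo_rate = "numeric",
  n_damaging_dnv = "integer",
  n_expr_outliers = "integer",
  expr_outlier_magnitude = "numeric",
  n_splicing_shifts = "integer",
  splicing_shift = "numeric",
  n_pathway_shifts = "integer",
  pathway_shift_log2 = "numeric",
  meanlog_range = "numeric",
  sdlog = "numeric",
  n_clusters = "integer",
  cluster_size = "integer",
  concentration = "numeric",
  junction_depth_mean = "numeric",
  junction_depth_size = "numeric",
  n_cp_genes = "integer",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  counts <- c(object@n_trios, object@n_genes, object@n_gene_sets,
              object@n_background_variants_per_trio, object@n_clusters,
              object@n_cp_genes)
  if (any(counts <= 0L)) return("all counts must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (object@denovo_rate < 0) return("denovo_rate must be >= 0")
  if (object@splicing_shift < 0 || object@splicing_shift >= 1)
    return("splicing_shift must lie in [0, 1)")
  if (object@n_trios < 6L)
    return("leave-one-out outlier detection needs at least 6 trios")
  TRUE
})

#' Assembled trio cohort
#'
#' Bundles every input the pipeline touches: pedigree, trio variant records,
#' expression, junction counts, gene sets and the curated CP-gene list, plus
#' (for synthetic cohorts) the truth registry of planted events.
#' @export
setClass("TrioCohort", representation(
  pedigree = "Pedigree",
  variants = "TrioVariantTable",
  expression = "ExpressionMatrix",
  junctions = "JunctionTable",
  gene_sets = "GeneSetCollection",
  cp_genes = "character",
  truth = "ANY"))

setValidity("TrioCohort", function(object) {
  fam <- object@pedigree@families
  rec <- object@variants@records
  if (nrow(rec) && !all(rec$family_id %in% fam$family_id))
    return("variant records reference unknown family ids")
  samp <- colnames(SummarizedExperiment::assay(object@expression, "tpm"))
  if (!all(samp %in% fam$proband_id))
    return("expression samples must be pedigree probands")
  jsamp <- colnames(SummarizedExperiment::assay(object@junctions, "counts"))
  if (!all(jsamp %in% fam$proband_id))
    return("junction samples must be pedigree probands")
  if (!is.null(object@truth) && !is(object@truth, "SyntheticTruth"))
    return("truth must be NULL or a SyntheticTruth")
  TRUE
})
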