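#' @include AllClasses.R AllGenerics.R denovo.R acmg.R expression-outliers.R
#' @include splicing-outliers.R gsva.R synthetic-cohort.R
NULL

#' Pipeline thresholds
#'
#' One auditable record of every threshold used in a run. Defaults are the
#' study values: CADD phred > 20, population frequency < 0.05 percent,
#' adjusted p < 0.05, Tukey fence multiplier 1.5.
#'
#' @param damaging see \code{\link{damagingFilterParams}}.
#' @param candidate see \code{\link{candidateFilterParams}}.
#' @param z_min,min_expression,expr_alpha expression-outlier thresholds.
#' @param splice_alpha,min_cluster_reads,min_sample_reads splicing-outlier
#'   thresholds.
#' @param gsva_tau,set_size_min,set_size_max GSVA parameters.
#' @param fence_k Tukey fence multiplier.
#' @param spliceai_reliable SpliceAI delta-score threshold above which a
#'   concordant DNA-level splicing prediction is reported as highly reliable.
#' @return named list of parameters for \code{\link{runPipeline}}.
#' @export
pipelineParams <- function(damaging = damagingFilterParams(),
                           candidate = candidateFilterParams(),
                           z_min = 3, min_expression = 1, expr_alpha = 0.05,
                           splice_alpha = 0.05, min_cluster_reads = 30,
                           min_sample_reads = 10,
                           gsva_tau = 1, set_size_min = 5, set_size_max = 500,
                           fence_k = 1.5, spliceai_reliable = 0.8) {
  list(damaging = damaging, candidate = candidate, z_min = z_min,
       min_expression = min_expression, expr_alpha = expr_alpha,
       splice_alpha = splice_alpha, min_cluster_reads = min_cluster_reads,
       min_sample_reads = min_sample_reads, gsva_tau = gsva_tau,
       set_size_min = set_size_min, set_size_max = set_size_max,
       fence_k = fence_k, spliceai_reliable = spliceai_reliable)
}

#' DNA x pathway cross-evidence links
#'
#' A link (proband, gene, set) is emitted when a proband has a damaging de
#' novo variant in a member gene of one of that same proband's outlier gene
#' sets — the automated form of spotting a de novo hit inside an aberrant
#' pathway.
#'
#' @param denovo_calls data.frame from \code{\link{screenDeNovo}}.
#' @param pathway_calls data.frame of pathway outlier calls
#'   (\code{\link{flagPathwayOutliers}}$calls).
#' @param gene_sets named list of member symbols.
#' @param pedigree a \linkS4class{Pedigree} (maps family ids to probands).
#' @return data.frame with columns proband, gene, set_name.
#' @export
crossLink <- function(denovo_calls, pathway_calls, gene_sets, pedigree) {
  fam <- families(pedigree)
  out <- list()
  if (nrow(denovo_calls) && nrow(pathway_calls)) {
    proband <- fam$proband_id[match(denovo_calls$family_id, fam$family_id)]
    for (i in seq_len(nrow(pathway_calls))) {
      members <- gene_sets[[pathway_calls$set_name[i]]]
      hit <- which(proband == pathway_calls$sample[i] &
                     denovo_calls$gene %in% members)
      for (h in hit)
        out[[length(out) + 1L]] <- data.frame(
          proband = proband[h], gene = denovo_calls$gene[h],
          set_name = pathway_calls$set_name[i], stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(proband = character(0), gene = character(0),
               set_name = character(0))
  rownames(res) <- NULL
  res
}

#' Run the integrated diagnostic pipeline on a cohort
#'
#' Executes every stage in order — damaging de novo screen and gene tally,
#' optional ACMG classification of a caller-supplied evidence table,
#' leave-one-out expression outliers, intron clustering and leave-one-out
#' splicing outliers (candidate set = CP genes plus damaging de novo genes),
#' GSVA scoring with Tukey-fence pathway outliers, and DNA x pathway
#' cross-evidence links — then assembles one report per proband. The run is
#' deterministic given the cohort and parameters.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param params see \code{\link{pipelineParams}}.
#' @param evidence_table optional data.frame (sample, gene, evidence) of
#'   ACMG evidence strings; clinical code assignment is an input, never
#'   computed.
#' @param gene_ranges \link[GenomicRanges]{GRanges} for cluster-to-gene
#'   assignment; defaults to the deterministic synthetic layout when the
#'   cohort carries a truth registry.
#' @param out_dir optional directory; every stage's TSV is written before
#'   the merged per-proband JSON reports.
#' @return list with stage artifacts (\code{denovo}, \code{gene_tally},
#'   \code{acmg}, \code{expression}, \code{splicing}, \code{gsva},
#'   \code{pathway}, \code{links}), per-proband \code{reports}, and a
#'   row-count \code{log}.
#' @export
runPipeline <- function(cohort, params = pipelineParams(),
                        evidence_table = NULL, gene_ranges = NULL,
                        out_dir = NULL) {
  fam <- families(cohort)
  if (is.null(gene_ranges) && !is.null(truthRegistry(cohort)))
    gene_ranges <- syntheticGeneRanges(nrow(cohort@expression))
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))

  denovo <- stage("denovo_screen", screenDeNovo(cohort, params$damaging))
  tally <- tallyGenes(denovo)

  acmg <- stage("acmg", if (!is.null(evidence_table))
    classifyCohort(evidence_table)
  else classifyCohort(data.frame(sample = character(0),
                                 gene = character(0),
                                 evidence = character(0))))

  expr <- stage("expression_outliers",
                callExpressionOutliers(cohortExpression(cohort),
                                       z_min = params$z_min,
                                       min_expression = params$min_expression,
                                       alpha = params$expr_alpha))

  candidate_genes <- unique(c(cpGenes(cohort), denovo$gene))
  spl <- stage("splicing_outliers",
               callSplicingOutliers(cohortJunctions(cohort),
                                    candidate_genes = candidate_genes,
                                    gene_ranges = gene_ranges,
                                    alpha = params$splice_alpha,
                                    min_cluster_reads = params$min_cluster_reads,
                                    min_sample_reads = params$min_sample_reads))

  gsva <- stage("pathway_gsva",
                gsvaScores(cohortExpression(cohort), cohort@gene_sets,
                           tau = params$gsva_tau,
                           min_size = params$set_size_min,
                           max_size = params$set_size_max))
  pathway <- flagPathwayOutliers(gsva, k = params$fence_k)

  links <- crossLink(denovo, pathway$calls, geneSets(cohort),
                     cohort@pedigree)

  proband_of <- stats::setNames(fam$proband_id, fam$family_id)
  reports <- lapply(seq_len(nrow(fam)), function(i) {
    pid <- fam$proband_id[i]
    dn <- denovo[denovo$family_id == fam$family_id[i], , drop = FALSE]
    dn$cp_gene <- dn$gene %in% cpGenes(cohort)
    list(proband = pid,
         plp_variants = acmg$classified[
           acmg$classified$sample == pid &
             acmg$classified$tier %in% c("pathogenic", "likely_pathogenic"), ,
           drop = FALSE],
         vus_variants = acmg$classified[
           acmg$classified$sample == pid &
             acmg$classified$tier == "uncertain_significance", , drop = FALSE],
         damaging_denovo = dn,
         expression_outliers = expr[expr$sample == pid, , drop = FALSE],
         splicing_outliers = spl$filtered[spl$filtered$sample == pid, ,
                                          drop = FALSE],
         pathway_outliers = pathway$calls[pathway$calls$sample == pid, ,
                                          drop = FALSE],
         cross_links = links[links$proband == pid, , drop = FALSE])
  })
  names(reports) <- fam$proband_id

  log <- list(n_trios = nrow(fam),
              n_variant_records = nrow(variantRecords(cohort)),
              n_damaging_denovo = nrow(denovo),
              n_denovo_genes = length(unique(denovo$gene)),
              n_expression_outliers = nrow(expr),
              n_splicing_tested = nrow(spl$all),
              n_splicing_calls = nrow(spl$filtered),
              n_gene_sets_scored = nrow(gsva),
              n_aberrant_sets = length(pathway$aberrant_sets),
              n_cross_links = nrow(links))

  out <- list(denovo = denovo, gene_tally = tally, acmg = acmg,
              expression = expr, splicing = spl, gsva = gsva,
              pathway = pathway, links = links, reports = reports,
              log = log)
  if (!is.null(out_dir)) .write_pipeline(out, out_dir, proband_of)
  out
}

.write_pipeline <- function(res, out_dir, proband_of) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$denovo, "denovo_calls.tsv")
  w(res$gene_tally, "gene_tally.tsv")
  w(res$acmg$classified, "acmg_classifications.tsv")
  w(res$expression, "expression_outliers.tsv")
  w(res$splicing$all, "splicing_tests.tsv")
  w(res$splicing$filtered, "splicing_outliers.tsv")
  w(data.frame(set_name = rownames(esMatrix(res$gsva)),
               esMatrix(res$gsva), check.names = FALSE), "gsva_scores.tsv")
  w(res$pathway$calls, "pathway_outliers.tsv")
  w(res$links, "cross_links.tsv")
  for (pid in names(res$reports))
    jsonlite::write_json(res$reports[[pid]],
                         file.path(out_dir, paste0("report_", pid, ".json")),
                         dataframe = "columns", digits = NA, pretty = TRUE,
                         auto_unbox = TRUE)
  jsonlite::write_json(res$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
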