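#' @include AllClasses.R AllGenerics.R
NULL

#' Damaging de novo filter parameters
#'
#' The filter keeps variants whose CADD phred score is strictly greater than
#' \code{cadd_min}, whose SIFT result is Deleterious, and whose PolyPhen-2
#' result is probably or possibly damaging. A required score that is absent
#' fails the filter.
#'
#' @param cadd_min CADD phred threshold, exclusive (default 20).
#' @param require_sift_deleterious require SIFT = deleterious (default TRUE).
#' @param polyphen_accept accepted PolyPhen-2 calls.
#' @return parameter list for \code{\link{isDamaging}} /
#'   \code{\link{screenDeNovo}}.
#' @export
damagingFilterParams <- function(cadd_min = 20,
                                 require_sift_deleterious = TRUE,
                                 polyphen_accept = c("probably_damaging",
                                                     "possibly_damaging")) {
  stopifnot(cadd_min >= 0)
  list(cadd_min = cadd_min,
       require_sift_deleterious = require_sift_deleterious,
       polyphen_accept = polyphen_accept)
}

#' De novo genotype pattern
#'
#' TRUE iff the proband is heterozygous or homozygous for the alternate
#' allele while both parents are confirmed wild-type homozygotes. A missing
#' genotype anywhere in the trio means the wild-type status is unconfirmed
#' and the variant is not called de novo.
#'
#' @param gt_proband,gt_father,gt_mother genotype vectors with values in
#'   \code{hom_ref}, \code{het}, \code{hom_alt}, \code{missing}.
#' @return logical vector.
#' @export
isDeNovo <- function(gt_proband, gt_father, gt_mother) {
  gt_proband %in% c("het", "hom_alt") &
    gt_father == "hom_ref" & gt_mother == "hom_ref"
}

#' Damaging-variant filter
#'
#' Vectorized over the rows of a variant record data.frame. The SIFT and
#' PolyPhen criteria use the categorical call when one is present (a given
#' call wins over its score; score-derived calls are filled in at annotation
#' time). Absence of any required score or call is failure, never a pass.
#'
#' @param records data.frame of variant records (see
#'   \code{\link{TrioVariantTable}}).
#' @param params see \code{\link{damagingFilterParams}}.
#' @return logical vector.
#' @export
isDamaging <- function(records, params = damagingFilterParams()) {
  cadd_ok <- !is.na(records$cadd_phred) & records$cadd_phred > params$cadd_min
  sift_ok <- if (params$require_sift_deleterious)
    !is.na(records$sift_call) & records$sift_call == "deleterious"
  else TRUE
  pp_ok <- !is.na(records$polyphen_call) &
    records$polyphen_call %in% params$polyphen_accept
  cadd_ok & sift_ok & pp_ok
}

#' Screen a cohort for damaging de novo variants
#'
#' @param x a \linkS4class{TrioCohort}, \linkS4class{TrioVariantTable} or a
#'   record data.frame.
#' @param params see \code{\link{damagingFilterParams}}.
#' @return data.frame of calls (records passing both the de novo genotype
#'   pattern and the damaging filter), ordered by (family, chrom, pos).
#' @export
screenDeNovo <- function(x, params = damagingFilterParams()) {
  rec <- if (is(x, "TrioCohort")) variantRecords(x)
         else if (is(x, "TrioVariantTable")) variantRecords(x)
         else x
  if (nrow(rec) == 0L) return(rec)
  keep <- isDeNovo(rec$gt_proband, rec$gt_father, rec$gt_mother) &
    isDamaging(rec, params)
  calls <- rec[keep, , drop = FALSE]
  calls <- calls[order(calls$family_id, calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Gene-level tallies of damaging de novo calls
#'
#' @param calls data.frame from \code{\link{screenDeNovo}}.
#' @return data.frame with one row per gene: \code{gene},
#'   \code{n_damaging_dnv} (total calls) and \code{n_probands} (distinct
#'   probands carrying at least one call in the gene), ordered by decreasing
#'   call count. Calls with no gene symbol are tallied under NA.
#' @export
tallyGenes <- function(calls) {
  if (nrow(calls) == 0L)
    return(data.frame(gene = character(0), n_damaging_dnv = integer(0),
                      n_probands = integer(0)))
  sp <- split(calls$family_id, calls$gene)
  out <- data.frame(gene = names(sp),
                    n_damaging_dnv = lengths(sp),
                    n_probands = vapply(sp, function(f)
                      length(unique(f)), integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_damaging_dnv, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recurrently hit genes
#'
#' Subsets a gene tally to genes with at least \code{min_count} damaging de
#' novo variants (\code{by = "variants"}) or hit in at least \code{min_count}
#' distinct probands (\code{by = "probands"}). The threshold is inclusive by
#' default (two or more).
#'
#' @param tally data.frame from \code{\link{tallyGenes}}.
#' @param min_count recurrence threshold (default 2).
#' @param by count variants or distinct probands.
#' @return subset of \code{tally}.
#' @export
recurrentGenes <- function(tally, min_count = 2L,
                           by = c("variants", "probands")) {
  by <- match.arg(by)
  col <- if (by == "variants") "n_damaging_dnv" else "n_probands"
  tally[tally[[col]] >= min_count, , drop = FALSE]
}
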