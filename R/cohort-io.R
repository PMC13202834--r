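#' @include AllClasses.R AllGenerics.R
NULL

# Standard file layout of a cohort directory (synthetic or user-assembled).
.COHORT_FILES <- c(vcf = "cohort.vcf", ped = "cohort.ped",
                   annotation = "annotations.tsv",
                   expression = "expression.tsv",
                   junctions = "junctions.tsv",
                   gmt = "gene_sets.gmt",
                   cp_genes = "cp_genes.txt",
                   truth = "truth.json")

# ---- pedigree --------------------------------------------------------------

#' Read a 6-column PED file into a Pedigree
#'
#' Standard PED columns: family, individual, father, mother, sex (1 male /
#' 2 female), phenotype (2 affected). One affected proband with both parents
#' present is required per family.
#'
#' @param path PED file path.
#' @return A \linkS4class{Pedigree}.
#' @export
readPedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "phenotype"))
  fams <- lapply(split(ped, ped$family), function(f) {
    pro <- f[f$phenotype == 2 & f$father != "0" & f$mother != "0", , drop = FALSE]
    if (nrow(pro) != 1L)
      stop("family ", f$family[1],
           ": exactly one affected proband with both parents is required")
    data.frame(family_id = pro$family, proband_id = pro$individual,
               father_id = pro$father, mother_id = pro$mother,
               sex = c("male", "female")[pro$sex], affected = "yes",
               stringsAsFactors = FALSE)
  })
  fam <- do.call(rbind, fams)
  rownames(fam) <- NULL
  Pedigree(fam[order(fam$family_id), , drop = FALSE])
}

writePedigree <- function(pedigree, path) {
  fam <- families(pedigree)
  rows <- do.call(rbind, lapply(seq_len(nrow(fam)), function(i) {
    f <- fam[i, ]
    rbind(c(f$family_id, f$father_id, "0", "0", 1, 1),
          c(f$family_id, f$mother_id, "0", "0", 2, 1),
          c(f$family_id, f$proband_id, f$father_id, f$mother_id,
            if (f$sex == "male") 1 else 2, 2))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- VCF trios -------------------------------------------------------------

# Classify a diploid GT string with respect to alt allele index `ai`
# (1-based among the site's ALT alleles). Anything unparseable is missing.
.gt_class <- function(gt, ai) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) == 1L) alleles <- c(alleles, alleles)  # hemizygous
  if (length(alleles) != 2L || any(!grepl("^[0-9.]+$", alleles)))
    return("missing")
  if (any(alleles == ".")) return("missing")
  n_alt <- sum(alleles == as.character(ai))
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

#' Read a multi-sample VCF into per-family trio variant records
#'
#' Emits one record per family x (decomposed, bi-allelic) variant at which
#' the trio carries any genotype other than homozygous reference.
#' Multi-allelic sites are decomposed into one record per alternate allele;
#' genotypes involving a different alternate allele at the same site count
#' toward that allele's record only. Malformed genotypes are flagged
#' \code{missing} (never silently reference).
#'
#' @param vcf_path VCF 4.x file (genotypes only; INFO is ignored).
#' @param pedigree a \linkS4class{Pedigree}; every referenced sample must
#'   have a genotype column.
#' @return A \linkS4class{TrioVariantTable} with annotation columns NA
#'   (attach with \code{\link{annotateRecords}}), ordered by
#'   (family, chrom, pos).
#' @export
readVcfTrios <- function(vcf_path, pedigree) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  fam <- families(pedigree)
  ids <- unique(c(fam$proband_id, fam$father_id, fam$mother_id))
  absent <- setdiff(ids, colnames(gt))
  if (length(absent))
    stop("sample column missing from VCF: ", paste(absent, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  out <- vector("list", 0L)
  for (v in seq_len(nrow(gt))) {
    alts <- as.character(alt_list[[v]])
    for (ai in seq_along(alts)) {
      if (alts[ai] == ref[v] || !nzchar(alts[ai])) next
      for (f in seq_len(nrow(fam))) {
        trio <- c(gt[v, fam$proband_id[f]], gt[v, fam$father_id[f]],
                  gt[v, fam$mother_id[f]])
        cls <- vapply(trio, .gt_class, character(1), ai = ai)
        if (all(cls == "hom_ref")) next
        out[[length(out) + 1L]] <- data.frame(
          family_id = fam$family_id[f], chrom = chrom[v], pos = pos[v],
          ref = ref[v], alt = alts[ai],
          gt_proband = cls[1], gt_father = cls[2], gt_mother = cls[3],
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (length(out)) do.call(rbind, out) else NULL
  tvt <- TrioVariantTable(rec)
  r <- tvt@records
  tvt@records <- r[order(r$family_id, r$chrom, r$pos), , drop = FALSE]
  rownames(tvt@records) <- NULL
  tvt
}

# ---- annotation ------------------------------------------------------------

.ANNOT_NUMERIC <- c(paste0("maf_", MAF_DATABASES), "cadd_phred",
                    "sift_score", "polyphen_score",
                    "ds_ag", "ds_al", "ds_dg", "ds_dl")

# SIFT/PolyPhen categorical calls derived from scores when only the score is
# given (standard cutoffs: SIFT <= 0.05 deleterious; PolyPhen HumDiv >= 0.909
# probably damaging, >= 0.447 possibly damaging). A given call always wins
# over its score.
.derive_calls <- function(df) {
  need_sift <- is.na(df$sift_call) & !is.na(df$sift_score)
  df$sift_call[need_sift] <-
    ifelse(df$sift_score[need_sift] <= 0.05, "deleterious", "tolerated")
  need_pp <- is.na(df$polyphen_call) & !is.na(df$polyphen_score)
  df$polyphen_call[need_pp] <- ifelse(
    df$polyphen_score[need_pp] >= 0.909, "probably_damaging",
    ifelse(df$polyphen_score[need_pp] >= 0.447, "possibly_damaging", "benign"))
  df
}

#' Read an ANNOVAR-style per-variant annotation table
#'
#' TSV keyed by (chrom, pos, ref, alt) with gene symbol, functional class,
#' per-database population frequencies, CADD phred, SIFT, PolyPhen-2,
#' optional SpliceAI delta scores and an optional ClinVar assertion. Empty or
#' unparseable numeric cells become NA with a warning; NA means absent, never
#' zero. Categorical SIFT/PolyPhen calls missing from the table are derived
#' from the scores.
#'
#' @param path TSV with a header row.
#' @return data.frame keyed by (chrom, pos, ref, alt).
#' @export
readAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", "", "."),
                          colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("annotation table must contain columns: ", paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  for (col in intersect(.ANNOT_NUMERIC, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      warning(sum(bad), " unparseable value(s) in column '", col,
              "' set to NA")
    df[[col]] <- num
  }
  for (col in setdiff(c("gene", "func_class", "sift_call", "polyphen_call",
                        "clinvar"), names(df)))
    df[[col]] <- NA_character_
  for (col in setdiff(.ANNOT_NUMERIC, names(df)))
    df[[col]] <- NA_real_
  .derive_calls(df)
}

#' Attach annotations to trio variant records
#'
#' @param tvt a \linkS4class{TrioVariantTable}.
#' @param annotation data.frame from \code{\link{readAnnotation}}.
#' @return the table with annotation columns filled by (chrom, pos, ref, alt)
#'   key; unannotated records keep NA.
#' @export
annotateRecords <- function(tvt, annotation) {
  rec <- tvt@records
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  idx <- match(key(rec), key(annotation))
  cols <- c("gene", "func_class", paste0("maf_", MAF_DATABASES),
            "cadd_phred", "sift_score", "sift_call",
            "polyphen_score", "polyphen_call",
            "ds_ag", "ds_al", "ds_dg", "ds_dl", "clinvar")
  for (col in cols) rec[[col]] <- annotation[[col]][idx]
  tvt@records <- rec
  methods::validObject(tvt)
  tvt
}

# ---- matrices --------------------------------------------------------------

#' Read a TPM expression matrix
#'
#' TSV with a header row of sample ids and a leading \code{gene} column.
#'
#' @param path TSV path.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- df$gene
  ExpressionMatrix(m)
}

#' Write a TPM expression matrix
#' @param em an \linkS4class{ExpressionMatrix}.
#' @param path output TSV path.
#' @export
writeExpression <- function(em, path) {
  m <- tpm(em)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junction count table
#'
#' TSV layout: chrom, start, end, strand, then one count column per sample.
#' Coordinates are 1-based inclusive intron positions (start = donor side,
#' end = acceptor side).
#'
#' @param path TSV path.
#' @return A \linkS4class{JunctionTable}.
#' @export
readJunctions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "strand")
  if (!identical(names(df)[1:4], need))
    stop("junction table must start with columns: ",
         paste(need, collapse = ", "))
  cnt <- as.matrix(df[, -(1:4), drop = FALSE])
  if (!is.numeric(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("junction counts must be non-negative integers")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  JunctionTable(cnt, gr)
}

#' Write a junction count table
#' @param jt a \linkS4class{JunctionTable}.
#' @param path output TSV path.
#' @export
writeJunctions <- function(jt, path) {
  rr <- SummarizedExperiment::rowRanges(jt)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                   start = GenomicRanges::start(rr),
                   end = GenomicRanges::end(rr),
                   strand = as.character(GenomicRanges::strand(rr)),
                   junctionCounts(jt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene sets and lists ---------------------------------------------------

#' Read a GMT gene-set file
#'
#' Tab-separated MSigDB dialect: set name, description, then member symbols.
#' Duplicate member symbols within a set are removed; duplicate set names and
#' lines with fewer than three fields are errors.
#'
#' @param path GMT path.
#' @return A \linkS4class{GeneSetCollection}, input order preserved.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  GeneSetCollection(sets, vapply(fields, `[[`, character(1), 2L))
}

#' Write a GMT gene-set file
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @export
writeGmt <- function(gsc, path) {
  lines <- vapply(names(gsc@sets), function(nm)
    paste(c(nm, gsc@description[[nm]], gsc@sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one symbol per line)
#' @param path file path.
#' @return character vector of unique symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Read gene intervals from a BED file
#'
#' Used to assign intron clusters to genes by overlap.
#'
#' @param path BED path; the name column holds the gene symbol.
#' @return \link[GenomicRanges]{GRanges} with a \code{gene} metadata column.
#' @export
readGeneRanges <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::mcols(gr)$gene <- GenomicRanges::mcols(gr)$name
  gr
}

# ---- cohort assembly -------------------------------------------------------

#' Read and validate a cohort directory
#'
#' Expects the standard layout written by \code{\link{writeCohort}}:
#' \code{cohort.vcf}, \code{cohort.ped}, \code{annotations.tsv},
#' \code{expression.tsv}, \code{junctions.tsv}, \code{gene_sets.gmt},
#' \code{cp_genes.txt} and, for synthetic cohorts, \code{truth.json}.
#'
#' @param dir cohort directory.
#' @return A validated \linkS4class{TrioCohort}.
#' @export
readCohort <- function(dir) {
  p <- function(f) file.path(dir, .COHORT_FILES[[f]])
  ped <- readPedigree(p("ped"))
  tvt <- annotateRecords(readVcfTrios(p("vcf"), ped), readAnnotation(p("annotation")))
  truth <- if (file.exists(p("truth"))) .read_truth(p("truth")) else NULL
  cohort <- new("TrioCohort",
                pedigree = ped, variants = tvt,
                expression = readExpression(p("expression")),
                junctions = readJunctions(p("junctions")),
                gene_sets = readGmt(p("gmt")),
                cp_genes = readGeneList(p("cp_genes")),
                truth = truth)
  methods::validObject(cohort)
  cohort
}

.read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asdf <- function(d) if (is.null(d) || length(d) == 0L) data.frame() else as.data.frame(d)
  SyntheticTruth(asdf(x$planted_denovo), asdf(x$planted_expr_outliers),
                 asdf(x$planted_splicing_shifts), asdf(x$planted_pathway_shifts))
}
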