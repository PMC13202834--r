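#' @include AllClasses.R AllGenerics.R cohort-io.R
NULL

#' Synthetic-cohort configuration
#'
#' The defaults are the study conditions the pipeline is exercised under: 27
#' trios; sparse background variation with a low de novo rate; heavy-tailed
#' per-gene log-normal TPM noise; overdispersed Dirichlet-multinomial
#' junction counts; and planted causal events (damaging de novo variants,
#' expression outliers in robust-z units, cluster usage shifts, pathway-wide
#' expression offsets) recorded in a truth registry.
#'
#' @param n_trios number of trio families (default 27).
#' @param n_genes expression/annotation gene universe size (default 600).
#' @param n_gene_sets,genes_per_set gene-set collection shape (default 40
#'   sets of 10-30 genes).
#' @param n_background_variants_per_trio inherited variants per trio
#'   (default 60).
#' @param denovo_rate expected background (non-damaging) de novo variants
#'   per trio, Poisson (default 2).
#' @param n_damaging_dnv planted damaging de novo variants cohort-wide
#'   (default 12).
#' @param n_expr_outliers planted expression outliers (default 10).
#' @param expr_outlier_magnitude magnitude range in robust-z units
#'   (default 5-8).
#' @param n_splicing_shifts planted cluster usage shifts (default 8).
#' @param splicing_shift usage fraction moved from the major to a minor
#'   junction (default 0.4).
#' @param n_pathway_shifts planted pathway shifts (default 4).
#' @param pathway_shift_log2 common log2 offset applied to a set's member
#'   genes in the target sample (default 2).
#' @param meanlog_range,sdlog per-gene log-normal TPM model: meanlog drawn
#'   uniformly from \code{meanlog_range} (natural log), common
#'   \code{sdlog} (defaults 0-5 and 0.4).
#' @param n_clusters,cluster_size intron clusters and junctions per cluster
#'   (defaults 40 clusters of 2-4 junctions).
#' @param concentration Dirichlet-multinomial concentration (default 50).
#' @param junction_depth_mean,junction_depth_size negative-binomial
#'   per-sample cluster depth (defaults mean 200, size 5; floored at 10
#'   reads).
#' @param n_cp_genes size of the curated CP-gene list (default 30).
#' @param seed mandatory integer seed; one global seed drives four named
#'   substreams (genotype, annotation, expression, splicing).
#' @return A validated \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(n_trios = 27L, n_genes = 600L, n_gene_sets = 40L,
                         genes_per_set = c(10L, 30L),
                         n_background_variants_per_trio = 60L,
                         denovo_rate = 2,
                         n_damaging_dnv = 12L,
                         n_expr_outliers = 10L,
                         expr_outlier_magnitude = c(5, 8),
                         n_splicing_shifts = 8L,
                         splicing_shift = 0.4,
                         n_pathway_shifts = 4L,
                         pathway_shift_log2 = 2,
                         meanlog_range = c(0, 5), sdlog = 0.4,
                         n_clusters = 40L, cluster_size = c(2L, 4L),
                         concentration = 50,
                         junction_depth_mean = 200,
                         junction_depth_size = 5,
                         n_cp_genes = 30L,
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- new("CohortConfig",
             n_trios = as.integer(n_trios), n_genes = as.integer(n_genes),
             n_gene_sets = as.integer(n_gene_sets),
             genes_per_set = as.integer(genes_per_set),
             n_background_variants_per_trio =
               as.integer(n_background_variants_per_trio),
             denovo_rate = denovo_rate,
             n_damaging_dnv = as.integer(n_damaging_dnv),
             n_expr_outliers = as.integer(n_expr_outliers),
             expr_outlier_magnitude = expr_outlier_magnitude,
             n_splicing_shifts = as.integer(n_splicing_shifts),
             splicing_shift = splicing_shift,
             n_pathway_shifts = as.integer(n_pathway_shifts),
             pathway_shift_log2 = pathway_shift_log2,
             meanlog_range = meanlog_range, sdlog = sdlog,
             n_clusters = as.integer(n_clusters),
             cluster_size = as.integer(cluster_size),
             concentration = concentration,
             junction_depth_mean = junction_depth_mean,
             junction_depth_size = junction_depth_size,
             n_cp_genes = as.integer(n_cp_genes),
             seed = as.integer(seed))
  methods::validObject(cfg)
  cfg
}

#' Deterministic genomic layout of the synthetic gene universe
#'
#' Gene i occupies a fixed 20 kb interval cycling over chr1-chr22, so that
#' junction coordinates and gene assignment are reproducible from the gene
#' count alone.
#'
#' @param n_genes number of genes.
#' @return \link[GenomicRanges]{GRanges} with a \code{gene} metadata column.
#' @export
syntheticGeneRanges <- function(n_genes) {
  i <- seq_len(n_genes)
  chrom <- paste0("chr", (i - 1L) %% 22L + 1L)
  start <- 1e6 + ((i - 1L) %/% 22L) * 1e5
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + 2e4 - 1))
  GenomicRanges::mcols(gr)$gene <- sprintf("G%04d", i)
  gr
}

.rdirichlet <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }

# draw a unique (chrom, pos) inside the given gene's interval
.draw_pos <- function(gene_idx, ranges, used) {
  repeat {
    pos <- GenomicRanges::start(ranges)[gene_idx] +
      sample.int(2e4, 1L) - 1L
    key <- paste0(gene_idx, ":", pos)
    if (is.null(used[[key]])) { used[[key]] <- TRUE; return(pos) }
  }
}

.draw_alleles <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1L)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  c(ref, alt)
}

#' Generate a synthetic trio cohort with a truth registry
#'
#' Deterministic for a fixed seed. Planted de novo variants satisfy the trio
#' genotype pattern (proband het/hom_alt, both parents hom_ref) and carry
#' annotation scores drawn to pass or fail the damaging filter according to
#' their registered \code{is_damaging} flag. Inherited variants always have
#' the alternate allele in at least one parent. Expression outliers are
#' injected on the log2(TPM + 1) scale at an exact leave-one-out robust-z
#' magnitude; splicing shifts move a usage fraction from a cluster's major
#' to its least-used junction in the target sample; pathway shifts add a
#' common log2 offset to a set's member genes in the target sample.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A \linkS4class{TrioCohort} with its \linkS4class{SyntheticTruth}
#'   attached.
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  substream <- sample.int(2147483646L, 4L)

  S <- config@n_trios
  genes <- sprintf("G%04d", seq_len(config@n_genes))
  gene_ranges <- syntheticGeneRanges(config@n_genes)
  fam <- data.frame(
    family_id = sprintf("FAM%03d", seq_len(S)),
    proband_id = sprintf("P%03d", seq_len(S)),
    father_id = sprintf("F%03d", seq_len(S)),
    mother_id = sprintf("M%03d", seq_len(S)),
    sex = rep_len(c("male", "female"), S), affected = "yes",
    stringsAsFactors = FALSE)
  ped <- Pedigree(fam)

  # ---- genotype substream --------------------------------------------------
  set.seed(substream[1])
  used <- new.env(parent = emptyenv())
  rows <- list()
  truth_dnv <- list()
  add_row <- function(fid, gidx, gt) {
    pos <- .draw_pos(gidx, gene_ranges, used)
    al <- .draw_alleles()
    data.frame(family_id = fid,
               chrom = as.character(GenomicRanges::seqnames(gene_ranges))[gidx],
               pos = pos, ref = al[1], alt = al[2],
               gt_proband = gt[1], gt_father = gt[2], gt_mother = gt[3],
               gene = genes[gidx], stringsAsFactors = FALSE)
  }
  for (f in seq_len(S)) {
    fid <- fam$family_id[f]
    # inherited background: carrier parent het, proband inherits with p 0.5
    for (b in seq_len(config@n_background_variants_per_trio)) {
      gidx <- sample.int(config@n_genes, 1L)
      from_father <- stats::runif(1) < 0.5
      inherits <- stats::runif(1) < 0.5
      gt <- c(if (inherits) "het" else "hom_ref",
              if (from_father) "het" else "hom_ref",
              if (from_father) "hom_ref" else "het")
      rows[[length(rows) + 1L]] <- add_row(fid, gidx, gt)
    }
    # background (non-damaging) de novos
    for (b in seq_len(stats::rpois(1L, config@denovo_rate))) {
      gidx <- sample.int(config@n_genes, 1L)
      r <- add_row(fid, gidx, c("het", "hom_ref", "hom_ref"))
      rows[[length(rows) + 1L]] <- r
      truth_dnv[[length(truth_dnv) + 1L]] <-
        cbind(r[, c("family_id", "chrom", "pos", "ref", "alt", "gene")],
              is_damaging = FALSE)
    }
  }
  # planted damaging de novos, trios assigned round-robin
  dnv_fam <- rep_len(seq_len(S), config@n_damaging_dnv)
  for (k in seq_len(config@n_damaging_dnv)) {
    gidx <- sample.int(config@n_genes, 1L)
    zyg <- if (stats::runif(1) < 0.9) "het" else "hom_alt"
    r <- add_row(fam$family_id[dnv_fam[k]], gidx, c(zyg, "hom_ref", "hom_ref"))
    rows[[length(rows) + 1L]] <- r
    truth_dnv[[length(truth_dnv) + 1L]] <-
      cbind(r[, c("family_id", "chrom", "pos", "ref", "alt", "gene")],
            is_damaging = TRUE)
  }
  rec <- do.call(rbind, rows)
  truth_dnv <- if (length(truth_dnv)) do.call(rbind, truth_dnv) else
    data.frame(family_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               gene = character(0), is_damaging = logical(0))
  rownames(truth_dnv) <- NULL

  # ---- annotation substream ------------------------------------------------
  set.seed(substream[2])
  n <- nrow(rec)
  key <- paste(rec$family_id, rec$chrom, rec$pos)
  damaging_key <- paste(truth_dnv$family_id, truth_dnv$chrom, truth_dnv$pos)
  is_planted_damaging <- key %in% damaging_key[truth_dnv$is_damaging]
  is_background_dnv <- key %in% damaging_key[!truth_dnv$is_damaging]
  func_pool <- c("missense", "synonymous", "intronic", "splice", "other")
  rec$func_class <- sample(func_pool, n, replace = TRUE,
                           prob = c(0.35, 0.25, 0.25, 0.05, 0.10))
  rec$cadd_phred <- stats::runif(n, 0, 35)
  rec$sift_score <- stats::runif(n)
  rec$polyphen_score <- stats::runif(n)
  for (db in paste0("maf_", MAF_DATABASES)) {
    rec[[db]] <- ifelse(stats::runif(n) < 0.4, stats::runif(n, 0, 0.01),
                        NA_real_)
  }
  # background de novos must fail the damaging filter on CADD alone
  rec$cadd_phred[is_background_dnv] <- stats::runif(sum(is_background_dnv), 0, 18)
  # planted damaging de novos pass every criterion exactly
  np <- sum(is_planted_damaging)
  rec$func_class[is_planted_damaging] <- "missense"
  rec$cadd_phred[is_planted_damaging] <- stats::runif(np, 25, 40)
  rec$sift_score[is_planted_damaging] <- stats::runif(np, 0, 0.03)
  rec$polyphen_score[is_planted_damaging] <- stats::runif(np, 0.92, 0.999)
  for (db in paste0("maf_", MAF_DATABASES))
    rec[[db]][is_planted_damaging] <- NA_real_
  rec$sift_call <- NA_character_
  rec$polyphen_call <- NA_character_
  rec$ds_ag <- NA_real_; rec$ds_al <- NA_real_
  rec$ds_dg <- NA_real_; rec$ds_dl <- NA_real_
  rec$clinvar <- NA_character_
  rec <- .derive_calls(rec)
  cp_genes <- sort(unique(c(
    sample(genes, config@n_cp_genes),
    truth_dnv$gene[truth_dnv$is_damaging][seq_len(min(3L, sum(truth_dnv$is_damaging)))])))

  tvt <- TrioVariantTable(rec)
  o <- order(tvt@records$family_id, tvt@records$chrom, tvt@records$pos)
  tvt@records <- tvt@records[o, , drop = FALSE]
  rownames(tvt@records) <- NULL

  # ---- expression substream ------------------------------------------------
  set.seed(substream[3])
  meanlog <- stats::runif(config@n_genes, config@meanlog_range[1],
                          config@meanlog_range[2])
  tpm_m <- matrix(stats::rlnorm(config@n_genes * S,
                                meanlog = rep(meanlog, S),
                                sdlog = config@sdlog),
                  nrow = config@n_genes, ncol = S,
                  dimnames = list(genes, fam$proband_id))
  # gene sets
  set_sizes <- sample(seq(config@genes_per_set[1], config@genes_per_set[2]),
                      config@n_gene_sets, replace = TRUE)
  sets <- lapply(set_sizes, function(sz) sample(genes, sz))
  names(sets) <- sprintf("SET_%02d", seq_len(config@n_gene_sets))
  # couple the first planted damaging de novo gene into the first set so a
  # pathway shift there yields a DNA x pathway cross-evidence event
  first_dnv <- which(truth_dnv$is_damaging)[1]
  if (config@n_pathway_shifts > 0L && !is.na(first_dnv))
    sets[[1]] <- unique(c(sets[[1]], truth_dnv$gene[first_dnv]))
  gsc <- GeneSetCollection(sets, rep("synthetic gene set", length(sets)))

  # pathway shifts
  truth_pw <- data.frame(sample = character(0), set_name = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
  if (config@n_pathway_shifts > 0L) {
    if (config@n_pathway_shifts > config@n_gene_sets)
      stop("more pathway shifts requested than gene sets available")
    pw_sets <- names(sets)[seq_len(config@n_pathway_shifts)]
    pw_samples <- c(
      if (!is.na(first_dnv)) fam$proband_id[match(truth_dnv$family_id[first_dnv],
                                                  fam$family_id)],
      sample(fam$proband_id, config@n_pathway_shifts))[seq_len(config@n_pathway_shifts)]
    pw_dir <- c("up", sample(c("up", "down"), config@n_pathway_shifts,
                             replace = TRUE))[seq_len(config@n_pathway_shifts)]
    for (k in seq_len(config@n_pathway_shifts)) {
      members <- sets[[pw_sets[k]]]
      off <- config@pathway_shift_log2 * if (pw_dir[k] == "up") 1 else -1
      lv <- log2(tpm_m[members, pw_samples[k]] + 1) + off
      tpm_m[members, pw_samples[k]] <- pmax(2^lv - 1, 0)
    }
    truth_pw <- data.frame(sample = pw_samples, set_name = pw_sets,
                           direction = pw_dir, stringsAsFactors = FALSE)
  }

  # expression outliers at exact leave-one-out robust-z magnitude
  truth_expr <- data.frame(sample = character(0), gene = character(0),
                           direction = character(0), magnitude = numeric(0),
                           stringsAsFactors = FALSE)
  if (config@n_expr_outliers > 0L) {
    shifted_genes <- unique(unlist(sets[unique(truth_pw$set_name)]))
    eligible_dn <- setdiff(genes[meanlog >= 3.5], shifted_genes)
    eligible_up <- setdiff(genes[meanlog >= 1.0], shifted_genes)
    if (length(eligible_dn) + length(eligible_up) < config@n_expr_outliers)
      stop("more expression outliers requested than eligible gene slots")
    dir <- sample(c("up", "down"), config@n_expr_outliers, replace = TRUE)
    g_dn <- sample(eligible_dn, sum(dir == "down"))
    g_up <- sample(setdiff(eligible_up, g_dn), sum(dir == "up"))
    og <- character(config@n_expr_outliers)
    og[dir == "down"] <- g_dn; og[dir == "up"] <- g_up
    os <- sample(fam$proband_id, config@n_expr_outliers, replace = TRUE)
    mag <- stats::runif(config@n_expr_outliers,
                        config@expr_outlier_magnitude[1],
                        config@expr_outlier_magnitude[2])
    for (k in seq_len(config@n_expr_outliers)) {
      ref <- log2(tpm_m[og[k], colnames(tpm_m) != os[k]] + 1)
      med <- stats::median(ref)
      mad_ref <- stats::median(abs(ref - med))
      lv <- med + (if (dir[k] == "up") 1 else -1) * mag[k] * 1.4826 * mad_ref
      tpm_m[og[k], os[k]] <- max(2^lv - 1, 0)
    }
    truth_expr <- data.frame(sample = os, gene = og, direction = dir,
                             magnitude = mag, stringsAsFactors = FALSE)
  }
  em <- ExpressionMatrix(tpm_m)

  # ---- splicing substream --------------------------------------------------
  set.seed(substream[4])
  cl_genes <- sample.int(config@n_genes, config@n_clusters)
  cl_sizes <- sample(seq(config@cluster_size[1], config@cluster_size[2]),
                     config@n_clusters, replace = TRUE)
  base_p <- lapply(cl_sizes, function(J) .rdirichlet(rep(2, J)))
  jx <- list(); cl_of_row <- integer(0)
  for (k in seq_len(config@n_clusters)) {
    gstart <- GenomicRanges::start(gene_ranges)[cl_genes[k]]
    donor <- gstart + 1000L
    acceptors <- donor + 300L * seq_len(cl_sizes[k])
    jx[[k]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gene_ranges))[cl_genes[k]],
      start = donor, end = acceptors, strand = "+",
      stringsAsFactors = FALSE)
    cl_of_row <- c(cl_of_row, rep(k, cl_sizes[k]))
  }
  jdf <- do.call(rbind, jx)
  truth_spl <- data.frame(sample = character(0), cluster_id = character(0),
                          gene = character(0), usage_shift = numeric(0),
                          stringsAsFactors = FALSE)
  shift_of <- rep(NA_integer_, config@n_clusters)  # sample index shifted
  if (config@n_splicing_shifts > 0L) {
    eligible <- which(vapply(base_p, max, numeric(1)) >=
                        config@splicing_shift + 0.15)
    if (length(eligible) < config@n_splicing_shifts)
      stop("more splicing shifts requested than eligible cluster slots")
    sh_cl <- sample(eligible, config@n_splicing_shifts)
    sh_sm <- sample.int(S, config@n_splicing_shifts, replace = TRUE)
    shift_of[sh_cl] <- sh_sm
  }
  cnt <- matrix(0L, nrow(jdf), S,
                dimnames = list(NULL, fam$proband_id))
  for (k in seq_len(config@n_clusters)) {
    J <- cl_sizes[k]
    depth <- stats::rnbinom(S, mu = config@junction_depth_mean,
                            size = config@junction_depth_size)
    depth[depth < 10] <- 10L
    p <- base_p[[k]]
    rows_k <- which(cl_of_row == k)
    for (s in seq_len(S)) {
      ps <- p
      if (!is.na(shift_of[k]) && shift_of[k] == s) {
        major <- which.max(p); minor <- which.min(p)
        ps[major] <- ps[major] - config@splicing_shift
        ps[minor] <- ps[minor] + config@splicing_shift
      }
      cnt[rows_k, s] <- stats::rmultinom(1L, depth[s],
                                         .rdirichlet(config@concentration * ps))
    }
  }
  gr <- GenomicRanges::GRanges(jdf$chrom, IRanges::IRanges(jdf$start, jdf$end),
                               strand = jdf$strand)
  jt <- JunctionTable(cnt, gr)
  # cluster ids as buildClusters will name them, for the truth registry
  cl_map <- buildClusters(jt, min_cluster_reads = 0, gene_ranges = gene_ranges)
  if (config@n_splicing_shifts > 0L) {
    sh <- which(!is.na(shift_of))
    truth_spl <- data.frame(
      sample = fam$proband_id[shift_of[sh]],
      cluster_id = vapply(sh, function(k)
        cl_map$cluster_id[match(which(cl_of_row == k)[1], cl_map$junction)],
        character(1)),
      gene = genes[cl_genes[sh]],
      usage_shift = config@splicing_shift, stringsAsFactors = FALSE)
  }

  # keep at least one planted splicing shift inside the curated CP-gene list
  # so the candidate-intersection path is exercised end to end
  if (nrow(truth_spl)) cp_genes <- sort(unique(c(cp_genes, truth_spl$gene[1])))

  truth <- SyntheticTruth(truth_dnv, truth_expr, truth_spl, truth_pw)
  cohort <- new("TrioCohort", pedigree = ped, variants = tvt,
                expression = em, junctions = jt, gene_sets = gsc,
                cp_genes = cp_genes, truth = truth)
  methods::validObject(cohort)
  cohort
}

# ---- writing ---------------------------------------------------------------

.gt_string <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")

.write_vcf <- function(cohort, path) {
  fam <- families(cohort)
  rec <- variantRecords(cohort)
  ids <- as.vector(t(as.matrix(fam[, c("father_id", "mother_id",
                                       "proband_id")])))
  # one line per unique site; genotypes default hom_ref outside the
  # record's own family
  site_key <- paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":")
  sites <- rec[!duplicated(site_key), c("chrom", "pos", "ref", "alt")]
  o <- order(sites$chrom, sites$pos, sites$alt)
  sites <- sites[o, , drop = FALSE]
  gt <- matrix("0/0", nrow(sites), length(ids),
               dimnames = list(NULL, ids))
  srow <- match(paste(rec$chrom, rec$pos, rec$ref, rec$alt, sep = ":"),
                paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":"))
  fi <- match(rec$family_id, fam$family_id)
  gt[cbind(srow, match(fam$proband_id[fi], ids))] <- .gt_string[rec$gt_proband]
  gt[cbind(srow, match(fam$father_id[fi], ids))] <- .gt_string[rec$gt_father]
  gt[cbind(srow, match(fam$mother_id[fi], ids))] <- .gt_string[rec$gt_mother]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

.write_annotation <- function(cohort, path) {
  rec <- variantRecords(cohort)
  cols <- c("chrom", "pos", "ref", "alt", "gene", "func_class",
            paste0("maf_", MAF_DATABASES), "cadd_phred",
            "sift_score", "sift_call", "polyphen_score", "polyphen_call",
            "ds_ag", "ds_al", "ds_dg", "ds_dl", "clinvar")
  ann <- rec[!duplicated(paste(rec$chrom, rec$pos, rec$ref, rec$alt)), cols]
  ann <- ann[order(ann$chrom, ann$pos, ann$alt), , drop = FALSE]
  num <- vapply(ann, is.numeric, logical(1))
  ann[num] <- lapply(ann[num], function(x) ifelse(is.na(x), NA,
                                                  format(x, digits = 15,
                                                         scientific = FALSE,
                                                         trim = TRUE)))
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(planted_denovo = truth@planted_denovo,
         planted_expr_outliers = truth@planted_expr_outliers,
         planted_splicing_shifts = truth@planted_splicing_shifts,
         planted_pathway_shifts = truth@planted_pathway_shifts),
    path, dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a cohort directory
#'
#' Emits the standard 8-file layout (VCF, PED, annotation/expression/junction
#' TSVs, GMT, CP-gene list, truth JSON) and returns a manifest of every file
#' with its MD5 checksum.
#'
#' @param cohort a \linkS4class{TrioCohort}.
#' @param out_dir output directory; must be empty or absent unless
#'   \code{overwrite}.
#' @param overwrite allow writing into a non-empty directory.
#' @return data.frame manifest (file, md5), invisibly.
#' @export
writeCohort <- function(cohort, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, .COHORT_FILES[[f]])
  .write_vcf(cohort, p("vcf"))
  writePedigree(cohort@pedigree, p("ped"))
  .write_annotation(cohort, p("annotation"))
  writeExpression(cohort@expression, p("expression"))
  writeJunctions(cohort@junctions, p("junctions"))
  writeGmt(cohort@gene_sets, p("gmt"))
  writeLines(cpGenes(cohort), p("cp_genes"))
  if (!is.null(cohort@truth)) .write_truth(cohort@truth, p("truth"))
  files <- file.path(out_dir, intersect(.COHORT_FILES,
                                        list.files(out_dir)))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}
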