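#' @include AllClasses.R AllGenerics.R stats-core.R
NULL

# ---- intron clustering -----------------------------------------------------

#' Build intron clusters from junction counts
#'
#' Junctions on the same chromosome and strand are joined into clusters when
#' they share a donor or an acceptor position (connected components).
#' Singleton clusters carry no usage information and are dropped, as are
#' clusters whose cohort-total read count falls below
#' \code{min_cluster_reads}. Clusters are optionally assigned to genes by
#' overlap with gene intervals.
#'
#' @param jt a \linkS4class{JunctionTable}.
#' @param min_cluster_reads minimum cohort-total reads per cluster
#'   (default 30).
#' @param gene_ranges optional \link[GenomicRanges]{GRanges} with a
#'   \code{gene} metadata column for cluster-to-gene assignment.
#' @return data.frame with one row per retained junction: \code{cluster_id},
#'   \code{junction} (row index into \code{jt}), coordinates, and
#'   \code{gene} (NA when unassigned).
#' @export
buildClusters <- function(jt, min_cluster_reads = 30, gene_ranges = NULL) {
  rr <- SummarizedExperiment::rowRanges(jt)
  n <- length(rr)
  empty <- data.frame(cluster_id = character(0), junction = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene = character(0))
  if (n == 0L) return(empty)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  strand <- as.character(GenomicRanges::strand(rr))
  donor_key <- paste(chrom, strand, "d", GenomicRanges::start(rr))
  acceptor_key <- paste(chrom, strand, "a", GenomicRanges::end(rr))
  # union-find over shared splice sites
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  for (key in list(donor_key, acceptor_key))
    for (grp in split(seq_len(n), key))
      if (length(grp) > 1L) for (i in grp[-1]) union_(grp[1], i)
  comp <- vapply(seq_len(n), find, integer(1))
  counts <- junctionCounts(jt)
  keep_comp <- names(which(
    tapply(seq_len(n), comp, function(idx)
      length(idx) > 1L && sum(counts[idx, , drop = FALSE]) >= min_cluster_reads)))
  if (!length(keep_comp)) return(empty)
  # deterministic ids ordered by leftmost junction
  comp_first <- tapply(seq_len(n), comp, min)[keep_comp]
  ord <- order(chrom[comp_first], GenomicRanges::start(rr)[comp_first])
  ids <- stats::setNames(sprintf("clu_%03d", seq_along(keep_comp)),
                         keep_comp[ord])
  rows <- which(as.character(comp) %in% keep_comp)
  out <- data.frame(cluster_id = unname(ids[as.character(comp[rows])]),
                    junction = rows, chrom = chrom[rows],
                    start = GenomicRanges::start(rr)[rows],
                    end = GenomicRanges::end(rr)[rows],
                    strand = strand[rows], gene = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(gene_ranges)) {
    hits <- GenomicRanges::findOverlaps(rr[rows], gene_ranges,
                                        ignore.strand = TRUE)
    gene_of_row <- rep(NA_character_, length(rows))
    gene_of_row[S4Vectors::queryHits(hits)] <-
      GenomicRanges::mcols(gene_ranges)$gene[S4Vectors::subjectHits(hits)]
    # one gene per cluster: majority vote over its junctions
    for (cid in unique(out$cluster_id)) {
      g <- gene_of_row[out$cluster_id == cid]
      g <- g[!is.na(g)]
      if (length(g)) out$gene[out$cluster_id == cid] <- names(which.max(table(g)))
    }
  }
  out <- out[order(out$cluster_id, out$junction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- Dirichlet-multinomial machinery --------------------------------------

#' Method-of-moments Dirichlet-multinomial concentration
#'
#' Pooled ANOVA-type moment estimator of the intraclass correlation
#' theta = 1/(concentration + 1) across a cluster's junctions, converted to
#' the concentration. Samples with zero reads are ignored.
#'
#' @param counts matrix, samples x junctions.
#' @return estimated concentration (clamped to a positive range), or NA with
#'   fewer than two informative samples.
#' @export
momConcentration <- function(counts) {
  n <- rowSums(counts)
  keep <- n > 0
  counts <- counts[keep, , drop = FALSE]; n <- n[keep]
  S <- nrow(counts); J <- ncol(counts)
  if (S < 2L) return(NA_real_)
  P <- counts / n
  pbar <- colSums(counts) / sum(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (S - 1)
  msb <- colSums(n * (P - matrix(pbar, S, J, byrow = TRUE))^2) / (S - 1)
  msw <- colSums(n * P * (1 - P)) / sum(n - 1)
  den <- sum(msb + (nc - 1) * msw)
  theta <- if (den > 0) sum(msb - msw) / den else 1e-8
  theta <- min(max(theta, 1e-8), 1 - 1e-8)
  (1 - theta) / theta
}

# DM log-likelihood terms that depend on p (X: samples x J)
.dm_ll <- function(X, conc, p) {
  A <- matrix(conc * p, nrow(X), ncol(X), byrow = TRUE)
  sum(lgamma(X + A) - lgamma(A))
}

# maximized DM log-likelihood over the proportion simplex, fixed concentration
.dm_fit <- function(X, conc) {
  J <- ncol(X)
  cs <- colSums(X)
  if (J == 2L) {
    f <- function(eta) { p <- c(stats::plogis(eta), 1 - stats::plogis(eta))
      -.dm_ll(X, conc, p) }
    opt <- stats::optimize(f, c(-15, 15))
    return(-opt$objective)
  }
  nll <- function(eta) {
    p <- exp(c(eta, 0)); p <- p / sum(p)
    -.dm_ll(X, conc, p)
  }
  init <- log((cs[-J] + 1) / (cs[J] + 1))
  opt <- stats::optim(init, nll, method = "BFGS")
  -opt$value
}

#' Leave-one-out Dirichlet-multinomial cluster test
#'
#' Likelihood-ratio test of the null that one sample's junction-usage
#' proportions equal those of the pooled remaining samples, under a
#' Dirichlet-multinomial with a fixed concentration. Both groups'
#' proportions are profiled out (one-vs-rest two-group LRT) and the
#' statistic is referred to chi-square with J - 1 degrees of freedom.
#'
#' @param counts matrix, junctions x samples, for one cluster (>= 2
#'   junctions).
#' @param sample column index or name of the tested sample.
#' @param concentration Dirichlet-multinomial concentration (see
#'   \code{\link{momConcentration}}); floored at \code{conc_floor}.
#' @param min_sample_reads minimum reads in the tested sample (default 10).
#' @param conc_floor lower bound for the concentration (default 1e-3).
#' @return list with \code{p_raw}, \code{stat}, \code{df}, \code{effect}
#'   (largest absolute usage-fraction change), or NULL when the test is
#'   skipped (shallow sample or empty reference).
#' @export
looClusterTest <- function(counts, sample, concentration,
                           min_sample_reads = 10, conc_floor = 1e-3) {
  X <- t(counts)  # samples x junctions
  if (is.character(sample)) sample <- match(sample, rownames(X))
  J <- ncol(X)
  stopifnot(J >= 2L)
  conc <- max(concentration, conc_floor)
  xs <- X[sample, , drop = FALSE]
  ref <- X[-sample, , drop = FALSE]
  if (sum(xs) < min_sample_reads || sum(ref) == 0) return(NULL)
  stat <- 2 * (.dm_fit(xs, conc) + .dm_fit(ref, conc) - .dm_fit(X, conc))
  stat <- max(0, stat)
  p_ref <- colSums(ref) / sum(ref)
  effect <- max(abs(xs / sum(xs) - p_ref))
  list(p_raw = stats::pchisq(stat, J - 1, lower.tail = FALSE),
       stat = stat, df = J - 1L, effect = effect)
}

#' Cohort-wide aberrant-splicing calls (leave-one-out design)
#'
#' Builds intron clusters, tests every (sample, cluster) pair with the
#' leave-one-out Dirichlet-multinomial LRT, adjusts p-values per sample
#' (each proband owns its family of tests; cohort-wide adjustment available
#' via \code{adjust_scope}), and intersects significant calls with the
#' candidate gene set (CP genes, phenotype-related genes and damaging
#' de novo genes, supplied by the caller).
#'
#' The default concentration is a cohort consensus: the median of per-cluster
#' method-of-moments estimates. Per-cluster estimation
#' (\code{concentration_method = "per_cluster"}) is noisier for small
#' cohorts and makes the deep tail of the chi-square reference
#' anticonservative; see the methods vignette.
#'
#' @param jt a \linkS4class{JunctionTable}.
#' @param candidate_genes character vector of candidate gene symbols (used
#'   for the filtered list; NULL keeps the filtered list empty).
#' @param gene_ranges optional \link[GenomicRanges]{GRanges} for
#'   cluster-to-gene assignment.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_cluster_reads,min_sample_reads,conc_floor see
#'   \code{\link{buildClusters}} and \code{\link{looClusterTest}}.
#' @param concentration_method \code{"consensus"} (default) or
#'   \code{"per_cluster"}.
#' @param adjust_scope \code{"per_sample"} (default) or \code{"cohort"}.
#' @return list with \code{all} (every tested (sample, cluster):
#'   sample, cluster_id, gene, p_raw, p_adjusted, effect) and
#'   \code{filtered} (p_adjusted < alpha and gene in candidate set), plus
#'   \code{clusters} (the cluster map).
#' @export
callSplicingOutliers <- function(jt, candidate_genes = NULL,
                                 gene_ranges = NULL, alpha = 0.05,
                                 min_cluster_reads = 30,
                                 min_sample_reads = 10, conc_floor = 1e-3,
                                 concentration_method = c("consensus",
                                                          "per_cluster"),
                                 adjust_scope = c("per_sample", "cohort")) {
  concentration_method <- match.arg(concentration_method)
  adjust_scope <- match.arg(adjust_scope)
  clusters <- buildClusters(jt, min_cluster_reads, gene_ranges)
  counts <- junctionCounts(jt)
  samples <- colnames(counts)
  empty <- data.frame(sample = character(0), cluster_id = character(0),
                      gene = character(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), effect = numeric(0))
  if (nrow(clusters) == 0L)
    return(list(all = empty, filtered = empty, clusters = clusters))
  cl_ids <- unique(clusters$cluster_id)
  cl_rows <- split(clusters$junction, clusters$cluster_id)[cl_ids]
  cl_gene <- vapply(cl_ids, function(cid)
    clusters$gene[match(cid, clusters$cluster_id)], character(1))
  conc_each <- vapply(cl_rows, function(rows)
    momConcentration(t(counts[rows, , drop = FALSE])), numeric(1))
  consensus <- stats::median(conc_each, na.rm = TRUE)
  res <- vector("list", length(cl_ids))
  for (k in seq_along(cl_ids)) {
    sub <- counts[cl_rows[[k]], , drop = FALSE]
    conc <- if (concentration_method == "consensus") consensus
            else conc_each[k]
    if (is.na(conc)) next
    rows <- lapply(seq_along(samples), function(s) {
      t <- looClusterTest(sub, s, conc, min_sample_reads, conc_floor)
      if (is.null(t)) return(NULL)
      data.frame(sample = samples[s], cluster_id = cl_ids[k],
                 gene = cl_gene[k], p_raw = t$p_raw, effect = t$effect,
                 stringsAsFactors = FALSE)
    })
    res[[k]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  all <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(all))
    return(list(all = empty, filtered = empty, clusters = clusters))
  if (adjust_scope == "per_sample") {
    all$p_adjusted <- NA_real_
    for (s in unique(all$sample)) {
      i <- all$sample == s
      all$p_adjusted[i] <- bhAdjust(all$p_raw[i])
    }
  } else {
    all$p_adjusted <- bhAdjust(all$p_raw)
  }
  all <- all[order(all$sample, all$p_adjusted), c("sample", "cluster_id",
                                                  "gene", "p_raw",
                                                  "p_adjusted", "effect")]
  rownames(all) <- NULL
  filtered <- all[all$p_adjusted < alpha &
                    !is.na(all$gene) & all$gene %in% candidate_genes, ,
                  drop = FALSE]
  rownames(filtered) <- NULL
  list(all = all, filtered = filtered, clusters = clusters)
}
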