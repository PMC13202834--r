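#' @include AllClasses.R AllGenerics.R stats-core.R
NULL

#' Gene-level kernel statistics for single-sample gene-set scoring
#'
#' For each gene, each sample's expression is placed on the cohort's
#' distribution by a Gaussian-kernel cumulative density estimate (bandwidth =
#' per-gene standard deviation / 4), then converted within each sample to
#' centered ranks (rank minus (p+1)/2, so the statistic is symmetric around
#' zero and genes at either expression extreme carry the largest absolute
#' weight). Expression is taken on the log2(TPM + 1) scale. Genes with zero
#' variance across samples carry no ordering information and are dropped.
#'
#' @param em an \linkS4class{ExpressionMatrix} or a numeric matrix already on
#'   the log scale (>= 3 samples).
#' @return list with \code{kcdf} (kernel CDF estimates, genes x samples),
#'   \code{stat} (centered ranks, genes x samples) and \code{dropped}
#'   (zero-variance gene symbols).
#' @export
gsvaGeneStats <- function(em) {
  x <- if (is(em, "ExpressionMatrix")) log2(tpm(em) + 1) else em
  if (ncol(x) < 3L) stop("need >= 3 samples")
  sds <- apply(x, 1L, stats::sd)
  dropped <- rownames(x)[sds == 0]
  if (length(dropped)) {
    message(length(dropped), " zero-variance gene(s) dropped")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  n <- ncol(x)
  kcdf <- x
  for (i in seq_len(nrow(x))) {
    h <- sds[i] / 4
    d <- outer(x[i, ], x[i, ], "-") / h   # [j, k] = (x_j - x_k) / h
    kcdf[i, ] <- rowMeans(stats::pnorm(d))
  }
  stat <- vapply(seq_len(ncol(kcdf)),
                 function(j) rank(kcdf[, j], ties.method = "average"),
                 numeric(nrow(kcdf)))
  stat <- matrix(stat, nrow = nrow(kcdf)) - (nrow(x) + 1) / 2
  dimnames(stat) <- dimnames(x)
  list(kcdf = kcdf, stat = stat, dropped = dropped)
}

# weighted KS random walk for one sample ordering; maxdiff scoring.
# stat_col: centered ranks for one sample; member: logical vector.
.gsva_walk <- function(stat_col, member, tau) {
  ord <- order(stat_col, decreasing = TRUE)
  mem <- member[ord]
  w <- abs(stat_col[ord])^tau
  w[!mem] <- 0
  wsum <- sum(w)
  if (wsum == 0) return(NA_real_)  # all member weights zero: undefined walk
  p_not <- sum(!mem)
  step <- w / wsum
  step[!mem] <- -1 / p_not
  cum <- cumsum(step)
  max(0, max(cum)) + min(0, min(cum))
}

#' Single-sample gene-set variation score
#'
#' Weighted Kolmogorov-Smirnov random walk over a sample's gene ranking:
#' walking down the ranking, set members add their normalized weight
#' |centered rank|^tau and non-members subtract 1/(p - m). The score is the
#' maximum positive deviation plus the minimum negative deviation of the walk
#' ("maxdiff" scoring), which is bounded in [-1, 1].
#'
#' @param stats output of \code{\link{gsvaGeneStats}}.
#' @param gene_set character vector of member symbols.
#' @param tau rank-weight exponent (default 1).
#' @return named numeric vector of per-sample scores.
#' @export
gsvaScore <- function(stats, gene_set, tau = 1) {
  stat <- stats$stat
  member <- rownames(stat) %in% gene_set
  if (!any(member)) return(stats::setNames(rep(NA_real_, ncol(stat)),
                                           colnames(stat)))
  if (all(member)) stop("complement empty: gene set covers every gene")
  apply(stat, 2L, .gsva_walk, member = member, tau = tau)
}

#' Gene-set x sample GSVA score matrix
#'
#' Scores every gene set against every sample. Sets are first restricted to
#' members present in the matrix; sets with fewer than \code{min_size} or
#' more than \code{max_size} matrix members are excluded (degenerate walks).
#'
#' @param em an \linkS4class{ExpressionMatrix} (>= 3 samples).
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param tau rank-weight exponent (default 1).
#' @param min_size,max_size gene-set size bounds after matrix intersection
#'   (defaults 5 and 500).
#' @return A \linkS4class{GsvaScoreMatrix}; provenance records the kernel,
#'   tau, scoring mode and size filter.
#' @export
gsvaScores <- function(em, gsc, tau = 1, min_size = 5, max_size = 500) {
  stats <- gsvaGeneStats(em)
  universe <- rownames(stats$stat)
  sets <- lapply(geneSets(gsc), intersect, y = universe)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (!length(sets)) stop("no gene set within the size bounds")
  es <- t(vapply(sets, function(s) gsvaScore(stats, s, tau),
                 numeric(ncol(stats$stat))))
  dimnames(es) <- list(names(sets), colnames(stats$stat))
  GsvaScoreMatrix(es, provenance = list(
    kernel = "gaussian", bandwidth = "sd/4", tau = tau,
    mode = "maxdiff", gene_filter = "nonzero variance",
    set_size = c(min_size, max_size)))
}

#' Flag pathway outliers by Tukey fences
#'
#' For each gene set, quartiles of its scores over samples (type-7 linear
#' interpolation) define the fences Q1 - k*IQR and Q3 + k*IQR; every score
#' strictly outside the fences is called, with direction \code{activated}
#' above the upper fence and \code{repressed} below the lower. A pathway is
#' aberrant when at least one proband is called.
#'
#' @param gsm a \linkS4class{GsvaScoreMatrix} (>= 5 samples) or a plain
#'   sets x samples matrix.
#' @param k fence multiplier (default 1.5).
#' @return list with \code{calls} (set_name, sample, score, direction,
#'   lower, upper) and \code{aberrant_sets} (sets with >= 1 call).
#' @export
flagPathwayOutliers <- function(gsm, k = 1.5) {
  es <- if (is(gsm, "GsvaScoreMatrix")) esMatrix(gsm) else gsm
  if (ncol(es) < 5L) stop("need >= 5 samples")
  calls <- vector("list", nrow(es))
  for (i in seq_len(nrow(es))) {
    f <- tukeyFences(es[i, ], k = k)
    out <- which(es[i, ] < f$lower | es[i, ] > f$upper)
    if (!length(out)) next
    calls[[i]] <- data.frame(
      set_name = rownames(es)[i], sample = colnames(es)[out],
      score = unname(es[i, out]),
      direction = ifelse(es[i, out] > f$upper, "activated", "repressed"),
      lower = f$lower, upper = f$upper, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls))
    calls <- data.frame(set_name = character(0), sample = character(0),
                        score = numeric(0), direction = character(0),
                        lower = numeric(0), upper = numeric(0))
  rownames(calls) <- NULL
  list(calls = calls, aberrant_sets = unique(calls$set_name))
}
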