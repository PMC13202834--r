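#' @include AllClasses.R
NULL

# Noncentral hypergeometric machinery shared by the CMLE and the exact CI.
# Support of the a-cell given margins (m = a+b, n = c+d, k = a+c).
.nchg_support <- function(m, n, k) seq.int(max(0L, k - n), min(k, m))

# log unnormalized noncentral hypergeometric weights at log-odds lpsi
.nchg_logw <- function(logdc, support, lpsi) logdc + support * lpsi

.nchg_mean <- function(logdc, support, lpsi) {
  lw <- .nchg_logw(logdc, support, lpsi)
  w <- exp(lw - max(lw))
  sum(support * w) / sum(w)
}

.nchg_cdf_upper <- function(logdc, support, lpsi, a) {
  lw <- .nchg_logw(logdc, support, lpsi)
  w <- exp(lw - max(lw))
  sum(w[support >= a]) / sum(w)
}

.nchg_cdf_lower <- function(logdc, support, lpsi, a) {
  lw <- .nchg_logw(logdc, support, lpsi)
  w <- exp(lw - max(lw))
  sum(w[support <= a]) / sum(w)
}

.solve_monotone <- function(f, target) {
  # find lpsi with f(lpsi) = target; f increasing in lpsi
  lo <- -1; hi <- 1
  while (f(lo) > target && lo > -745) lo <- lo * 2
  while (f(hi) < target && hi < 745) hi <- hi * 2
  stats::uniroot(function(x) f(x) - target, c(lo, hi), tol = 1e-10)$root
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Exact inference for a 2x2 table by full enumeration of the hypergeometric
#' support. The two-sided p-value sums the probabilities of all tables (with
#' the observed margins) no more probable than the observed one. The primary
#' odds-ratio estimate is the conditional MLE under the noncentral
#' hypergeometric likelihood, with an exact conditional 95\% interval obtained
#' by inverting the one-sided tails at 0.025 each. The sample cross-product
#' ratio and its Wald interval are also reported, since clinical papers often
#' print those instead.
#'
#' @param a,b,c,d non-negative integer cell counts (rows = exposure,
#'   columns = outcome), or \code{a} may be a 2x2 matrix.
#' @param estimate compute the odds-ratio estimates and intervals
#'   (default TRUE); FALSE returns the exact p-value only, which is much
#'   faster in exhaustive sweeps.
#' @return list with elements \code{p_two_sided}, \code{or_cmle},
#'   \code{ci95} (exact conditional), \code{or_sample}, \code{ci95_wald},
#'   and \code{degenerate} (TRUE when a margin is zero, in which case
#'   p = 1 and the odds ratio is undefined).
#' @examples
#' fisherExact(5, 2, 1, 15)$p_two_sided
#' @export
fisherExact <- function(a, b = NULL, c = NULL, d = NULL, estimate = TRUE) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("table total must be positive")
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c); d <- as.integer(d)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) {
    return(list(p_two_sided = 1, or_cmle = NA_real_, ci95 = c(NA_real_, NA_real_),
                or_sample = NA_real_, ci95_wald = c(NA_real_, NA_real_),
                degenerate = TRUE))
  }
  support <- .nchg_support(m, n, k)
  logdc <- stats::dhyper(support, m, n, k, log = TRUE)
  d_obs <- stats::dhyper(a, m, n, k)
  p2 <- sum(exp(logdc)[exp(logdc) <= d_obs * (1 + 1e-7)])
  p2 <- min(p2, 1)
  if (!estimate)
    return(list(p_two_sided = p2, or_cmle = NA_real_,
                ci95 = c(NA_real_, NA_real_), or_sample = NA_real_,
                ci95_wald = c(NA_real_, NA_real_), degenerate = FALSE))

  # conditional MLE: E[A | psi, margins] = a
  or_cmle <-
    if (a == min(support)) 0
    else if (a == max(support)) Inf
    else exp(.solve_monotone(function(l) .nchg_mean(logdc, support, l), a))

  lower <-
    if (a == min(support)) 0
    else exp(.solve_monotone(function(l) .nchg_cdf_upper(logdc, support, l, a), 0.025))
  upper <-
    if (a == max(support)) Inf
    else exp(.solve_monotone(function(l) 1 - .nchg_cdf_lower(logdc, support, l, a), 1 - 0.025))

  or_sample <- (a * d) / (b * c)
  wald <- if (all(c(a, b, c, d) > 0)) {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    exp(log(or_sample) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)

  list(p_two_sided = p2, or_cmle = or_cmle, ci95 = c(lower, upper),
       or_sample = or_sample, ci95_wald = wald, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Values outside [0, 1] are an error; NAs are
#' propagated.
#'
#' @param p numeric vector of p-values.
#' @param method adjustment method, "BH" (default) or "bonferroni".
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap between a
#' hit list and a gene set drawn from a common universe.
#'
#' @param hit_genes,gene_set,universe character vectors of gene symbols;
#'   hits and set must be subsets of the universe.
#' @return list with \code{overlap}, \code{expected} and \code{p}.
#' @export
hypergeomOra <- function(hit_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_genes <- unique(hit_genes); gene_set <- unique(gene_set)
  if (!all(hit_genes %in% universe)) stop("hit genes outside universe")
  if (!all(gene_set %in% universe)) stop("gene set outside universe")
  q <- length(intersect(hit_genes, gene_set))
  K <- length(gene_set); N <- length(universe); nh <- length(hit_genes)
  p <- stats::phyper(q - 1, K, N - K, nh, lower.tail = FALSE)
  list(overlap = q, expected = nh * K / N, p = p)
}

#' Tukey fences
#'
#' Quartiles by linear interpolation of order statistics (quantile type 7)
#' and the classical outlier fences Q1 - k*IQR, Q3 + k*IQR.
#'
#' @param values numeric vector, at least 4 finite values.
#' @param k fence multiplier (default 1.5).
#' @return list with \code{q1}, \code{q3}, \code{iqr}, \code{lower},
#'   \code{upper}.
#' @export
tukeyFences <- function(values, k = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("insufficient for quartiles: need >= 4 finite values")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  list(q1 = q[1], q3 = q[2], iqr = iqr,
       lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}
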