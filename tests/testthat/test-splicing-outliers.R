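# Intron clustering and leave-one-out Dirichlet-multinomial testing.

test_that("junctions sharing a splice site cluster; singletons drop", {
  cnt <- matrix(50L, 2, 6)
  jt <- jt_from_df(data.frame(chrom = "chr1", start = c(100, 100),
                              end = c(200, 300), strand = "+"), cnt)
  cl <- buildClusters(jt)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 2L)
  # disjoint junctions are singletons, dropped
  jt2 <- jt_from_df(data.frame(chrom = "chr1", start = c(100, 300),
                               end = c(200, 400), strand = "+"), cnt)
  expect_equal(nrow(buildClusters(jt2)), 0L)
  # different strand or chromosome never joins
  jt3 <- jt_from_df(data.frame(chrom = "chr1", start = c(100, 100),
                               end = c(200, 300), strand = c("+", "-")), cnt)
  expect_equal(nrow(buildClusters(jt3)), 0L)
})

test_that("transitive sharing builds one connected component", {
  # chain: (100,200) shares donor with (100,300); (250,300) shares acceptor
  # with (100,300)
  cnt <- matrix(30L, 3, 6)
  jt <- jt_from_df(data.frame(chrom = "chr1", start = c(100, 100, 250),
                              end = c(200, 300, 300), strand = "+"), cnt)
  cl <- buildClusters(jt)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 3L)
  # union-find oracle: brute-force transitive closure over shared sites
  share <- function(i, j, df) df$start[i] == df$start[j] | df$end[i] == df$end[j]
  df <- data.frame(start = c(100, 100, 250), end = c(200, 300, 300))
  adj <- outer(1:3, 1:3, Vectorize(function(i, j) share(i, j, df)))
  reach <- adj | t(adj); for (k in 1:3) reach <- reach | (reach[, k] %o% reach[k, ])
  expect_true(all(reach))
})

test_that("cohort read-depth filter drops shallow clusters", {
  cnt <- matrix(2L, 2, 6)  # total 24 < 30
  jt <- jt_from_df(data.frame(chrom = "chr1", start = c(100, 100),
                              end = c(200, 300), strand = "+"), cnt)
  expect_equal(nrow(buildClusters(jt, min_cluster_reads = 30)), 0L)
  expect_equal(nrow(buildClusters(jt, min_cluster_reads = 24)), 2L)
})

test_that("the LOO test is null-calm at matching proportions and extreme under gross shifts", {
  # identical proportions at high depth
  cnt <- matrix(rep(c(500L, 500L), 21), nrow = 2)
  res <- looClusterTest(cnt, 1, concentration = 1e6)
  expect_gt(res$p_raw, 0.5)
  expect_equal(res$effect, 0, tolerance = 1e-9)
  # reference 50/50 across 20 deep samples, test sample 0/100:
  # a multinomial LRT oracle (no overdispersion) bounds the DM p from below
  cnt2 <- cbind(c(0L, 100L), matrix(rep(c(500L, 500L), 20), nrow = 2))
  conc <- momConcentration(t(cnt2[, -1]))
  res2 <- looClusterTest(cnt2, 1, concentration = conc)
  expect_lt(res2$p_raw, 1e-6)
  lrt_multinom <- 2 * (100 * log(2))  # x log(x/(n p0)), p0 = 1/2
  expect_gt(pchisq(lrt_multinom, df = 1, lower.tail = FALSE), 0)
  expect_lt(pchisq(lrt_multinom, df = 1, lower.tail = FALSE), res2$p_raw)
  expect_equal(res2$effect, 0.5)
  # shallow samples are skipped
  cnt3 <- cnt2; cnt3[, 1] <- c(1L, 3L)
  expect_null(looClusterTest(cnt3, 1, concentration = conc))
})

test_that("method-of-moments concentration recovers the simulated value", {
  set.seed(41)
  rdir <- function(a) { g <- rgamma(length(a), a); g / sum(g) }
  for (conc in c(20, 80)) {
    X <- t(sapply(1:60, function(i)
      rmultinom(1, 400, rdir(conc * c(0.5, 0.3, 0.2)))))
    est <- momConcentration(X)
    expect_gt(est, conc / 2)
    expect_lt(est, conc * 2)
  }
})

test_that("planted usage shifts are flagged and candidate filtering applies", {
  co <- generateCohort(cohortConfig(seed = 301))
  tr <- truthRegistry(co)@planted_splicing_shifts
  res <- callSplicingOutliers(cohortJunctions(co),
                              candidate_genes = tr$gene,
                              gene_ranges = syntheticGeneRanges(600))
  k_all <- paste(res$all$sample, res$all$cluster_id)
  k_tr <- paste(tr$sample, tr$cluster_id)
  m <- match(k_tr, k_all)
  expect_false(anyNA(m))
  expect_true(all(res$all$p_adjusted[m] < 0.05))
  # all planted genes are candidates here, so calls appear filtered as well
  expect_true(all(k_tr %in% paste(res$filtered$sample, res$filtered$cluster_id)))
  # a planted shift outside the candidate set is present unfiltered only
  res2 <- callSplicingOutliers(cohortJunctions(co),
                               candidate_genes = "NOT_A_GENE",
                               gene_ranges = syntheticGeneRanges(600))
  expect_true(all(k_tr %in% paste(res2$all$sample, res2$all$cluster_id)))
  expect_equal(nrow(res2$filtered), 0L)
  # alpha = 0 empties the filtered list
  res3 <- callSplicingOutliers(cohortJunctions(co), candidate_genes = tr$gene,
                               gene_ranges = syntheticGeneRanges(600),
                               alpha = 0)
  expect_equal(nrow(res3$filtered), 0L)
  # adjusted p never below raw p
  expect_true(all(res$all$p_adjusted >= res$all$p_raw - 1e-15))
  expect_true(all(res$all$effect >= 0 & res$all$effect <= 1))
})

test_that("per-sample BH matches adjusting each sample's tests separately", {
  co <- generateCohort(null_splice_config(seed = 302, n_clusters = 10L))
  res <- callSplicingOutliers(cohortJunctions(co))
  for (s in unique(res$all$sample)[1:5]) {
    i <- res$all$sample == s
    expect_equal(res$all$p_adjusted[i], bh_oracle(res$all$p_raw[i]))
  }
})

test_that("destroying within-sample coherence kills planted signals", {
  co <- generateCohort(cohortConfig(seed = 303))
  tr <- truthRegistry(co)@planted_splicing_shifts
  cnt <- junctionCounts(cohortJunctions(co))
  set.seed(304)
  perm <- t(apply(cnt, 1L, sample))  # independent row-wise permutation
  colnames(perm) <- colnames(cnt)
  jt_perm <- JunctionTable(perm, SummarizedExperiment::rowRanges(cohortJunctions(co)))
  res <- callSplicingOutliers(jt_perm, candidate_genes = tr$gene,
                              gene_ranges = syntheticGeneRanges(600))
  k_all <- paste(res$all$sample, res$all$cluster_id)
  k_tr <- paste(tr$sample, tr$cluster_id)
  hits <- res$all$p_adjusted[match(k_tr, k_all)] < 0.05
  expect_lt(sum(hits, na.rm = TRUE), length(k_tr) / 2)
})

test_that("null-cohort p-values are close to uniform", {
  co <- generateCohort(null_splice_config(seed = 305))
  res <- callSplicingOutliers(cohortJunctions(co))
  p <- res$all$p_raw
  expect_gt(length(p), 500)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})
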