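# Single-sample gene-set variation scores and pathway fences.


test_that("kernel statistics preserve sample order and match the empirical CDF", {
  # well-separated values: the kernel estimate approaches the ECDF
  x <- rbind(gA = c(0, 10, 20, 30), gB = c(5, 4, 3, 2), gC = c(1, 2, 3, 4))
  colnames(x) <- sprintf("s%d", 1:4)
  st <- gsvaGeneStats(x)
  expect_equal(which.max(st$kcdf["gA", ]), c(s4 = 4L))  # cohort max ranks top
  ecdf_self <- function(v) vapply(v, function(xi) mean(v <= xi), numeric(1))
  for (g in rownames(x))
    expect_equal(unname(st$kcdf[g, ]), unname(ecdf_self(x[g, ])) - 0.125,
                 tolerance = 0.13)
  # duplicated sample columns receive identical statistics
  xx <- x[, c(1, 2, 3, 4, 1)]
  colnames(xx) <- sprintf("s%d", 1:5)
  st2 <- gsvaGeneStats(xx)
  expect_equal(st2$stat[, 1], st2$stat[, 5], ignore_attr = TRUE)
})

test_that("zero-variance genes are dropped with a message", {
  x <- rbind(gA = c(1, 2, 3, 4), gFlat = c(2, 2, 2, 2))
  colnames(x) <- sprintf("s%d", 1:4)
  expect_message(st <- gsvaGeneStats(x), "zero-variance")
  expect_identical(st$dropped, "gFlat")
  expect_equal(rownames(st$stat), "gA")
})

test_that("scores equal the brute-force random walk on 5-gene toys", {
  set.seed(51)
  for (rep in 1:20) {
    x <- matrix(rnorm(15), 5, 3,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:3)))
    st <- gsvaGeneStats(x)
    member <- rownames(x) %in% c("g2", "g4")
    es <- gsvaScore(st, c("g2", "g4"), tau = 1)
    for (j in 1:3)
      expect_equal(unname(es[j]), walk_oracle(st$stat[, j], member),
                   tolerance = 1e-9)
    expect_true(all(es >= -1 & es <= 1))
  }
})

test_that("a member at the top of a sample's ranking scores positive there", {
  # in s1, gTop sits at the maximum of its own distribution while every
  # other gene sits at its minimum, so gTop tops s1's within-sample ranking
  x <- rbind(gTop = c(10, 1, 2), gA = c(1, 2, 3), gB = c(0, 5, 6),
             gC = c(2, 8, 9))
  colnames(x) <- sprintf("s%d", 1:3)
  st <- gsvaGeneStats(x)
  expect_equal(unname(which.max(st$stat[, "s1"])), 1L)
  es <- gsvaScore(st, "gTop")
  expect_gt(es["s1"], 0)
})

test_that("reversing the expression ranking flips the score sign exactly", {
  set.seed(52)
  x <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  set_m <- sprintf("g%02d", c(3, 7, 11, 20))
  es <- gsvaScore(gsvaGeneStats(x), set_m)
  es_rev <- gsvaScore(gsvaGeneStats(-x), set_m)
  expect_equal(es_rev, -es, tolerance = 1e-12)
})

test_that("scores are invariant under order-preserving per-gene affine maps", {
  set.seed(53)
  x <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  a <- runif(30, 0.5, 3); b <- rnorm(30)
  x2 <- x * a + b
  set_m <- sprintf("g%02d", c(2, 9, 17))
  expect_equal(gsvaScore(gsvaGeneStats(x2), set_m),
               gsvaScore(gsvaGeneStats(x), set_m), tolerance = 1e-12)
})

test_that("degenerate sets are rejected or absent", {
  x <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  st <- gsvaGeneStats(x)
  expect_error(gsvaScore(st, sprintf("g%d", 1:5)), "complement empty")
  expect_true(all(is.na(gsvaScore(st, "nope"))))
  gsc <- GeneSetCollection(list(tiny = "g1",
                                ok = sprintf("g%d", 1:5)))
  em <- ExpressionMatrix(matrix(rlnorm(40 * 6), 40, 6,
                                dimnames = list(sprintf("h%02d", 1:40),
                                                sprintf("s%d", 1:6))))
  expect_error(gsvaScores(em, gsc), "no gene set within the size bounds")
})

test_that("Tukey fences flag exactly the prescribed scores", {
  m <- rbind(flat = rep(0.2, 5), spike = c(0, 0, 0, 0, 1))
  colnames(m) <- sprintf("s%d", 1:5)
  res <- flagPathwayOutliers(m)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$set_name, "spike")
  expect_equal(res$calls$sample, "s5")
  expect_equal(res$calls$direction, "activated")
  expect_identical(res$aberrant_sets, "spike")
})

test_that("planted pathway shifts are flagged with the right direction", {
  co <- generateCohort(cohortConfig(seed = 501))
  gsm <- gsvaScores(cohortExpression(co), co@gene_sets)
  expect_true(all(abs(esMatrix(gsm)) <= 1))
  res <- flagPathwayOutliers(gsm)
  tr <- truthRegistry(co)@planted_pathway_shifts
  k_calls <- paste(res$calls$set_name, res$calls$sample)
  m <- match(paste(tr$set_name, tr$sample), k_calls)
  expect_false(anyNA(m))
  expect_identical(res$calls$direction[m],
                   ifelse(tr$direction == "up", "activated", "repressed"))
})

test_that("per-set outlier rate on exchangeable cohorts is near the n=27 fence level", {
  # Tukey-fence exceedance for 27 exchangeable Gaussian-like scores is ~2-4%
  # per observation (estimated quartiles are noisy at this n); the band below
  # was fixed from a Gaussian Monte Carlo at n = 27
  rates <- numeric(3)
  for (i in 1:3) {
    co <- generateCohort(cohortConfig(seed = 510 + i, n_pathway_shifts = 0L,
                                      n_expr_outliers = 0L))
    gsm <- gsvaScores(cohortExpression(co), co@gene_sets)
    res <- flagPathwayOutliers(gsm)
    rates[i] <- nrow(res$calls) / length(esMatrix(gsm))
  }
  expect_gt(mean(rates), 0.001)
  expect_lt(mean(rates), 0.06)
})
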