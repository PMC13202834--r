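# Synthetic cohort generator: determinism, truth registry, Mendelian
# consistency, file layout and round-trips.

small_cfg <- function(seed, n_pathway_shifts = 2L, n_splicing_shifts = 3L) {
  cohortConfig(seed = seed, n_trios = 8L, n_genes = 80L, n_gene_sets = 8L,
               genes_per_set = c(5L, 10L),
               n_background_variants_per_trio = 10L,
               n_damaging_dnv = 4L, n_expr_outliers = 3L,
               n_splicing_shifts = n_splicing_shifts,
               n_pathway_shifts = n_pathway_shifts,
               n_clusters = 12L, n_cp_genes = 8L)
}

test_that("generation is deterministic and written cohorts are byte-identical", {
  co1 <- generateCohort(small_cfg(7))
  co2 <- generateCohort(small_cfg(7))
  expect_identical(variantRecords(co1), variantRecords(co2))
  expect_identical(tpm(co1), tpm(co2))
  expect_identical(junctionCounts(co1), junctionCounts(co2))
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- writeCohort(co1, d1); m2 <- writeCohort(co2, d2)
  expect_identical(m1$md5, m2$md5)
  # checksums change iff the seed changes (the pedigree is structural and
  # seed-independent by design)
  d3 <- tempfile()
  m3 <- writeCohort(generateCohort(small_cfg(8)), d3)
  data_files <- m1$file != "cohort.ped"
  expect_false(any(m3$md5[data_files] == m1$md5[data_files]))
  expect_identical(m3$md5[!data_files], m1$md5[!data_files])
})

test_that("the written layout has the documented 8 files and round-trips", {
  co <- generateCohort(small_cfg(9))
  d <- tempfile()
  man <- writeCohort(co, d)
  expect_equal(nrow(man), 8L)
  expect_setequal(man$file, c("cohort.vcf", "cohort.ped", "annotations.tsv",
                              "expression.tsv", "junctions.tsv",
                              "gene_sets.gmt", "cp_genes.txt", "truth.json"))
  expect_error(writeCohort(co, d), "not empty")
  expect_silent(writeCohort(co, d, overwrite = TRUE))
  back <- readCohort(d)
  expect_identical(families(back), families(co))
  expect_identical(variantRecords(back)[, 1:8], variantRecords(co)[, 1:8])
  expect_equal(variantRecords(back)$cadd_phred, variantRecords(co)$cadd_phred,
               tolerance = 1e-12)
  expect_equal(tpm(back), tpm(co), tolerance = 1e-12)
  expect_identical(junctionCounts(back), junctionCounts(co))
  expect_identical(geneSets(back), geneSets(co))
  expect_identical(cpGenes(back), cpGenes(co))
  expect_equal(truthRegistry(back)@planted_denovo,
               truthRegistry(co)@planted_denovo)
})

test_that("a null configuration yields no de novo genotype patterns", {
  co <- generateCohort(cohortConfig(seed = 10, n_trios = 6L, n_genes = 40L,
                                    denovo_rate = 0, n_damaging_dnv = 0L,
                                    n_expr_outliers = 0L,
                                    n_splicing_shifts = 0L,
                                    n_pathway_shifts = 0L,
                                    n_clusters = 6L, n_gene_sets = 5L,
                                    genes_per_set = c(5L, 8L),
                                    n_cp_genes = 5L,
                                    n_background_variants_per_trio = 10L))
  rec <- variantRecords(co)
  expect_equal(sum(isDeNovo(rec$gt_proband, rec$gt_father, rec$gt_mother)), 0L)
  expect_equal(nrow(truthRegistry(co)@planted_denovo), 0L)
})

test_that("every planted event exists in the generated data", {
  co <- generateCohort(small_cfg(11))
  tr <- truthRegistry(co)
  rec <- variantRecords(co)
  key <- function(d) paste(d$family_id, d$chrom, d$pos, d$ref, d$alt)
  expect_true(all(key(tr@planted_denovo) %in% key(rec)))
  expect_true(all(tr@planted_expr_outliers$gene %in% rownames(tpm(co))))
  expect_true(all(tr@planted_expr_outliers$sample %in% colnames(tpm(co))))
  cl <- buildClusters(cohortJunctions(co), min_cluster_reads = 0)
  expect_true(all(tr@planted_splicing_shifts$cluster_id %in% cl$cluster_id))
  expect_true(all(tr@planted_pathway_shifts$set_name %in%
                    names(geneSets(co))))
})

test_that("planted damaging flags align with the damaging filter", {
  co <- generateCohort(small_cfg(12))
  tr <- truthRegistry(co)@planted_denovo
  rec <- variantRecords(co)
  key <- function(d) paste(d$family_id, d$chrom, d$pos)
  idx <- match(key(tr), key(rec))
  expect_false(anyNA(idx))
  expect_identical(unname(isDamaging(rec[idx, ])), tr$is_damaging)
})

test_that("inherited alternate alleles are Mendelian-consistent", {
  co <- generateCohort(small_cfg(13))
  rec <- variantRecords(co)
  planted <- paste(rec$family_id, rec$chrom, rec$pos) %in%
    with(truthRegistry(co)@planted_denovo, paste(family_id, chrom, pos))
  inh <- rec[!planted & rec$gt_proband %in% c("het", "hom_alt"), ]
  expect_true(all(inh$gt_father != "hom_ref" | inh$gt_mother != "hom_ref"))
})

test_that("over-subscribed planted events are fatal", {
  expect_error(generateCohort(small_cfg(14, n_pathway_shifts = 50L)),
               "positive|pathway shifts")
  expect_error(
    generateCohort(cohortConfig(seed = 15, n_trios = 8L, n_genes = 80L,
                                n_clusters = 4L, n_splicing_shifts = 40L,
                                n_gene_sets = 8L, genes_per_set = c(5L, 10L),
                                n_cp_genes = 8L)),
    "splicing shifts")
  expect_error(cohortConfig(n_trios = 5L, seed = 1), "at least 6")
  expect_error(cohortConfig(), "seed")
})

test_that("expression outliers are planted at their exact leave-one-out magnitude", {
  co <- generateCohort(small_cfg(16))
  tr <- truthRegistry(co)@planted_expr_outliers
  for (i in seq_len(nrow(tr))) {
    z <- looRobustZ(cohortExpression(co), tr$sample[i], tr$gene[i])$robust_z
    signed <- if (tr$direction[i] == "up") tr$magnitude[i] else -tr$magnitude[i]
    expect_equal(z, signed, tolerance = 1e-6)
  }
})
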