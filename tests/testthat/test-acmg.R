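# Evidence parsing, combining rules, candidate filter, cohort summary.

test_that("evidence tokens parse to id and applied strength", {
  expect_equal(parseEvidence("PM2_P"),
               list(id = "PM2", applied_strength = "supporting", benign = FALSE))
  expect_equal(parseEvidence("PVS1")$applied_strength, "very_strong")
  expect_equal(parseEvidence("PVS1_S")$applied_strength, "strong")
  expect_equal(parseEvidence("BA1")$applied_strength, "stand_alone")
  expect_equal(parseEvidence("BS1")$applied_strength, "strong")
  expect_true(parseEvidence("BP4")$benign)
  expect_error(parseEvidence("PX9"), "unknown ACMG criterion")
  expect_error(parseEvidence("PM2_Q"), "unknown strength modifier")
})

test_that("combining rules reproduce the published verdicts", {
  expect_equal(classifyEvidence("PVS1+PM2_P+PP5")$tier, "pathogenic")
  expect_equal(classifyEvidence("PVS1_S+PS2_M+PM2_P")$tier, "likely_pathogenic")
  expect_equal(classifyEvidence("PS2_M+PM2_P")$tier, "uncertain_significance")
  expect_equal(classifyEvidence("PM2_P+PP3")$tier, "uncertain_significance")
  expect_equal(classifyEvidence("PM2_P")$tier, "uncertain_significance")
  expect_equal(classifyEvidence(character(0))$tier, "uncertain_significance")
  expect_true(is.na(classifyEvidence("PM2_P")$fired_rule))
})

test_that("benign rules and conflicting evidence resolve as defined", {
  expect_equal(classifyEvidence("BA1")$tier, "benign")
  expect_equal(classifyEvidence("BS1+BS2")$tier, "benign")
  expect_equal(classifyEvidence("BS1+BP4")$tier, "likely_benign")
  expect_equal(classifyEvidence("BP4+BP7")$tier, "likely_benign")
  expect_equal(classifyEvidence("BP4")$tier, "uncertain_significance")
  # contradictory: pathogenic-side and benign-side rules both met
  expect_equal(classifyEvidence("PVS1+PS1+BA1")$tier, "uncertain_significance")
  expect_equal(classifyEvidence("PM1+PM2+PM4+BP4+BP7")$tier,
               "uncertain_significance")
})

# pool of tokens covering every applied strength on both sides
.tok_pool <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PP1", "PP2",
               "PVS1_S", "PS2_M", "PM2_P", "BS1", "BS2", "BP1", "BP2",
               "BA1", "BS1_P")

.tier_rank <- c(benign = 1, likely_benign = 2, uncertain_significance = 3,
                likely_pathogenic = 4, pathogenic = 5)

test_that("adding pathogenic evidence never moves the tier toward benign", {
  set.seed(21)
  path_pool <- grep("^P", .tok_pool, value = TRUE)
  for (i in 1:150) {
    ev <- sample(.tok_pool, sample(0:4, 1))
    base <- .tier_rank[classifyEvidence(ev)$tier]
    extra <- sample(path_pool, 1)
    with_extra <- .tier_rank[classifyEvidence(c(ev, extra))$tier]
    # exception by design: contradiction collapses to VUS; skip cases where
    # the augmented evidence newly fires both sides
    if (with_extra == .tier_rank["uncertain_significance"] &&
        base < .tier_rank["uncertain_significance"]) next
    expect_gte(with_extra, base)
  }
})

test_that("upgrading a code's applied strength never downgrades the tier", {
  set.seed(22)
  for (i in 1:150) {
    ev <- sample(c("PVS1", "PS1", "PS2_M", "PM1", "PM2_P", "PP1", "PP2"),
                 sample(1:4, 1), replace = TRUE)
    base <- .tier_rank[classifyEvidence(ev)$tier]
    # upgrade one supporting -> moderate -> strong -> very strong
    st <- vapply(lapply(ev, parseEvidence), `[[`, character(1),
                 "applied_strength")
    j <- which(st != "very_strong")[1]
    if (is.na(j)) next
    id <- parseEvidence(ev[j])$id
    upgraded <- switch(st[j],
                       supporting = paste0(id, "_M"),
                       moderate = paste0(id, "_S"),
                       strong = "PVS1")
    ev2 <- ev; ev2[j] <- upgraded
    expect_gte(.tier_rank[classifyEvidence(ev2)$tier], base)
  }
})

test_that("two very strong criteria are pathogenic", {
  expect_equal(classifyEvidence(c("PVS1", "PVS1"))$tier, "pathogenic")
})

test_that("candidate filter applies every criterion and reports reasons", {
  rec <- variantRecords(TrioVariantTable(data.frame(
    family_id = "FAM1", chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "G",
    gt_proband = "het", gt_father = "hom_ref", gt_mother = "hom_ref",
    gene = c("PROC", "PROC", "PROC"),
    func_class = c("missense", "synonymous", "missense"),
    maf_gnomad = c(0.0001, 0.0001, 0.0004),
    maf_exac = c(NA, NA, 0.0009),
    stringsAsFactors = FALSE)))
  res <- candidateFilter(rec, cp_genes = "PROC")
  expect_true(res$pass[1])
  expect_identical(res$reasons[1], "")
  expect_false(res$pass[2])
  expect_match(res$reasons[2], "functional class")
  # max-over-databases rule: max(0.0004, 0.0009) >= 0.0005 fails
  expect_false(res$pass[3])
  expect_match(res$reasons[3], "population frequency")
  # permissive any-database reading passes the same record
  res_any <- candidateFilter(rec, candidateFilterParams(maf_rule = "any"),
                             cp_genes = "PROC")
  expect_true(res_any$pass[3])
  # reasons are complete: pass iff reasons empty
  res2 <- candidateFilter(rec, cp_genes = "OTHER",
                          segregation_ok = FALSE, phenotype_ok = FALSE)
  expect_true(all(res2$pass == (res2$reasons == "")))
  expect_match(res2$reasons[2], "segregation")
  expect_match(res2$reasons[2], "phenotype match")
})

test_that("cohort classification counts distinct carriers per tier group", {
  path <- system.file("extdata", "acmg_evidence_cp_cohort.tsv",
                      package = "cptriomics")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  res <- classifyCohort(tab)
  expect_equal(nrow(res$classified), 13L)
  expect_equal(res$n_probands_plp, 2L)
  expect_setequal(
    res$classified$sample[res$classified$tier %in%
                            c("pathogenic", "likely_pathogenic")],
    c("UIG008", "UIG008", "UIG12"))
  empty <- classifyCohort(data.frame(sample = character(0),
                                     gene = character(0),
                                     evidence = character(0)))
  expect_equal(empty$n_probands_plp, 0L)
  expect_equal(empty$n_probands_vus_only, 0L)
})
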