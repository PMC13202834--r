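# Shared fixture builders. Everything is generated in code; nothing binary.

# expression matrix from a genes x samples numeric matrix of log2 values:
# converts to TPM so that log2(TPM + 1) reproduces the given values exactly
em_from_log2 <- function(log2m) {
  ExpressionMatrix(pmax(2^log2m - 1, 0))
}

random_em <- function(n_genes = 50, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n_genes * n_samples, meanlog = 2, sdlog = 0.4),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  ExpressionMatrix(m)
}

# minimal trio pedigree
tiny_pedigree <- function(n = 1) {
  Pedigree(data.frame(
    family_id = sprintf("FAM%d", seq_len(n)),
    proband_id = sprintf("P%d", seq_len(n)),
    father_id = sprintf("F%d", seq_len(n)),
    mother_id = sprintf("M%d", seq_len(n)),
    sex = "male", affected = "yes", stringsAsFactors = FALSE))
}

# write a minimal VCF for the given sites; gts is a list of named character
# vectors (sample -> GT string) parallel to sites rows
write_tiny_vcf <- function(path, sites, gts, samples) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(sites))) {
    gt <- vapply(samples, function(s)
      if (s %in% names(gts[[i]])) gts[[i]][[s]] else "0/0", character(1))
    lines <- c(lines, paste(c(sites$chrom[i], sites$pos[i], ".",
                              sites$ref[i], sites$alt[i], ".", "PASS", ".",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# junction table from a data.frame(chrom,start,end,strand) and count matrix
jt_from_df <- function(df, counts) {
  colnames(counts) <- colnames(counts) %||% sprintf("s%02d", seq_len(ncol(counts)))
  JunctionTable(counts, GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force BH step-up, straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small null cohort config for splicing calibration runs: only the junction
# layer matters, the rest is minimized for speed
null_splice_config <- function(seed, n_clusters = 30L) {
  cohortConfig(seed = seed, n_trios = 27L, n_genes = 60L, n_gene_sets = 5L,
               genes_per_set = c(5L, 8L),
               n_background_variants_per_trio = 1L, denovo_rate = 0,
               n_damaging_dnv = 0L, n_expr_outliers = 0L,
               n_splicing_shifts = 0L, n_pathway_shifts = 0L,
               n_clusters = n_clusters, n_cp_genes = 5L)
}

# independent enumeration oracle built from choose(), not dhyper
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  pr <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# independent straight-line implementation of the weighted KS walk
walk_oracle <- function(stat_col, member, tau = 1) {
  ord <- order(stat_col, decreasing = TRUE)
  cum <- 0; best_up <- 0; best_dn <- 0
  w_tot <- sum(abs(stat_col[member])^tau)
  n_out <- sum(!member)
  for (g in ord) {
    cum <- cum + if (member[g]) abs(stat_col[g])^tau / w_tot else -1 / n_out
    best_up <- max(best_up, cum)
    best_dn <- min(best_dn, cum)
  }
  best_up + best_dn
}
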