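test_that("SNP-to-gene windows are inclusive at 50 kb", {
  genes <- gene_annotation(c("gA", "gB"), c("1", "1"),
                           c(100000L, 100500L), c(101000L, 102000L))
  ss <- toy_summary(3, pos = c(50000L, 49999L, 100700L), pvalue = rep(0.5, 3))
  m <- map_snps_to_genes(ss, genes)
  expect_true("rs001" %in% m$gA)      # boundary: 100000 - 50000
  expect_false("rs002" %in% m$gA)     # one bp outside
  expect_true(all(c("gA", "gB") %in%
                  names(Filter(function(x) "rs003" %in% x, m))))

  # non-autosomal genes are not mapped
  genes_x <- gene_annotation("gX", "X", 100L, 200L)
  expect_length(map_snps_to_genes(toy_summary(1, pos = 150L, chrom = "X"),
                                  genes_x), 0)
})

test_that("LD matrices match brute-force correlation and stay PSD", {
  set.seed(21)
  dos <- matrix(sample(0:2, 5 * 80, replace = TRUE), 5, 80,
                dimnames = list(sprintf("rs%d", 1:5), NULL))
  geno <- genotype_ref(dos)
  ld <- ld_matrix(geno, rownames(dos))
  brute <- cor(t(dos))
  expect_equal(max(abs(ld$corr - brute)), 0, tolerance = 1e-12)
  expect_equal(diag(ld$corr), setNames(rep(1, 5), rownames(dos)))
  expect_true(min(eigen(ld$corr, TRUE, TRUE)$values) >= -1e-12)

  # one SNP
  expect_equal(unname(ld_matrix(geno, "rs1")$corr), matrix(1))
  # identical dosage vectors give off-diagonal 1
  geno2 <- genotype_ref(rbind(a = dos[1, ], b = dos[1, ]))
  expect_equal(unname(ld_matrix(geno2, c("a", "b"))$corr[1, 2]), 1)
  # zero-variance SNPs are dropped with a warning
  geno3 <- genotype_ref(rbind(dos, flat = rep(1, 80)))
  expect_warning(ld3 <- ld_matrix(geno3, c("rs1", "flat")), "zero-variance")
  expect_identical(ld3$snp_ids, "rs1")
  expect_error(ld_matrix(geno, "nope"), "absent")
})

test_that("gene P-values reduce to closed forms in degenerate LD", {
  one <- structure(list(snp_ids = "rs1", corr = matrix(1, 1, 1)),
                   class = "ld_matrix")
  expect_equal(gene_pvalue_sum(0.01, one), 0.01, tolerance = 1e-12)

  k <- 5
  iden <- structure(list(snp_ids = paste0("rs", 1:k), corr = diag(k)),
                    class = "ld_matrix")
  p <- c(0.2, 0.01, 0.6, 0.35, 0.08)
  tstat <- sum(qchisq(p, 1, lower.tail = FALSE))
  expect_equal(gene_pvalue_sum(p, iden),
               pchisq(tstat, df = k, lower.tail = FALSE), tolerance = 1e-8)

  perfect <- structure(list(snp_ids = paste0("rs", 1:k),
                            corr = matrix(1, k, k)), class = "ld_matrix")
  expect_equal(gene_pvalue_sum(p, perfect),
               pchisq(tstat / k, df = 1, lower.tail = FALSE),
               tolerance = 1e-8)

  expect_error(gene_pvalue_sum(c(0.1, 0.2), one), "!=")
  expect_error(gene_pvalue_sum(0, one), "0, 1")
})

test_that("the weighted chi-square tail is monotone and bounded", {
  set.seed(31)
  R <- cov2cor(crossprod(matrix(rnorm(16), 4)) + diag(4) * 0.05)
  ld <- structure(list(snp_ids = paste0("rs", 1:4), corr = R),
                  class = "ld_matrix")
  base <- c(0.3, 0.2, 0.5, 0.4)
  p0 <- gene_pvalue_sum(base, ld)
  for (i in 1:4) {
    shrunk <- base
    shrunk[i] <- base[i] / 10
    expect_lte(gene_pvalue_sum(shrunk, ld), p0)
  }
  lam <- eigen(R, TRUE, TRUE)$values
  expect_equal(weighted_chisq_tail(0, lam), 1)
  expect_lt(weighted_chisq_tail(500, lam), 1e-30)
})

test_that("null gene P-values are uniform under simulated LD", {
  cfg <- sim_config(seed = 7, n_genes = 2000L, n_causal_genes = 0L,
                    n_ref_samples = 300L, n_snps_per_gene = 4L)
  genes <- gen_gene_annotation(cfg)
  geno <- gen_genotypes(cfg)
  ss <- gen_summary_stats(cfg, geno, genes, tseakit:::sim_truth(cfg))
  gs <- score_study(ss, genes, geno, gene_score_config(min_genes = 100L))
  pv <- gs$table$pvalue[gs$table$status == "ok"]
  expect_length(pv, 2000)
  d <- suppressWarnings(ks.test(pv, "punif"))$statistic
  expect_lt(unname(d), 1.628 / sqrt(length(pv)))  # 1% critical value
})

test_that("study scoring tracks coverage and the success threshold", {
  cfg <- small_sim_config(seed = 4, n_genes = 50L, n_causal_genes = 2L)
  sim <- simulate_study(cfg)
  gs <- score_study(sim$ss, sim$genes, sim$geno,
                    gene_score_config(min_genes = 40L))
  expect_equal(gs$n_success, 50L)
  expect_true(gs$qualified)

  # a gene whose only SNP is absent from the reference fails
  genes2 <- rbind(sim$genes,
                  gene_annotation("orphan", "22", 90e6, 90001e3))
  ss2 <- sim$ss
  ss2$records <- rbind(ss2$records,
                       data.frame(snp_id = "rs_orphan", chrom = "22",
                                  pos = 90000500L, effect_allele = "A",
                                  other_allele = "G", maf = 0.2, effect = 0,
                                  se = 0.01, pvalue = 0.5, n = 1000L))
  gs2 <- score_study(ss2, genes2, sim$geno, gene_score_config(min_genes = 40L))
  expect_identical(gs2$table$status[gs2$table$gene_id == "orphan"], "failed")
  expect_equal(gs2$n_success, 50L)

  # one success short of the configured threshold disqualifies the study
  gs_strict <- score_study(sim$ss, sim$genes, sim$geno,
                           gene_score_config(min_genes = 51L))
  expect_false(gs_strict$qualified)
})
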