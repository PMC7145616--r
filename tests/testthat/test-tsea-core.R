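test_that("TAG sets qualify strictly between 20 and 3000 genes", {
  gs <- toy_gene_scores(c(runif(19, 0, 9e-6), runif(3500, 0.2, 1)))
  tags <- make_tag_sets(gs)
  expect_false(tags$sets[["0.00001"]]$qualified)      # 19 genes
  expect_equal(length(tags$sets[["0.00001"]]$genes), 19)

  gs20 <- toy_gene_scores(c(runif(20, 0, 9e-6), runif(3500, 0.2, 1)))
  expect_true(make_tag_sets(gs20)$sets[["0.00001"]]$qualified)

  gs_big <- toy_gene_scores(runif(3001, 0.001, 0.049))
  expect_false(make_tag_sets(gs_big)$sets[["0.05"]]$qualified)  # 3001 genes
  gs_ok <- toy_gene_scores(c(runif(3000, 0.001, 0.049), runif(100, 0.5, 1)))
  expect_true(make_tag_sets(gs_ok)$sets[["0.05"]]$qualified)    # 3000 genes

  # membership uses strict inequality
  gs_edge <- toy_gene_scores(c(0.05, rep(0.5, 30)))
  expect_false("G00001" %in% make_tag_sets(gs_edge)$sets[["0.05"]]$genes)

  # failed genes never enter a TAG set
  gs_f <- toy_gene_scores(c(1e-7, rep(0.5, 30)), failed = "G00002")
  expect_false("G00002" %in% make_tag_sets(gs_f)$sets[["0.05"]]$genes)
})

test_that("TAG sets are nested across all five thresholds", {
  set.seed(41)
  for (rep in 1:5) {
    gs <- toy_gene_scores(10^runif(500, -8, 0))
    tags <- make_tag_sets(gs)
    for (i in seq_along(tags$sets)[-1])
      expect_true(all(tags$sets[[i]]$genes %in% tags$sets[[i - 1]]$genes))
  }
})

test_that("chi-square enrichment matches the textbook 2x2 computation", {
  universe <- sprintf("g%04d", 1:1000)
  tis <- universe[1:50]
  tag <- c(tis[1:20], universe[301:380])           # overlap 20
  r <- chi2_enrichment(tag, tis, universe)
  # independent oracle: Pearson statistic from the printed margins
  o <- chisq.test(matrix(c(20, 80, 30, 870), 2), correct = FALSE)
  expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-10)
  expect_equal(r$pvalue, unname(o$p.value) / 2, tolerance = 1e-10)
  expect_equal(r$expected, 100 * 50 / 1000)
  expect_equal(r$overlap, 20)

  # overlap equal to expectation gives P = 0.5
  tag2 <- c(tis[1:5], universe[101:195])           # overlap 5 = expected
  expect_equal(chi2_enrichment(tag2, tis, universe)$pvalue, 0.5)

  # depletion lands above 0.5
  tag3 <- universe[101:200]
  expect_gt(chi2_enrichment(tag3, tis, universe)$pvalue, 0.5)

  expect_error(chi2_enrichment(character(0), tis, universe), "empty TAG")
  expect_error(chi2_enrichment(tag, tis, character(0)), "empty universe")
})

test_that("one-sided chi-square and Fisher agree when expected cells are large", {
  universe <- sprintf("g%05d", 1:2000)
  tis <- universe[1:200]
  for (ov in c(15, 20, 25, 30, 40)) {
    tag <- c(tis[seq_len(ov)], universe[500:(500 + 200 - ov - 1)])
    r <- chi2_enrichment(tag, tis, universe)
    f <- fisher.test(matrix(c(ov, 200 - ov, 200 - ov, 2000 - 400 + ov), 2),
                     alternative = "greater")$p.value
    # Fisher's exact test is discrete and conservative, so only loose
    # absolute agreement is expected
    expect_lt(abs(r$pvalue - f), 0.05)
    # direction agreement with the hypergeometric tail
    expect_identical(r$pvalue < 0.5, r$overlap > r$expected)
  }
})

test_that("enrichment scans every tissue at every qualified threshold", {
  sim <- simulate_study(small_sim_config(seed = 12))
  gs <- score_study(sim$ss, sim$genes, sim$geno,
                    gene_score_config(min_genes = 100L))
  tags <- make_tag_sets(gs)
  spec <- score_panel(sim$panel)
  sets <- top_fraction_sets(spec)
  universe <- intersect(gs$table$gene_id[gs$table$status == "ok"],
                        rownames(spec$scores))
  res <- run_tsea(tags, sets, universe)
  qualified <- names(Filter(function(s) s$qualified, tags$sets))
  unqualified <- setdiff(names(tags$sets), qualified)
  expect_true(all(!is.na(res$pvalues[, qualified])))
  expect_true(all(is.na(res$pvalues[, unqualified])))
  # the planted tissue attains the minimum P at every qualified threshold
  for (thr in qualified)
    expect_identical(names(which.min(res$pvalues[, thr])), "T01")

  # single-tissue specificity sets give a one-row matrix
  sets1 <- sets
  sets1$sets <- sets1$sets["T02"]
  expect_equal(nrow(run_tsea(tags, sets1, universe)$pvalues), 1L)
})

test_that("top-tissue selection ranks by minimum P with stated tie-breaks", {
  mk <- function(pv, ov) {
    structure(list(study_id = "s", panel_id = "p", pvalues = pv,
                   overlap = ov, expected = ov, counts = list()),
              class = "tsea_result")
  }
  pv <- matrix(c(0.001, 0.01, 0.5, 0.2, 0.05, 0.9), 3, 2,
               dimnames = list(c("t1", "t2", "t3"), c("a", "b")))
  ov <- matrix(5, 3, 2, dimnames = dimnames(pv))
  expect_identical(select_top_tissues(mk(pv, ov), 3), c("t1", "t2", "t3"))
  expect_identical(select_top_tissues(mk(pv, ov), 2), c("t1", "t2"))
  # tie on P broken by larger overlap, then name
  pv2 <- matrix(c(0.01, 0.01, 0.01), 3, 1,
                dimnames = list(c("t1", "t2", "t3"), "a"))
  ov2 <- matrix(c(1, 7, 1), 3, 1, dimnames = dimnames(pv2))
  expect_identical(select_top_tissues(mk(pv2, ov2), 2), c("t2", "t1"))
  # k beyond the tissue count returns everything
  expect_length(select_top_tissues(mk(pv2, ov2), 10), 3)
})

test_that("GSEA scores a top-ranked set at ES = 1 with minimal permutation P", {
  scores <- setNames(seq(5, 0.5, length.out = 30), sprintf("g%02d", 1:30))
  tag <- names(sort(scores, decreasing = TRUE))[1:5]
  g <- gsea_validate(scores, tag, n_perm = 2000L, seed = 3)
  expect_equal(g$es, 1)
  expect_equal(g$perm_p, 1 / 2001)
  expect_gt(g$nes, 1)
  expect_setequal(g$leading_edge, tag)
  expect_identical(sign(g$nes), sign(g$es))
})

test_that("Monte-Carlo permutation P matches exhaustive enumeration", {
  set.seed(8)
  scores <- setNames(sort(rnorm(10, 2, 1), decreasing = TRUE),
                     sprintf("g%02d", 1:10))
  tag <- c("g03", "g07")
  g <- gsea_validate(scores, tag, n_perm = 4000L, seed = 11)
  # enumerate all 45 placements of a 2-gene set
  w <- abs(scores)
  combos <- combn(10, 2)
  es_all <- apply(combos, 2, function(ix) tseakit:::running_es(sort(ix), w, 10))
  same <- es_all[sign(es_all) == sign(g$es)]
  exact <- sum(abs(same) >= abs(g$es)) / length(es_all)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(g$perm_p - exact), 3 * se + 1 / 4000)
  expect_gte(g$perm_p, 1 / 4001)
})

test_that("enrichment scores agree with the fgsea statistic", {
  set.seed(19)
  scores <- setNames(sort(rnorm(200), decreasing = TRUE),
                     sprintf("g%03d", 1:200))
  for (m in c(5, 20)) {
    tag <- sample(names(scores), m)
    g <- gsea_validate(scores, tag, n_perm = 10L, seed = 1)
    ref <- fgsea::calcGseaStat(scores, selectedStats = sort(match(tag, names(scores))),
                               gseaParam = 1, scoreType = "std")
    expect_equal(g$es, ref, tolerance = 1e-10)
  }
})

test_that("random TAG sets give NES near one in magnitude", {
  set.seed(23)
  scores <- setNames(sort(rnorm(150, 1, 2), decreasing = TRUE),
                     sprintf("g%03d", 1:150))
  nes <- replicate(40, {
    g <- gsea_validate(scores, sample(names(scores), 12), n_perm = 300L,
                       seed = sample.int(1e6, 1))
    abs(g$nes)
  })
  expect_equal(mean(nes), 1, tolerance = 0.25)
})
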