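test_that("summary statistics parse, drop bad rows, and round-trip", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ss.tsv")
  writeLines(c("snp_id\tchrom\tpos\tmaf\tpvalue",
               "rs1\tchr1\t100\t0.2\t3.2e-08",
               "rs2\t2\t200\t0.3\tNA",
               "rs3\tX\t300\t0.1\t0.5",
               "rs4\t4\t400\t0.4\t1.0",
               "rs5\t5\t500\t0.2\t0.07"), tsv)
  ss <- read_summary_stats(tsv)
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss$records), 4)                 # rs2 dropped
  expect_equal(unname(ss$drop_counts["bad_pvalue"]), 1)
  expect_identical(ss$records$pvalue[1], 3.2e-08)   # scientific notation
  expect_identical(ss$records$chrom, c("1", "X", "4", "5"))

  out <- file.path(d, "out.tsv")
  write_summary_stats(ss, out)
  ss2 <- read_summary_stats(out, study_id = ss$study_id)
  expect_identical(ss$records$snp_id, ss2$records$snp_id)
  expect_identical(ss$records$pvalue, ss2$records$pvalue)
  expect_identical(ss$records$pos, ss2$records$pos)
  expect_true(file.exists(paste0(out, ".json")))
})

test_that("summary-stat reader enforces its contracts", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ss.tsv")
  writeLines(c("snp\tchr\tbp\tp", "rs1\t1\t100\t0.5"), tsv)
  expect_error(read_summary_stats(tsv), "not found")
  expect_error(read_summary_stats(tsv, column_map = c(snp_id = "snp")),
               "column_map")
  cm <- c(snp_id = "snp", chrom = "chr", pos = "bp", pvalue = "p")
  ss <- read_summary_stats(tsv, column_map = cm)
  expect_equal(nrow(ss$records), 1)
  empty <- file.path(d, "empty.tsv")
  writeLines("snp_id\tchrom\tpos\tpvalue", empty)
  expect_error(read_summary_stats(empty))
})

test_that("column maps load from YAML", {
  d <- withr::local_tempdir()
  yml <- file.path(d, "map.yaml")
  writeLines(c("snp_id: SNP", "chrom: CHR", "pos: BP", "pvalue: P"), yml)
  cm <- read_column_map(yml)
  expect_identical(cm[["snp_id"]], "SNP")
  expect_identical(cm[["pvalue"]], "P")
})

test_that("BED and GFF encodings of one locus agree after normalization", {
  d <- withr::local_tempdir()
  bed <- file.path(d, "g.bed")
  writeLines("chr1\t999\t2000\tG1\t0\t+", bed)
  gff <- file.path(d, "g.gff")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=G1;Name=G1"), gff)
  b <- read_gene_annotation(bed, "bed")
  g <- read_gene_annotation(gff, "gff")
  expect_equal(b$start, 1000)   # 0-based half-open converted
  expect_equal(b$end, 2000)
  expect_identical(b[, c("gene_id", "chrom", "start", "end", "strand")],
                   g[, c("gene_id", "chrom", "start", "end", "strand")])
  expect_true(b$autosomal)
})

test_that("non-autosomal genes are retained but flagged", {
  ann <- gene_annotation(c("g1", "g2", "g3"), c("1", "chrX", "MT"),
                         c(10, 10, 10), c(20, 20, 20))
  expect_identical(ann$autosomal, c(TRUE, FALSE, FALSE))
  expect_error(gene_annotation("g", "1", 30, 20), "start > end")
})

test_that("chromosome labels normalize consistently", {
  expect_identical(normalize_chrom(c("chr1", "CHRX", "chrM", "22", "y")),
                   c("1", "X", "MT", "22", "Y"))
  expect_identical(is_autosome(c("chr22", "X", "chr23")),
                   c(TRUE, FALSE, FALSE))
})

test_that("expression panels validate their labels and gene IDs", {
  d <- withr::local_tempdir()
  expr <- file.path(d, "e.tsv"); labs <- file.path(d, "l.tsv")
  m <- matrix(1:60, 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  write.table(data.frame(gene_id = rownames(m), m), expr, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(m),
                         tissue = rep(c("A", "B", "C"), each = 2)),
              labs, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- read_expression_panel(expr, labs)
  expect_equal(length(unique(p$sample_tissue)), 3)
  expect_equal(dim(p$expr), c(10, 6))

  # a sample missing from the labels is a configuration error
  write.table(data.frame(sample = colnames(m)[-6],
                         tissue = rep(c("A", "B", "C"), c(2, 2, 1))),
              labs, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression_panel(expr, labs), "s6")

  # duplicated gene rows are rejected by name
  m2 <- rbind(m, m[1, , drop = FALSE])
  st <- setNames(rep(c("A", "B", "C"), each = 2), colnames(m))
  expect_error(expression_panel(m2, st), "g01")
})

test_that("VCF and dosage genotypes load into the same container", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "r.vcf")
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t0|0\t0/1\t1/1"), vcf)
  g <- read_genotype_ref(vcf)
  expect_equal(unname(g$dosages["rs1", ]), c(1, 2, 0))
  expect_equal(unname(g$dosages["rs2", ]), c(0, 1, 2))

  dos <- file.path(d, "d.tsv")
  write.table(data.frame(snp_id = c("rs1", "rs2"),
                         S1 = c(1, 0), S2 = c(2, 1), S3 = c(0, 2)),
              dos, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_genotype_ref(dos)
  expect_equal(g$dosages, g2$dosages, ignore_attr = TRUE)
})
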