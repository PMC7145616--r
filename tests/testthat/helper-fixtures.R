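# Shared fixture builders: everything is generated in code at test time.

# summary stats with controllable fields
toy_summary <- function(n = 5, pvalue = NULL, chrom = "1", maf = 0.3,
                        pos = NULL, snp_id = NULL, study_id = "toy") {
  if (is.null(pvalue)) pvalue <- seq(0.1, 0.9, length.out = n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(snp_id)) snp_id <- sprintf("rs%03d", seq_len(n))
  summary_stats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                           maf = maf, pvalue = pvalue,
                           stringsAsFactors = FALSE),
                study_id = study_id)
}

# a gene-score table with given P-values (all status ok unless failed given)
toy_gene_scores <- function(pvalues, study_id = "toy",
                            failed = character(0)) {
  ids <- sprintf("G%05d", seq_along(pvalues))
  tab <- data.frame(gene_id = ids, n_snps = 1L, pvalue = pvalues,
                    status = "ok", stringsAsFactors = FALSE)
  tab$status[tab$gene_id %in% failed] <- "failed"
  tab$pvalue[tab$status == "failed"] <- NA_real_
  structure(list(study_id = study_id, table = tab,
                 n_success = sum(tab$status == "ok"),
                 qualified = TRUE),
            class = "gene_score_table")
}

# standard small synthetic study used across end-to-end tests
small_sim_config <- function(seed, ...) {
  args <- list(seed = seed, n_genes = 300L, n_causal_genes = 15L,
               n_ref_samples = 300L, n_snps_per_gene = 4L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

small_study_config <- function(...) {
  args <- list(qc = qc_config(min_variants = 100L),
               gene_score = gene_score_config(min_genes = 100L),
               n_perm = 300L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(study_config, args)
}

# tiny deterministic expression panel: 2 tissues x n_per samples
toy_panel <- function(n_genes = 40, n_per = 10, n_tissues = 2, sd = 1,
                      seed = 1) {
  set.seed(seed)
  tissues <- LETTERS[seq_len(n_tissues)]
  n_samp <- n_per * n_tissues
  le <- matrix(rnorm(n_genes * n_samp, 5, sd), n_genes, n_samp,
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               sprintf("s%03d", seq_len(n_samp))))
  st <- setNames(rep(tissues, each = n_per), colnames(le))
  expression_panel(pmax(2^le - 1, 0), st, panel_id = "toy_panel")
}
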