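# Seeded synthetic inputs with known ground truth: an expression panel with
# planted tissue-specific genes, LD-structured reference genotypes, and GWAS
# summary statistics simulated directly at the z-score level (multivariate
# normal with the block LD as covariance), with association signal planted
# in the genes specific to one target tissue.

#' Simulation configuration
#'
#' Defaults describe a small but realistic study: a five-tissue panel with
#' 30 samples per tissue (enough for t-scores), tissue-specific genes
#' shifted by 4 log2-units, five SNPs per gene in compound-symmetric LD
#' blocks (rho = 0.5), and causal genes whose SNPs carry a mean per-SNP
#' non-centrality of 5 standard errors.
#'
#' @param seed integer RNG seed; per-component streams are derived from it
#'   deterministically.
#' @param n_genes number of genes (default 1000).
#' @param n_tissues number of tissues (default 5, labelled T01, T02, ...).
#' @param n_samples_per_tissue expression samples per tissue (default 30).
#' @param specificity_effect mean log2-expression shift of a planted gene in
#'   its tissue (default 4).
#' @param n_snps_per_gene SNPs per gene block (default 5).
#' @param ld_block_rho within-block latent correlation in [0, 1)
#'   (default 0.5).
#' @param n_causal_genes genes of the causal tissue carrying association
#'   signal; must not exceed floor(0.05 * n_genes) so planted genes fit the
#'   top-5 percent tissue sets (default 30).
#' @param causal_tissue tissue whose specific genes are causal
#'   (default "T01").
#' @param gwas_n GWAS sample size reported per SNP (default 50000).
#' @param noncentrality mean per-SNP non-centrality (in z-score units) of
#'   causal SNPs (default 5).
#' @param effect_sd standard deviation of the per-SNP non-centrality
#'   (default 1).
#' @param n_ref_samples individuals in the LD reference panel (default 500).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_tissues = 5L,
                       n_samples_per_tissue = 30L, specificity_effect = 4,
                       n_snps_per_gene = 5L, ld_block_rho = 0.5,
                       n_causal_genes = 30L, causal_tissue = "T01",
                       gwas_n = 50000L, noncentrality = 5, effect_sd = 1,
                       n_ref_samples = 500L) {
  if (n_causal_genes > floor(0.05 * n_genes))
    stop("n_causal_genes must be <= floor(0.05 * n_genes)")
  if (ld_block_rho < 0 || ld_block_rho >= 1)
    stop("ld_block_rho must lie in [0, 1)")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tissues = as.integer(n_tissues),
                 n_samples_per_tissue = as.integer(n_samples_per_tissue),
                 specificity_effect = specificity_effect,
                 n_snps_per_gene = as.integer(n_snps_per_gene),
                 ld_block_rho = ld_block_rho,
                 n_causal_genes = as.integer(n_causal_genes),
                 causal_tissue = causal_tissue,
                 gwas_n = as.integer(gwas_n),
                 noncentrality = noncentrality, effect_sd = effect_sd,
                 n_ref_samples = as.integer(n_ref_samples)),
            class = "sim_config")
}

sim_tissue_names <- function(cfg) sprintf("T%02d", seq_len(cfg$n_tissues))
sim_gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
sim_snp_ids <- function(cfg)
  sprintf("rs%06d", seq_len(cfg$n_genes * cfg$n_snps_per_gene))

#' Synthetic gene annotation
#'
#' Genes of 10 kb are laid out across the 22 autosomes, 2 Mb apart on each
#' chromosome so that 50 kb SNP-to-gene windows never overlap.
#'
#' @param cfg a [sim_config()].
#' @return a \code{gene_annotation} data.frame of \code{cfg$n_genes} genes.
#' @export
gen_gene_annotation <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  chrom <- as.character(((g - 1L) %% 22L) + 1L)
  slot <- (g - 1L) %/% 22L
  start <- 1e6 + slot * 2e6
  gene_annotation(sim_gene_ids(cfg), chrom, start, start + 1e4 - 1)
}

# planted tissue-specific genes: n_causal_genes genes per tissue, disjoint,
# assigned in gene-ID order
sim_truth <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  tissues <- sim_tissue_names(cfg)
  per <- cfg$n_causal_genes
  if (per * cfg$n_tissues > cfg$n_genes)
    stop("not enough genes to plant specific sets for every tissue")
  truth <- lapply(seq_along(tissues), function(i)
    ids[((i - 1L) * per + 1L):(i * per)])
  names(truth) <- tissues
  truth
}

#' Generate a synthetic expression panel with planted specific genes
#'
#' Baseline log2-expression is i.i.d. normal(5, 1); each planted gene gains
#' \code{specificity_effect} log2-units in its tissue. The stored expression
#' is on the raw scale (2^log2 - 1) so the scoring transform recovers the
#' simulated values.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{panel} (an \code{expression_panel}) and
#'   \code{truth} (tissue -> planted gene IDs).
#' @export
gen_expression_panel <- function(cfg) {
  set.seed(cfg$seed + 11L)
  tissues <- sim_tissue_names(cfg)
  genes <- sim_gene_ids(cfg)
  n_samp <- cfg$n_tissues * cfg$n_samples_per_tissue
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  sample_tissue <- stats::setNames(rep(tissues,
                                       each = cfg$n_samples_per_tissue),
                                   sample_ids)
  le <- matrix(stats::rnorm(cfg$n_genes * n_samp, mean = 5, sd = 1),
               nrow = cfg$n_genes, dimnames = list(genes, sample_ids))
  truth <- sim_truth(cfg)
  for (tt in tissues) {
    cols <- sample_tissue == tt
    le[truth[[tt]], cols] <- le[truth[[tt]], cols] + cfg$specificity_effect
  }
  expr <- pmax(2^le - 1, 0)
  list(panel = expression_panel(expr, sample_tissue,
                                panel_id = sprintf("sim_panel_seed%d",
                                                   cfg$seed)),
       truth = truth)
}

# compound-symmetric correlation matrix
cs_corr <- function(k, rho) {
  r <- matrix(rho, k, k)
  diag(r) <- 1
  r
}

#' Generate LD-structured reference genotypes
#'
#' One LD block per gene: two latent Gaussian haplotypes per individual with
#' within-block correlation \code{ld_block_rho} are thresholded to alleles
#' at a minor allele frequency drawn uniform(0.06, 0.5) per SNP (so every
#' SNP survives the MAF > 0.05 keep-rule); dosage is the allele sum. The
#' drawn MAFs are attached as attribute \code{"maf"}.
#'
#' @param cfg a [sim_config()].
#' @return a \code{genotype_ref} of
#'   \code{n_genes * n_snps_per_gene} SNPs x \code{n_ref_samples} samples.
#' @export
gen_genotypes <- function(cfg) {
  set.seed(cfg$seed + 23L)
  k <- cfg$n_snps_per_gene
  ns <- cfg$n_ref_samples
  ch <- chol(cs_corr(k, cfg$ld_block_rho))
  snp_ids <- sim_snp_ids(cfg)
  mafs <- stats::runif(length(snp_ids), 0.06, 0.5)
  dos <- matrix(NA_real_, length(snp_ids), ns,
                dimnames = list(snp_ids,
                                sprintf("I%04d", seq_len(ns))))
  for (g in seq_len(cfg$n_genes)) {
    rows <- ((g - 1L) * k + 1L):(g * k)
    thr <- stats::qnorm(1 - mafs[rows])
    hap1 <- matrix(stats::rnorm(ns * k), ns, k) %*% ch
    hap2 <- matrix(stats::rnorm(ns * k), ns, k) %*% ch
    dos[rows, ] <- t((sweep(hap1, 2, thr, ">")) + (sweep(hap2, 2, thr, ">")))
  }
  geno <- genotype_ref(dos)
  attr(geno, "maf") <- stats::setNames(mafs, snp_ids)
  geno
}

#' Generate synthetic GWAS summary statistics
#'
#' Per-gene SNP z-scores are drawn from a multivariate normal whose
#' covariance is the block's empirical LD (from the reference genotypes).
#' Non-causal blocks have mean zero; for a causal block the mean is
#' LD x delta, with per-SNP non-centrality delta ~
#' normal(noncentrality, effect_sd^2). Z-scores are converted to two-sided
#' P-values and to effect/SE via effect = z / sqrt(gwas_n).
#'
#' @param cfg a [sim_config()].
#' @param geno genotypes from [gen_genotypes()].
#' @param genes annotation from [gen_gene_annotation()].
#' @param truth planted-gene map from [gen_expression_panel()]; causal genes
#'   are the first \code{n_causal_genes} members of
#'   \code{truth[[causal_tissue]]} (none when \code{n_causal_genes} is 0).
#' @return a \code{summary_stats} object.
#' @export
gen_summary_stats <- function(cfg, geno, genes, truth) {
  set.seed(cfg$seed + 37L)
  k <- cfg$n_snps_per_gene
  causal <- if (cfg$n_causal_genes > 0)
    truth[[cfg$causal_tissue]][seq_len(cfg$n_causal_genes)] else character(0)
  mafs <- attr(geno, "maf")
  recs <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    rows <- ((g - 1L) * k + 1L):(g * k)
    ids <- names(geno$snp_index)[rows]
    r <- stats::cor(t(geno$dosages[rows, , drop = FALSE]))
    ch <- chol(r + diag(1e-8, k))
    mu <- if (genes$gene_id[g] %in% causal) {
      delta <- stats::rnorm(k, mean = cfg$noncentrality, sd = cfg$effect_sd)
      as.vector(r %*% delta)
    } else rep(0, k)
    z <- mu + as.vector(t(ch) %*% stats::rnorm(k))
    pos <- genes$start[g] + round(seq(0, 1e4 - 1, length.out = k))
    recs[[g]] <- data.frame(
      snp_id = ids, chrom = genes$chrom[g], pos = as.integer(pos),
      effect_allele = "A", other_allele = "G",
      maf = unname(mafs[ids]),
      effect = z / sqrt(cfg$gwas_n), se = 1 / sqrt(cfg$gwas_n),
      pvalue = 2 * stats::pnorm(-abs(z)), n = cfg$gwas_n,
      stringsAsFactors = FALSE)
  }
  summary_stats(do.call(rbind, recs),
                study_id = sprintf("sim_study_seed%d", cfg$seed))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing every input the pipeline needs, with the
#' planted ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list with \code{panel}, \code{truth}, \code{genes}, \code{geno},
#'   \code{ss} and \code{cfg}.
#' @export
simulate_study <- function(cfg = sim_config()) {
  ep <- gen_expression_panel(cfg)
  genes <- gen_gene_annotation(cfg)
  geno <- gen_genotypes(cfg)
  ss <- gen_summary_stats(cfg, geno, genes, ep$truth)
  list(panel = ep$panel, truth = ep$truth, genes = genes, geno = geno,
       ss = ss, cfg = cfg)
}

#' Write a synthetic study to the pipeline's file formats
#'
#' Emits the same plain-text formats the real pipeline reads: GWAS TSV,
#' expression TSV, tissue label TSV, dosage TSV and gene BED.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths.
#' @export
write_sim_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gwas = file.path(dir, "gwas.tsv"),
             expr = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             dosage = file.path(dir, "dosage.tsv"),
             genes = file.path(dir, "genes.bed"))
  write_summary_stats(sim$ss, paths["gwas"], sidecar = FALSE)
  utils::write.table(data.frame(gene_id = rownames(sim$panel$expr),
                                sim$panel$expr, check.names = FALSE),
                     paths["expr"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(sim$panel$sample_tissue),
                                tissue = unname(sim$panel$sample_tissue)),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(snp_id = rownames(sim$geno$dosages),
                                sim$geno$dosages, check.names = FALSE),
                     paths["dosage"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = sim$genes$chrom, start = sim$genes$start - 1L,
                    end = sim$genes$end, name = sim$genes$gene_id)
  utils::write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths
}
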