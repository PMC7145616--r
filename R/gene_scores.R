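# LD-aware gene-based association P-values: map SNPs to genes, estimate LD
# from a reference genotype panel, and evaluate the sum-of-chi-squares
# statistic against its weighted-chi-square null.

#' Map SNPs to genes by position
#'
#' A SNP is assigned to a gene when it lies in the gene body or within
#' \code{window} bp up- or downstream (boundaries inclusive). A SNP may be
#' assigned to several overlapping genes. Only autosomal genes are mapped.
#'
#' @param ss a \code{summary_stats} object.
#' @param genes a \code{gene_annotation} data.frame.
#' @param window flanking window in bp (default 50000).
#' @return named list: gene_id -> character vector of SNP IDs. Genes with no
#'   SNPs are absent.
#' @export
map_snps_to_genes <- function(ss, genes, window = 50000L) {
  genes <- genes[genes$autosomal, , drop = FALSE]
  rec <- ss$records
  if (!nrow(genes) || !nrow(rec)) return(list())
  snp_gr <- GenomicRanges::GRanges(rec$chrom,
                                   IRanges::IRanges(rec$pos, rec$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - window), genes$end + window))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (!length(hits)) return(list())
  split(rec$snp_id[S4Vectors_from(hits)],
        genes$gene_id[S4Vectors_to(hits)])
}

# thin indirection so the Hits accessors resolve without importing S4Vectors
S4Vectors_from <- function(h) S4Vectors::from(h)
S4Vectors_to <- function(h) S4Vectors::to(h)

#' Pairwise LD matrix from reference dosages
#'
#' Pearson correlation of dosage vectors for the requested SNPs. SNPs with
#' zero dosage variance are dropped with a warning. The correlation matrix
#' is projected to the nearest positive semi-definite matrix by truncating
#' negative eigenvalues at zero and rescaling to unit diagonal.
#'
#' @param geno a \code{genotype_ref} object.
#' @param snps character vector of SNP IDs present in \code{geno}.
#' @return list of class \code{ld_matrix} with \code{snp_ids} and
#'   \code{corr}; NULL when no usable SNP remains.
#' @export
ld_matrix <- function(geno, snps) {
  idx <- geno$snp_index[snps]
  if (any(is.na(idx)))
    stop("SNP(s) absent from genotype reference: ",
         paste(snps[is.na(idx)], collapse = ", "))
  dos <- geno$dosages[idx, , drop = FALSE]
  v <- apply(dos, 1, stats::var)
  if (any(v == 0 | is.na(v))) {
    dead <- snps[v == 0 | is.na(v)]
    warning("dropping zero-variance SNP(s): ", paste(dead, collapse = ", "))
    keep <- !(snps %in% dead)
    snps <- snps[keep]
    dos <- dos[keep, , drop = FALSE]
  }
  if (!length(snps)) return(NULL)
  corr <- stats::cor(t(dos))
  eg <- eigen(corr, symmetric = TRUE)
  if (any(eg$values < 0)) {
    lam <- pmax(eg$values, 0)
    corr <- eg$vectors %*% (lam * t(eg$vectors))
    corr <- (corr + t(corr)) / 2
    corr <- stats::cov2cor(corr)
  }
  dimnames(corr) <- list(snps, snps)
  structure(list(snp_ids = snps, corr = corr), class = "ld_matrix")
}

# Lugannani-Rice saddlepoint approximation to P(Q > q) for
# Q = sum lambda_j Z_j^2; accurate in relative terms deep in the tail.
saddlepoint_tail <- function(q, lambda) {
  kfun <- function(s) -0.5 * sum(log1p(-2 * s * lambda))
  k1 <- function(s) sum(lambda / (1 - 2 * s * lambda))
  k2 <- function(s) 2 * sum(lambda^2 / (1 - 2 * s * lambda)^2)
  s_hi <- 1 / (2 * max(lambda))
  if (q <= sum(lambda)) return(NA_real_)  # only used in the upper tail
  shat <- stats::uniroot(function(s) k1(s) - q,
                         lower = 0, upper = s_hi * (1 - 1e-12),
                         tol = 1e-14)$root
  w <- sqrt(2 * (shat * q - kfun(shat)))
  v <- shat * sqrt(k2(shat))
  if (w < 1e-8) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# 15-point Gauss-Legendre nodes/weights on [0, 1], via Golub-Welsch
gl15 <- local({
  n <- 15L
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  eg <- eigen(matrix(0, n, n) + diag(0, n) +
                `[<-`(`[<-`(matrix(0, n, n), cbind(j, j + 1), b),
                      cbind(j + 1, j), b),
              symmetric = TRUE)
  list(x = (rev(eg$values) + 1) / 2,
       w = rev(2 * eg$vectors[1, ]^2) / 2)
})

# Imhof inversion integral for P(Q > q). The head of the integral (up to
# the first sign change of the oscillating factor past the phase maximum)
# is evaluated adaptively; the oscillatory tail is summed half-period by
# half-period between successive zeros of sin(theta) (fixed Gauss-Legendre
# per wave) and accelerated as an alternating series by repeated averaging
# (Euler transformation).
imhof_tail <- function(q, lambda, tol = 1e-11, max_waves = 40L) {
  theta <- function(u)
    0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  integrand <- function(u) {
    th <- theta(u)
    rho <- exp(0.25 * colSums(log1p(outer(lambda, u)^2)))
    out <- sin(th) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)
    out
  }
  dtheta <- function(u) 0.5 * sum(lambda / (1 + (lambda * u)^2)) - 0.5 * q
  # point past which theta decreases monotonely
  u_star <- 0
  if (dtheta(0) > 0) {
    hi <- 1
    while (dtheta(hi) > 0) hi <- hi * 2
    u_star <- stats::uniroot(dtheta, c(0, hi), tol = 1e-12)$root
  }
  # successive crossings theta(u) = -m * pi beyond u_star
  th0 <- theta(u_star)
  m <- floor(-th0 / pi) + 1
  spacing <- 2 * pi / q
  # zero placement can be loose: a misplaced cut only moves mass between
  # adjacent waves without changing their sum. Newton with a bisection
  # safeguard; theta is strictly decreasing past u_star.
  cross <- function(level, from) {
    u <- from + spacing / 2
    for (i in 1:30) {
      step <- (theta(u) - level) / min(dtheta(u), -1e-12)
      u_new <- u - step
      if (u_new <= from) u_new <- (u + from) / 2
      if (abs(u_new - u) < 1e-9 * (1 + u)) return(u_new)
      u <- u_new
    }
    hi <- from + spacing
    while (theta(hi) > level) hi <- hi + spacing
    stats::uniroot(function(x) theta(x) - level, c(from, hi),
                   tol = 1e-7)$root
  }
  wave_quad <- function(a, b) {
    h <- b - a
    h * sum(gl15$w * integrand(a + h * gl15$x))
  }
  z_prev <- cross(-m * pi, u_star)
  total <- stats::integrate(integrand, 0, z_prev, rel.tol = 1e-10,
                            abs.tol = 1e-14, subdivisions = 200L,
                            stop.on.error = FALSE)$value
  terms <- numeric(max_waves)
  n <- 0L
  repeat {
    m <- m + 1
    z_next <- cross(-m * pi, z_prev)
    n <- n + 1L
    terms[n] <- wave_quad(z_prev, z_next)
    z_prev <- z_next
    if (n >= 4 && abs(terms[n]) < tol) break
    if (n >= max_waves) break
  }
  terms <- terms[seq_len(n)]
  # Euler acceleration of the alternating remainder
  ps <- cumsum(terms)
  while (length(ps) > 1) ps <- (ps[-1] + ps[-length(ps)]) / 2
  0.5 + (total + ps) / pi
}

#' Upper-tail probability of a weighted sum of chi-squares
#'
#' P(Q > q) for Q = sum_j lambda_j Z_j^2 with independent standard normal
#' Z_j. Equal weights reduce to an exact scaled chi-square tail; otherwise
#' Imhof's inversion integral is evaluated (adaptive head plus an
#' Euler-accelerated sum over oscillation half-periods). Because the
#' inversion integral has absolute rather than relative accuracy, tail
#' probabilities below 1e-8 are recomputed with a Lugannani-Rice
#' saddlepoint approximation; if numerical evaluation fails entirely, a
#' Monte-Carlo estimate (default 1e6 draws) is returned.
#'
#' @param q the observed statistic (>= 0).
#' @param lambda positive eigenvalue weights.
#' @param n_mc Monte-Carlo draws for the fallback.
#' @return tail probability in [0, 1].
#' @export
weighted_chisq_tail <- function(q, lambda, n_mc = 1e6) {
  lambda <- lambda[lambda > 0]
  k <- length(lambda)
  if (!k) stop("no positive eigenvalues")
  if (q <= 0) return(1)
  # equal weights: exact chi-square tail (covers the single-SNP case)
  if (diff(range(lambda)) <= 1e-12 * max(lambda))
    return(stats::pchisq(q / lambda[1], df = k, lower.tail = FALSE))
  p <- tryCatch(imhof_tail(q, lambda), error = function(e) NA_real_)
  if (!is.na(p) && p < 1e-8) {
    sp <- tryCatch(saddlepoint_tail(q, lambda), error = function(e) NA_real_)
    if (!is.na(sp)) p <- sp
  }
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6) {
    draws <- matrix(stats::rchisq(k * n_mc, df = 1), nrow = k)
    p <- mean(colSums(lambda * draws) > q)
  }
  min(max(p, 0), 1)
}

#' Gene-based P-value from SNP P-values and LD
#'
#' The gene statistic is the sum over SNPs of the chi-square(1) quantiles of
#' (1 - p). Under the null the statistic follows a weighted sum of
#' independent chi-squares with weights the eigenvalues of the LD matrix;
#' the returned value is the upper-tail probability of that law, clipped to
#' (1e-300, 1]. Eigenvalues below 1e-8 times the largest are dropped for
#' numerical stability.
#'
#' @param snp_pvalues SNP association P-values in (0, 1], same length and
#'   order as the LD matrix dimension.
#' @param ld an \code{ld_matrix}.
#' @return the gene-based P-value.
#' @export
gene_pvalue_sum <- function(snp_pvalues, ld) {
  k <- length(snp_pvalues)
  if (k != nrow(ld$corr))
    stop("length of snp_pvalues (", k, ") != LD dimension (", nrow(ld$corr), ")")
  if (any(is.na(snp_pvalues)) || any(snp_pvalues <= 0) || any(snp_pvalues > 1))
    stop("SNP P-values must lie in (0, 1]")
  tstat <- sum(stats::qchisq(snp_pvalues, df = 1, lower.tail = FALSE))
  lambda <- eigen(ld$corr, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-8 * max(lambda)]
  p <- weighted_chisq_tail(tstat, lambda)
  min(max(p, 1e-300), 1)
}

#' Gene-score configuration
#'
#' @param window SNP-to-gene flanking window in bp (default 50000).
#' @param min_genes minimum number of successfully scored genes for a study
#'   to qualify (default 18000; synthetic genomes use smaller values).
#' @param max_snps genes with more SNPs than this are scored on their
#'   top-variance subset, a guard against pathological inputs (default 5000).
#' @return list of class \code{gene_score_config}.
#' @export
gene_score_config <- function(window = 50000L, min_genes = 18000L,
                              max_snps = 5000L) {
  structure(list(window = window, min_genes = min_genes,
                 max_snps = max_snps),
            class = "gene_score_config")
}

#' Score every gene of a study
#'
#' Maps SNPs to autosomal genes, estimates per-gene LD from the reference
#' panel, and computes the gene-based P-value. Genes whose SNPs all lack
#' usable LD-reference coverage get status \code{failed}. The study
#' qualifies when at least \code{cfg$min_genes} genes succeed.
#'
#' @param ss QC-passed \code{summary_stats}.
#' @param genes a \code{gene_annotation} data.frame.
#' @param geno a \code{genotype_ref}.
#' @param cfg a [gene_score_config()].
#' @return object of class \code{gene_score_table}: list with
#'   \code{study_id}, \code{table} (data.frame: gene_id, n_snps, pvalue,
#'   status), \code{n_success}, \code{qualified}.
#' @export
score_study <- function(ss, genes, geno, cfg = gene_score_config()) {
  snp_map <- map_snps_to_genes(ss, genes, window = cfg$window)
  pv <- stats::setNames(ss$records$pvalue, ss$records$snp_id)
  rows <- lapply(names(snp_map), function(g) {
    snps <- intersect(snp_map[[g]], names(geno$snp_index))
    if (length(snps) > cfg$max_snps) {
      v <- apply(geno$dosages[geno$snp_index[snps], , drop = FALSE], 1,
                 stats::var)
      snps <- snps[order(v, decreasing = TRUE)][seq_len(cfg$max_snps)]
      message("gene ", g, ": pruned to top-", cfg$max_snps,
              " variance SNPs")
    }
    ld <- if (length(snps)) suppressWarnings(ld_matrix(geno, snps)) else NULL
    if (is.null(ld))
      return(data.frame(gene_id = g, n_snps = 0L, pvalue = NA_real_,
                        status = "failed", stringsAsFactors = FALSE))
    p <- gene_pvalue_sum(pv[ld$snp_ids], ld)
    data.frame(gene_id = g, n_snps = length(ld$snp_ids), pvalue = p,
               status = "ok", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(0), n_snps = integer(0),
                      pvalue = numeric(0), status = character(0),
                      stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  n_success <- sum(tab$status == "ok")
  structure(list(study_id = ss$study_id, table = tab,
                 n_success = n_success,
                 qualified = n_success >= cfg$min_genes),
            class = "gene_score_table")
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat("Gene scores:", x$study_id, "-", nrow(x$table), "genes,",
      x$n_success, "successful",
      if (x$qualified) "[qualified]" else "[unqualified]", "\n")
  invisible(x)
}

#' Write a gene-score table to TSV
#'
#' @param gs a \code{gene_score_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_scores <- function(gs, path) {
  utils::write.table(gs$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
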