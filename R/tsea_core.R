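# Trait-associated gene (TAG) sets, the one-sided chi-square tissue
# enrichment test, and permutation GSEA validation of top tissues.

#' Build thresholded trait-associated gene sets
#'
#' Five nested TAG sets by default, using strict inequality on the
#' gene-based P-value. A set with fewer than 20 or more than 3000 genes is
#' flagged unqualified (too small or too large for the enrichment test); a
#' study with no qualified set at all is flagged excluded.
#'
#' @param gs a \code{gene_score_table}; only status-ok genes are used.
#' @param thresholds decreasing P-value thresholds
#'   (default 0.05, 0.01, 1e-3, 1e-4, 1e-5).
#' @param min_size,max_size qualification bounds (defaults 20 and 3000).
#' @return object of class \code{tag_set_collection}: list with
#'   \code{study_id}, \code{thresholds}, \code{sets} (per threshold: list
#'   with \code{genes}, \code{qualified}), \code{excluded}.
#' @export
make_tag_sets <- function(gs, thresholds = c(0.05, 0.01, 1e-3, 1e-4, 1e-5),
                          min_size = 20L, max_size = 3000L) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  ok <- gs$table[gs$table$status == "ok", , drop = FALSE]
  sets <- lapply(thresholds, function(thr) {
    genes <- sort(ok$gene_id[ok$pvalue < thr])
    list(genes = genes,
         qualified = length(genes) >= min_size && length(genes) <= max_size)
  })
  names(sets) <- format(thresholds, scientific = FALSE, trim = TRUE,
                        drop0trailing = TRUE)
  structure(list(study_id = gs$study_id, thresholds = thresholds,
                 sets = sets,
                 excluded = !any(vapply(sets, `[[`, TRUE, "qualified"))),
            class = "tag_set_collection")
}

#' @export
print.tag_set_collection <- function(x, ...) {
  cat("TAG sets:", x$study_id,
      if (x$excluded) "[excluded: no qualified set]" else "", "\n")
  for (nm in names(x$sets))
    cat(sprintf("  P < %-8s %5d genes %s\n", nm, length(x$sets[[nm]]$genes),
                if (x$sets[[nm]]$qualified) "[qualified]" else ""))
  invisible(x)
}

#' One-sided chi-square enrichment of a gene set in a tissue set
#'
#' A 2x2 contingency table (in/out of the TAG set x in/out of the
#' tissue-specific set, over the gene universe) is tested with the Pearson
#' chi-square statistic without continuity correction. The one-sided
#' P-value for overrepresentation is half the upper-tail chi-square(1)
#' probability when the overlap exceeds its expectation, and one minus that
#' half otherwise.
#'
#' @param tag,tissue_set character vectors of gene IDs (intersected with the
#'   universe before testing).
#' @param universe character vector of background gene IDs.
#' @return list with \code{pvalue}, \code{overlap}, \code{expected},
#'   \code{statistic}, \code{tag_size}, \code{tissue_set_size},
#'   \code{universe_size}.
#' @export
chi2_enrichment <- function(tag, tissue_set, universe) {
  n <- length(unique(universe))
  if (n == 0) stop("empty universe")
  tag <- intersect(tag, universe)
  tissue_set <- intersect(tissue_set, universe)
  a <- length(tag)
  if (a == 0) stop("empty TAG set after intersecting with universe")
  b <- length(tissue_set)
  ov <- length(intersect(tag, tissue_set))
  expected <- a * b / n
  # Pearson statistic on the 2x2 table, no continuity correction
  n11 <- ov; n12 <- a - ov; n21 <- b - ov; n22 <- n - a - b + ov
  denom <- as.numeric(a) * (n - a) * b * (n - b)
  x2 <- if (denom > 0) n * (as.numeric(n11) * n22 - as.numeric(n12) * n21)^2 / denom else 0
  half <- stats::pchisq(x2, df = 1, lower.tail = FALSE) / 2
  p <- if (ov > expected) half else 1 - half
  list(pvalue = p, overlap = ov, expected = expected, statistic = x2,
       tag_size = a, tissue_set_size = b, universe_size = n)
}

#' Run the tissue-specific enrichment analysis for one study
#'
#' Tests every qualified TAG set against every tissue's specific gene set
#' over the shared gene universe (genes both scored and present in the
#' panel). Unqualified thresholds yield no entries.
#'
#' @param tags a \code{tag_set_collection}.
#' @param sets a \code{tissue_specific_sets}.
#' @param universe background gene IDs; defaults to the union of genes in
#'   all tissue sets is NOT used - callers should pass the intersection of
#'   scored genes and panel genes (see [run_study()]).
#' @return object of class \code{tsea_result}: list with \code{study_id},
#'   \code{panel_id}, \code{pvalues} (tissue x threshold matrix, NA for
#'   unqualified thresholds), \code{overlap}, \code{expected} (same shape),
#'   and \code{counts} metadata.
#' @export
run_tsea <- function(tags, sets, universe) {
  tissues <- names(sets$sets)
  thr_names <- names(tags$sets)
  pv <- matrix(NA_real_, length(tissues), length(thr_names),
               dimnames = list(tissues, thr_names))
  ov <- pv; expct <- pv
  counts <- list()
  for (tn in thr_names) {
    s <- tags$sets[[tn]]
    if (!s$qualified) next
    for (tt in tissues) {
      r <- chi2_enrichment(s$genes, sets$sets[[tt]], universe)
      pv[tt, tn] <- r$pvalue
      ov[tt, tn] <- r$overlap
      expct[tt, tn] <- r$expected
      counts[[paste(tt, tn, sep = "|")]] <-
        r[c("overlap", "tag_size", "tissue_set_size", "universe_size")]
    }
  }
  structure(list(study_id = tags$study_id, panel_id = sets$panel_id,
                 pvalues = pv, overlap = ov, expected = expct,
                 counts = counts),
            class = "tsea_result")
}

#' @export
print.tsea_result <- function(x, ...) {
  cat("TSEA result:", x$study_id, "on panel", x$panel_id, "\n")
  print(round(x$pvalues, 4))
  invisible(x)
}

#' Select the most significantly enriched tissues
#'
#' Tissues are ranked by their minimum enrichment P-value across qualified
#' thresholds; ties are broken by the larger overlap count at the minimizing
#' threshold, then by tissue name.
#'
#' @param res a \code{tsea_result}.
#' @param k number of tissues to return (default 3; truncated to the number
#'   of tissues available).
#' @return character vector of tissue names, most significant first.
#' @export
select_top_tissues <- function(res, k = 3L) {
  pv <- res$pvalues
  has <- rowSums(!is.na(pv)) > 0
  pv <- pv[has, , drop = FALSE]
  if (!nrow(pv)) return(character(0))
  minp <- apply(pv, 1, min, na.rm = TRUE)
  ov_at_min <- vapply(rownames(pv), function(tt) {
    j <- which.min(pv[tt, ])
    res$overlap[tt, j]
  }, numeric(1))
  ord <- order(minp, -ov_at_min, rownames(pv))
  utils::head(rownames(pv)[ord], k)
}

# Running-sum enrichment score for a set of hit positions in a ranked list.
# idx: sorted positions of the set in the ranking; w: |score| at each
# position of the full list; n: list length. Returns the signed extreme of
# the running sum (weight exponent 1).
running_es <- function(idx, w, n) {
  m <- length(idx)
  wsum <- sum(w[idx])
  hit <- if (wsum > 0) cumsum(w[idx]) / wsum else seq_len(m) / m
  miss_rate <- 1 / (n - m)
  # running sum at each hit position and just before it
  at_hit <- hit - (idx - seq_len(m)) * miss_rate
  before_hit <- c(0, hit[-m]) - (idx - seq_len(m)) * miss_rate
  cand <- c(at_hit, before_hit)
  unname(cand[which.max(abs(cand))])
}

#' Permutation GSEA of a TAG set against a tissue's specificity ranking
#'
#' Genes are ranked by decreasing specificity score; the classic weighted
#' running-sum enrichment score (weight exponent 1 on the absolute score)
#' is computed for the TAG set and compared with a null built by re-drawing
#' gene labels uniformly without replacement. NES is the enrichment score
#' divided by the absolute mean of same-sign permutation scores; the
#' permutation P-value is (1 + number of same-sign permutation scores at
#' least as extreme) / (n_perm + 1).
#'
#' @param spec_column named numeric vector: gene -> specificity score.
#' @param tag character vector of TAG gene IDs; its intersection with the
#'   ranked genes must be nonempty and smaller than the list.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed, recorded in the result.
#' @param tissue,study_id labels carried into the result.
#' @return object of class \code{gsea_result}: list with \code{es},
#'   \code{nes}, \code{perm_p}, \code{n_perm}, \code{leading_edge},
#'   \code{seed}, \code{tissue}, \code{study_id}.
#' @export
gsea_validate <- function(spec_column, tag, n_perm = 10000L, seed = 1L,
                          tissue = NA_character_, study_id = NA_character_) {
  ord <- order(spec_column, decreasing = TRUE)
  ranked <- names(spec_column)[ord]
  w <- abs(spec_column[ord])
  n <- length(ranked)
  idx <- sort(match(intersect(tag, ranked), ranked))
  m <- length(idx)
  if (m == 0) stop("TAG set shares no gene with the ranked list")
  if (m >= n) stop("TAG set as large as the ranked list")
  es <- running_es(idx, w, n)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    running_es(sort(sample.int(n, m)), w, n), numeric(1))
  same <- perm[sign(perm) == sign(es)]
  nes <- if (length(same)) es / abs(mean(same)) else NA_real_
  perm_p <- (1 + sum(abs(same) >= abs(es))) / (n_perm + 1)
  # leading edge: TAG genes up to (or from, for negative ES) the peak
  m_hit <- cumsum(w[idx]) / sum(w[idx])
  at_hit <- m_hit - (idx - seq_len(m)) / (n - m)
  leading <- if (es >= 0) {
    peak <- idx[which.max(at_hit)]
    ranked[idx[idx <= peak]]
  } else {
    before <- c(0, m_hit[-m]) - (idx - seq_len(m)) / (n - m)
    peak <- idx[which.min(before)]
    ranked[idx[idx >= peak]]
  }
  structure(list(study_id = study_id, tissue = tissue, es = es, nes = nes,
                 perm_p = perm_p, n_perm = n_perm, leading_edge = leading,
                 seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: %s / %s  ES=%.3f NES=%.3f perm_p=%.2g (%d perms)\n",
              x$study_id, x$tissue, x$es, x$nes, x$perm_p, x$n_perm))
  invisible(x)
}
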