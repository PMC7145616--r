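# Readers and writers for the external formats the pipeline touches.
# All genomic coordinates are 1-based inclusive internally; only the BED
# reader converts (BED is 0-based half-open). Chromosome labels are
# normalized by stripping a leading "chr" and upper-casing X/Y/MT.

#' Normalize chromosome labels
#'
#' Strips a leading \code{"chr"} prefix (case-insensitive) and upper-cases
#' X, Y and MT (M is mapped to MT).
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels ("1".."22", "X", "Y", "MT").
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

#' Test whether normalized chromosome labels are autosomal
#'
#' @param chrom character vector (already normalized or not).
#' @return logical vector, TRUE for chromosomes 1-22.
#' @export
is_autosome <- function(chrom) {
  normalize_chrom(chrom) %in% as.character(1:22)
}

#' Default column mapping for GWAS summary statistics
#'
#' Maps the internal field names onto common header spellings. Users with a
#' different dialect supply their own mapping (internal name -> file column),
#' e.g. from a YAML config via [read_column_map()].
#'
#' @return named character vector: internal field -> file column name.
#' @export
default_column_map <- function() {
  c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    maf = "maf", effect = "effect", se = "se", pvalue = "pvalue", n = "n")
}

#' Read a column mapping from a YAML config file
#'
#' The file holds flat \code{internal_name: file_column} pairs.
#'
#' @param path path to a YAML file.
#' @return named character vector suitable for [read_summary_stats()].
#' @export
read_column_map <- function(path) {
  m <- yaml::read_yaml(path)
  if (!length(m)) stop("empty column map: ", path)
  unlist(m)
}

#' Read GWAS summary statistics
#'
#' Parses a tab- or whitespace-separated file with a header into a
#' normalized \code{summary_stats} object. Rows whose P-value cannot be
#' parsed or lies outside (0, 1] are dropped and counted; the drop counts
#' travel with the object.
#'
#' @param path path to the summary statistics file.
#' @param column_map named character vector, internal field -> file column.
#'   Must cover at least \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{pvalue}. Defaults to [default_column_map()].
#' @param study_id study identifier; defaults to the file name.
#' @return an object of class \code{summary_stats}: a list with
#'   \code{study_id}, \code{records} (data.frame with columns snp_id, chrom,
#'   pos, effect_allele, other_allele, maf, effect, se, pvalue, n) and
#'   \code{drop_counts} (named integer vector).
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               study_id = basename(path)) {
  mandatory <- c("snp_id", "chrom", "pos", "pvalue")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map))
    stop("column_map must name: ", paste(missing_map, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty summary statistics file: ", path)
  absent <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(absent))
    stop("mandatory column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "))

  pick <- function(field, parser = identity, default = NA) {
    col <- column_map[field]
    if (is.na(col) || !(col %in% names(raw))) return(rep(default, nrow(raw)))
    parser(raw[[col]])
  }
  rec <- data.frame(
    snp_id = as.character(raw[[column_map["snp_id"]]]),
    chrom = normalize_chrom(raw[[column_map["chrom"]]]),
    pos = suppressWarnings(as.integer(raw[[column_map["pos"]]])),
    effect_allele = as.character(pick("effect_allele")),
    other_allele = as.character(pick("other_allele")),
    maf = suppressWarnings(as.numeric(pick("maf"))),
    effect = suppressWarnings(as.numeric(pick("effect"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pvalue = suppressWarnings(as.numeric(raw[[column_map["pvalue"]]])),
    n = suppressWarnings(as.integer(pick("n"))),
    stringsAsFactors = FALSE
  )
  bad_p <- is.na(rec$pvalue) | rec$pvalue <= 0 | rec$pvalue > 1
  bad_pos <- is.na(rec$pos) | rec$pos < 1
  drop <- bad_p | bad_pos
  drop_counts <- c(bad_pvalue = sum(bad_p), bad_pos = sum(bad_pos & !bad_p))
  structure(list(study_id = study_id,
                 records = rec[!drop, , drop = FALSE],
                 drop_counts = drop_counts),
            class = "summary_stats")
}

#' Construct a summary_stats object from a data frame
#'
#' Convenience constructor used by the synthetic-data generator and tests.
#'
#' @param records data.frame with the summary-stat columns (at least snp_id,
#'   chrom, pos, pvalue).
#' @param study_id study identifier.
#' @return a \code{summary_stats} object.
#' @export
summary_stats <- function(records, study_id = "study") {
  needed <- c("snp_id", "chrom", "pos", "pvalue")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  for (opt in c("effect_allele", "other_allele", "maf", "effect", "se", "n"))
    if (is.null(records[[opt]])) records[[opt]] <- NA
  records$chrom <- normalize_chrom(records$chrom)
  rownames(records) <- NULL
  structure(list(study_id = study_id, records = records,
                 drop_counts = c(bad_pvalue = 0L, bad_pos = 0L)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics:", x$study_id, "\n")
  cat(" ", nrow(x$records), "variants;",
      sum(x$drop_counts), "rows dropped on read\n")
  invisible(x)
}

#' Write summary statistics to a TSV file
#'
#' Writes the normalized records plus a JSON sidecar (same path with
#' \code{.json} appended) carrying drop counts and provenance.
#'
#' @param ss a \code{summary_stats} object.
#' @param path output TSV path.
#' @param sidecar write the JSON provenance sidecar? Default TRUE.
#' @return \code{path}, invisibly.
#' @export
write_summary_stats <- function(ss, path, sidecar = TRUE) {
  utils::write.table(ss$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    meta <- list(study_id = ss$study_id,
                 n_records = nrow(ss$records),
                 drop_counts = as.list(ss$drop_counts),
                 file_md5 = unname(tools::md5sum(path)))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read gene annotation from BED or GFF
#'
#' BED input (0-based half-open) is converted to 1-based inclusive; GFF is
#' already 1-based inclusive. Features on non-autosomes are retained but
#' flagged; filtering happens downstream.
#'
#' @param path annotation file path.
#' @param format \code{"bed"} or \code{"gff"}.
#' @return data.frame of class \code{gene_annotation} with columns gene_id,
#'   symbol, chrom, start, end, strand, autosomal.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff") {
    types <- as.character(gr$type)
    if (any(types == "gene")) gr <- gr[types == "gene"]
  }
  ids <- if (format == "bed") as.character(gr$name)
         else {
           id <- gr$gene_id
           if (is.null(id)) id <- gr$ID
           if (is.null(id)) id <- gr$Name
           as.character(id)
         }
  sym <- if (format == "gff" && !is.null(gr$Name)) as.character(gr$Name) else ids
  ann <- data.frame(
    gene_id = ids,
    symbol = sym,
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    stringsAsFactors = FALSE
  )
  if (any(ann$start > ann$end))
    stop("gene annotation has start > end after normalization")
  ann$autosomal <- is_autosome(ann$chrom)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Construct a gene annotation table
#'
#' @param gene_id,chrom,start,end vectors of equal length (1-based inclusive
#'   coordinates).
#' @param symbol gene symbols; defaults to \code{gene_id}.
#' @param strand strand; defaults to "+".
#' @return a \code{gene_annotation} data.frame.
#' @export
gene_annotation <- function(gene_id, chrom, start, end,
                            symbol = gene_id, strand = "+") {
  if (any(start > end)) stop("gene annotation has start > end")
  ann <- data.frame(gene_id = as.character(gene_id), symbol = symbol,
                    chrom = normalize_chrom(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = strand, stringsAsFactors = FALSE)
  ann$autosomal <- is_autosome(ann$chrom)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read an expression panel
#'
#' @param path TSV with gene rows and sample columns; the first column holds
#'   gene IDs.
#' @param label_path two-column TSV (sample, tissue) mapping every sample
#'   column to a tissue.
#' @param panel_id panel identifier; defaults to the matrix file name.
#' @return an \code{expression_panel} object (see [expression_panel()]).
#' @export
read_expression_panel <- function(path, label_path,
                                  panel_id = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- genes
  labs <- utils::read.table(label_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  sample_tissue <- stats::setNames(as.character(labs[[2]]),
                                   as.character(labs[[1]]))
  expression_panel(expr, sample_tissue, panel_id = panel_id)
}

#' Construct an expression panel
#'
#' @param expr numeric gene x sample matrix of non-negative expression
#'   values, with row and column names.
#' @param sample_tissue named character vector mapping every sample (column)
#'   to a tissue label.
#' @param covariates optional data.frame of per-sample covariates, rows
#'   named by sample.
#' @param panel_id panel identifier.
#' @return an object of class \code{expression_panel}.
#' @export
expression_panel <- function(expr, sample_tissue, covariates = NULL,
                             panel_id = "panel") {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene row names and sample column names")
  dup <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup))
    stop("duplicated gene ID(s) in expression matrix: ",
         paste(unique(dup), collapse = ", "))
  unlabeled <- setdiff(colnames(expr), names(sample_tissue))
  if (length(unlabeled))
    stop("sample(s) missing from tissue labels: ",
         paste(unlabeled, collapse = ", "))
  sample_tissue <- sample_tissue[colnames(expr)]
  if (!is.null(covariates)) {
    missc <- setdiff(colnames(expr), rownames(covariates))
    if (length(missc))
      stop("sample(s) missing from covariates: ", paste(missc, collapse = ", "))
    covariates <- covariates[colnames(expr), , drop = FALSE]
  }
  structure(list(panel_id = panel_id, expr = expr,
                 sample_tissue = sample_tissue, covariates = covariates),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("Expression panel:", x$panel_id, "-", nrow(x$expr), "genes x",
      ncol(x$expr), "samples,", length(unique(x$sample_tissue)), "tissues\n")
  invisible(x)
}

#' Construct a genotype reference panel
#'
#' @param dosages numeric SNP x sample matrix of allele dosages in [0, 2],
#'   with SNP IDs as row names.
#' @param samples sample identifiers; defaults to column names.
#' @return an object of class \code{genotype_ref}.
#' @export
genotype_ref <- function(dosages, samples = colnames(dosages)) {
  if (is.null(rownames(dosages))) stop("dosage matrix needs SNP row names")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosages)))
  structure(list(samples = samples, dosages = dosages,
                 snp_index = stats::setNames(seq_len(nrow(dosages)),
                                             rownames(dosages))),
            class = "genotype_ref")
}

#' Read a genotype reference from VCF or a dosage TSV
#'
#' VCF genotypes (GT) are converted to alternate-allele dosages; a dosage
#' TSV has SNP rows (first column the SNP ID) and sample columns.
#'
#' @param path input file.
#' @param format \code{"vcf"} or \code{"dosage"}; guessed from the file
#'   extension when missing.
#' @return a \code{genotype_ref} object.
#' @export
read_genotype_ref <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a)
               sum(a != "0" & a != "."), numeric(1)))
    }
    dos <- apply(gt, 2, count_alt)
    dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
    ids <- vcfR::getID(v)
    if (any(is.na(ids)))
      ids[is.na(ids)] <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))[is.na(ids)]
    rownames(dos) <- ids
    genotype_ref(dos)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- as.character(tab[[1]])
    genotype_ref(dos)
  }
}
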