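#' Construct an expression matrix
#'
#' A light container for one expression compendium dataset: a numeric
#' genes x samples matrix with a dataset identifier and a platform tag that
#' decides which normalization the pipeline applies (quantile normalization
#' for microarray intensities, TMM for RNA-seq counts).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). At least 2 samples; all values finite.
#' @param dataset_id Short string identifying the dataset.
#' @param platform One of `"microarray"`, `"rnaseq_counts"`, `"rnaseq_fpkm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, dataset_id,
                              platform = c("microarray", "rnaseq_counts", "rnaseq_fpkm")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("`values` must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop_validation(sprintf("duplicate gene id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop_validation(sprintf("duplicate sample id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (ncol(values) < 2L) {
    stop_validation("an expression matrix needs at least 2 samples (correlation is undefined otherwise)")
  }
  if (!all(is.finite(values))) {
    stop_validation("`values` must be finite")
  }
  structure(
    list(dataset_id = as.character(dataset_id), values = values, platform = platform),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %s: %d genes x %d samples [%s]\n",
    x$dataset_id, nrow(x$values), ncol(x$values), x$platform
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row `gene_id<TAB>sample1<TAB>...` followed by one row per
#' gene. Structural problems are rejected, never repaired: a duplicated gene
#' id or a non-numeric cell is an error (naming the offending row and column),
#' not a silent merge or NA.
#'
#' @param path Path to a tab-separated file.
#' @param platform Platform tag, see [expression_matrix()].
#' @param dataset_id Dataset identifier; defaults to the file name sans
#'   extension.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   platform = c("microarray", "rnaseq_counts", "rnaseq_fpkm"),
                                   dataset_id = NULL) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop_parse("expression TSV needs a gene_id column plus at least one sample column")
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_validation(sprintf("duplicate gene id(s) in %s: %s", path, paste(head(dup, 5), collapse = ", ")))
  }
  samples <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !(toupper(body) %in% c("NA", "NAN")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_parse(sprintf(
      "non-numeric value '%s' at gene '%s', sample '%s' in %s",
      body[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]], samples[bad[1L, 2L]], path
    ))
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_parse(sprintf(
      "missing value at gene '%s', sample '%s' in %s (imputation is out of scope)",
      genes[bad[1L, 1L]], samples[bad[1L, 2L]], path
    ))
  }
  dimnames(num) <- list(genes, samples)
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  expression_matrix(num, dataset_id = dataset_id, platform = platform)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; full `%.17g`-style precision so a
#' write-then-read round trip reproduces values exactly.
#'
#' @param m An `expression_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  chr <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values))
  df <- data.frame(gene_id = gene_ids(m), chr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Filter genes by standard deviation
#'
#' Retains the genes with the largest sample standard deviation across
#' samples, keeping `ceiling(retain_fraction * n_genes)` of them (compendium
#' preprocessing typically retains ~75% of genes). Ties at the cutoff are
#' broken in favour of the lower row index; the original gene order of the
#' survivors is preserved.
#'
#' @param m An `expression_matrix` with at least 2 samples.
#' @param retain_fraction Fraction of genes to keep, in (0, 1]. Default 0.75.
#' @return A filtered `expression_matrix`.
#' @export
filter_by_sd <- function(m, retain_fraction = 0.75) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!is.numeric(retain_fraction) || length(retain_fraction) != 1L ||
      is.na(retain_fraction) || retain_fraction <= 0 || retain_fraction > 1) {
    stop_parameter("`retain_fraction` must be in (0, 1]")
  }
  n <- nrow(m$values)
  k <- as.integer(ceiling(retain_fraction * n))
  sds <- row_sds(m$values)
  keep <- sort(order(-sds, seq_len(n))[seq_len(k)])
  expression_matrix(m$values[keep, , drop = FALSE], m$dataset_id, m$platform)
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the identical distribution: the
#' per-rank mean across columns. Values tied within a column receive the mean
#' of the reference values at their tied ranks.
#'
#' @param m An `expression_matrix` (typically microarray intensities).
#' @return A normalized `expression_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  x <- m$values
  if (ncol(x) < 2L) {
    warn("quantile_normalize: single-sample matrix, returning input unchanged")
    return(m)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(v) {
    rk <- rank(v, ties.method = "min")
    if (anyDuplicated(rk)) {
      # tie group starting at integer rank s with k members spans ref[s..s+k-1]
      cnt <- tabulate(rk, nbins = length(v))
      grp_val <- vapply(which(cnt > 0L), function(s) mean(ref[s:(s + cnt[s] - 1L)]), numeric(1))
      names(grp_val) <- as.character(which(cnt > 0L))
      unname(grp_val[as.character(rk)])
    } else {
      ref[rk]
    }
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, m$dataset_id, m$platform)
}

#' TMM normalization for RNA-seq counts
#'
#' Computes per-sample scale factors by the trimmed mean of M-values method
#' (Robinson & Oshlack): the reference sample is the one whose upper quartile
#' is closest to the mean upper quartile; per-pair M (log ratio) and A (log
#' abundance) values are computed on genes with positive counts in both
#' samples; 30% of M and 5% of A are trimmed from each tail; the factor is
#' 2^(mean of the remaining M); factors are rescaled to geometric mean 1.
#' The normalized output is counts-per-million divided by the factor, then
#' log2(x + 1). With `do_weighting = TRUE` the mean of M is precision-weighted
#' (inverse delta-method variance); the unweighted default keeps the factors
#' exactly invariant to rescaling any single library, since M and A are
#' library-size ratios but the precision weights are not.
#'
#' @param m An `expression_matrix` with `platform == "rnaseq_counts"` and
#'   non-negative values.
#' @param logratio_trim Fraction of M values trimmed from each tail (default 0.3).
#' @param sum_trim Fraction of A values trimmed from each tail (default 0.05).
#' @param cpm_scale Library-size scale for the output (default 1e6).
#' @param pseudo Offset inside the log2 (default 1).
#' @param do_weighting Precision-weight the trimmed mean of M (default `FALSE`).
#' @return A normalized `expression_matrix` with attribute `"norm_factors"`.
#' @export
tmm_normalize <- function(m, logratio_trim = 0.30, sum_trim = 0.05,
                          cpm_scale = 1e6, pseudo = 1, do_weighting = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  x <- m$values
  if (m$platform != "rnaseq_counts") {
    stop_parameter("tmm_normalize expects platform 'rnaseq_counts'")
  }
  if (any(x < 0)) stop_validation("TMM requires non-negative counts")
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop_validation(sprintf("all-zero sample(s): %s",
                            paste(colnames(x)[lib == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(x, method = "TMM",
                              logratioTrim = logratio_trim, sumTrim = sum_trim,
                              doWeighting = do_weighting)
  f <- f / exp(mean(log(f)))  # geometric mean exactly 1
  cpm <- sweep(x, 2L, lib * f / cpm_scale, "/")
  out <- log2(cpm + pseudo)
  res <- expression_matrix(out, m$dataset_id, m$platform)
  attr(res, "norm_factors") <- setNames(f, colnames(x))
  res
}

#' Normalize an expression matrix according to its platform
#'
#' Dispatches to [quantile_normalize()] for microarray data, to
#' [tmm_normalize()] for RNA-seq counts; FPKM-like data are log2(x + 1)
#' transformed only.
#'
#' @param m An `expression_matrix`.
#' @param ... Passed to the platform-specific normalizer.
#' @return A normalized `expression_matrix`.
#' @export
normalize_expression <- function(m, ...) {
  stopifnot(inherits(m, "expression_matrix"))
  switch(m$platform,
    microarray = quantile_normalize(m),
    rnaseq_counts = tmm_normalize(m, ...),
    rnaseq_fpkm = expression_matrix(log2(m$values + 1), m$dataset_id, m$platform)
  )
}
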