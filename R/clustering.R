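#' Construct a clustering solution
#'
#' A partition of (a subset of) one dataset's genes into co-expression
#' modules. Genes without a module are "unclustered"; every module must have
#' at least 2 members (a single gene cannot define within-module
#' co-expression).
#'
#' @param assignment Named integer vector: names are gene ids, values are
#'   non-negative module ids.
#' @param clustering_id Short identifier for the solution.
#' @param dataset_id Identifier of the expression dataset it partitions.
#' @param unclustered Character vector of gene ids carrying no module.
#' @return An object of class `clustering_solution`.
#' @export
clustering_solution <- function(assignment, clustering_id, dataset_id,
                                unclustered = character()) {
  if (length(assignment) > 0L) {
    if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
      stop_validation("`assignment` must be a named vector (gene ids)")
    }
    if (anyDuplicated(names(assignment))) {
      dup <- unique(names(assignment)[duplicated(names(assignment))])
      stop_validation(sprintf("gene(s) assigned more than once: %s",
                              paste(head(dup, 5), collapse = ", ")))
    }
    if (any(assignment < 0)) stop_validation("module ids must be non-negative")
    sizes <- table(assignment)
    if (any(sizes < 2L)) {
      stop_validation(sprintf("module(s) with fewer than 2 members: %s",
                              paste(head(names(sizes)[sizes < 2L], 5), collapse = ", ")))
    }
  }
  if (any(unclustered %in% names(assignment))) {
    stop_validation("a gene cannot be both assigned and unclustered")
  }
  structure(
    list(clustering_id = as.character(clustering_id),
         dataset_id = as.character(dataset_id),
         assignment = assignment,
         unclustered = unique(as.character(unclustered))),
    class = "clustering_solution"
  )
}

#' @export
print.clustering_solution <- function(x, ...) {
  cat(sprintf("<clustering_solution> %s on %s: %d genes in %d modules, %d unclustered\n",
              x$clustering_id, x$dataset_id, length(x$assignment),
              length(unique(x$assignment)), length(x$unclustered)))
  invisible(x)
}

# Drop modules that fell below 2 members, moving their genes to unclustered.
dissolve_singletons <- function(assignment, unclustered, quiet = FALSE) {
  if (length(assignment) > 0L) {
    sizes <- table(assignment)
    singletons <- as.integer(names(sizes)[sizes < 2L])
    if (length(singletons) > 0L) {
      moved <- names(assignment)[assignment %in% singletons]
      if (!quiet) {
        warn(sprintf("%d singleton module(s) dissolved; member(s) moved to unclustered: %s",
                     length(singletons), paste(head(moved, 5), collapse = ", ")))
      }
      unclustered <- union(unclustered, moved)
      assignment <- assignment[!(assignment %in% singletons)]
    }
  }
  list(assignment = assignment, unclustered = unclustered)
}

#' Read a clustering solution from TSV
#'
#' Two-column TSV `gene_id<TAB>module_id`; a module id of `-1` marks an
#' unclustered gene, as does absence from the file. Genes absent from the
#' matrix are dropped (with a logged count); modules reduced to a single
#' member are dissolved into the unclustered set with a warning. A gene
#' listed twice with different modules is a validation error.
#'
#' @param path Path to the TSV (an optional `gene_id<TAB>module_id` header row
#'   is tolerated).
#' @param matrix The `expression_matrix` the solution partitions.
#' @param clustering_id Identifier; defaults to the file name sans extension.
#' @return A `clustering_solution`.
#' @export
read_clustering <- function(path, matrix, clustering_id = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  raw <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                    quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop_parse("clustering TSV needs two columns: gene_id, module_id")
  if (nrow(raw) > 0L && is.na(suppressWarnings(as.integer(raw[1L, 2L])))) {
    raw <- raw[-1L, , drop = FALSE]   # header row
  }
  genes <- raw[[1L]]
  mods <- suppressWarnings(as.integer(raw[[2L]]))
  if (anyNA(mods)) {
    stop_parse(sprintf("non-integer module id '%s' for gene '%s' in %s",
                       raw[[2L]][which(is.na(mods))[1L]], genes[which(is.na(mods))[1L]], path))
  }
  df <- unique(data.frame(gene = genes, mod = mods, stringsAsFactors = FALSE))
  conflict <- unique(df$gene[duplicated(df$gene)])
  if (length(conflict) > 0L) {
    stop_validation(sprintf("gene(s) assigned to more than one module in %s: %s",
                            path, paste(head(conflict, 5), collapse = ", ")))
  }
  present <- df$gene %in% gene_ids(matrix)
  if (any(!present)) {
    inform(sprintf("read_clustering: dropped %d gene(s) absent from dataset '%s'",
                   sum(!present), matrix$dataset_id))
    df <- df[present, , drop = FALSE]
  }
  unclustered <- df$gene[df$mod < 0L]
  df <- df[df$mod >= 0L, , drop = FALSE]
  assignment <- setNames(df$mod, df$gene)
  fixed <- dissolve_singletons(assignment, unclustered)
  if (is.null(clustering_id)) clustering_id <- sub("\\.[^.]*$", "", basename(path))
  clustering_solution(fixed$assignment, clustering_id, matrix$dataset_id,
                      fixed$unclustered)
}

#' Write a clustering solution to TSV
#'
#' @param cl A `clustering_solution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(cl, path) {
  stopifnot(inherits(cl, "clustering_solution"))
  df <- rbind(
    data.frame(gene_id = names(cl$assignment), module_id = unname(cl$assignment)),
    data.frame(gene_id = cl$unclustered,
               module_id = rep(-1L, length(cl$unclustered)))
  )
  df <- df[order(df$gene_id), , drop = FALSE]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' k-means clustering of an expression matrix
#'
#' A generic stand-in clustering so the pipeline runs end-to-end without
#' external clustering software (production compendia typically come with
#' precomputed solutions, read via [read_clustering()]). Gene rows are
#' standardized to mean 0 / SD 1 before clustering (rows with SD below 1e-12
#' are kept but centred only and flagged); the result is deterministic given
#' `seed`; singleton clusters are dissolved into the unclustered set.
#'
#' @param m An `expression_matrix`.
#' @param k Number of clusters, `2 <= k <= n_genes / 2`.
#' @param seed Integer seed.
#' @param clustering_id Identifier (default `"kmeans<k>"`).
#' @return A `clustering_solution`; attribute `"zero_variance_genes"` lists
#'   flagged constant-expression genes.
#' @export
cluster_kmeans <- function(m, k, seed, clustering_id = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  n <- nrow(m$values)
  if (!is.numeric(k) || length(k) != 1L || k < 2L || k > n / 2) {
    stop_parameter(sprintf("`k` must satisfy 2 <= k <= n_genes/2 (= %.0f)", n / 2))
  }
  s <- row_sds(m$values)
  flagged <- gene_ids(m)[s < 1e-12]
  s[s < 1e-12] <- 1
  scaled <- (m$values - rowMeans(m$values)) / s
  km <- with_seed(seed, kmeans(scaled, centers = as.integer(k),
                               nstart = 10L, iter.max = 100L))
  assignment <- setNames(as.integer(km$cluster), gene_ids(m))
  fixed <- dissolve_singletons(assignment, character(), quiet = TRUE)
  if (is.null(clustering_id)) clustering_id <- sprintf("kmeans%d", as.integer(k))
  out <- clustering_solution(fixed$assignment, clustering_id, m$dataset_id,
                             fixed$unclustered)
  attr(out, "zero_variance_genes") <- flagged
  out
}

#' Pair an expression matrix with a clustering solution
#'
#' A configuration is the unit of model selection: one expression dataset
#' together with one clustering of it. Candidate scoring caches per-module
#' correlation matrices inside the configuration, so repeated scoring (LOOCV,
#' permutation nulls) reuses them.
#'
#' @param matrix An `expression_matrix`.
#' @param clustering A `clustering_solution` for the same dataset.
#' @return An object of class `configuration` with id
#'   `"dataset_id/clustering_id"`.
#' @export
configuration <- function(matrix, clustering) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(clustering, "clustering_solution"))
  if (!identical(matrix$dataset_id, clustering$dataset_id)) {
    stop_validation(sprintf("dataset mismatch: matrix '%s' vs clustering '%s'",
                            matrix$dataset_id, clustering$dataset_id))
  }
  missing <- setdiff(names(clustering$assignment), gene_ids(matrix))
  if (length(missing) > 0L) {
    stop_validation(sprintf("clustered gene(s) absent from the matrix: %s",
                            paste(head(missing, 5), collapse = ", ")))
  }
  structure(
    list(matrix = matrix, clustering = clustering,
         config_id = paste(matrix$dataset_id, clustering$clustering_id, sep = "/"),
         cache = new.env(parent = emptyenv())),
    class = "configuration"
  )
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %s\n", x$config_id))
  invisible(x)
}

# Cached correlation matrix among the members of one module.
module_cor <- function(config, module_id, members) {
  key <- as.character(module_id)
  if (!is.null(config$cache[[key]])) return(config$cache[[key]])
  cm <- row_cor(config$matrix$values[members, , drop = FALSE])
  dimnames(cm) <- list(members, members)
  config$cache[[key]] <- cm
  cm
}

# Module membership lists for a configuration, computed once and cached.
module_members <- function(config) {
  if (!is.null(config$cache[[".members"]])) return(config$cache[[".members"]])
  mm <- split(names(config$clustering$assignment), config$clustering$assignment)
  config$cache[[".members"]] <- mm
  mm
}
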