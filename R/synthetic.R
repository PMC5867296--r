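# Synthetic expression compendia with planted co-expression modules, so the
# whole pipeline — scoring, LOOCV, nulls, networks — is testable without any
# external download. The latent-factor construction gives an analytically
# known expected within-module Pearson correlation, enabling calibrated
# property tests.

#' Specification of a synthetic compendium
#'
#' @param n_modules Number of planted co-expression modules.
#' @param genes_per_module Genes per module.
#' @param n_background_genes Pure-noise genes (unclustered in the truth).
#' @param n_samples Samples (conditions) per dataset.
#' @param n_datasets Independent datasets sharing the same gene ids and
#'   module structure (their latent profiles and noise are independent).
#' @param rho Target expected within-module Pearson correlation, in (0, 1).
#' @param noise_sd SD multiplier of the gene-specific noise (default 1, which
#'   makes the expected within-module correlation exactly `rho`).
#' @param seed Master integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 10L, genes_per_module = 20L,
                           n_background_genes = 100L, n_samples = 50L,
                           n_datasets = 2L, rho = 0.9, noise_sd = 1,
                           seed = 1L) {
  counts <- c(n_modules, genes_per_module, n_background_genes, n_samples, n_datasets)
  if (any(counts < 1L)) stop_parameter("all counts must be positive")
  if (!is.numeric(rho) || rho <= 0 || rho >= 1) {
    stop_parameter("`rho` must lie in the open interval (0, 1)")
  }
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 n_samples = as.integer(n_samples),
                 n_datasets = as.integer(n_datasets),
                 rho = rho, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression compendium
#'
#' Per dataset, every planted module `m` draws a latent sample profile
#' `f_m ~ N(0, 1)`; each member gene is
#' `sqrt(rho) * f_m + sqrt(1 - rho) * noise_sd * eps` with gene-specific
#' standard-normal noise `eps`, so (at `noise_sd = 1`) the expected pairwise
#' within-module correlation is `rho`. Background genes are pure noise. The
#' truth clustering assigns module members their planted module and leaves
#' background genes unclustered.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrices` (list of [expression_matrix()], platform
#'   `"microarray"`), `clusterings` (matching truth [clustering_solution()]s),
#'   `configurations` (ready-made [configuration()] pairings), and `truth`
#'   (tibble `gene_id`, `module`; background genes have module `NA`).
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_mod_genes <- spec$n_modules * spec$genes_per_module
  n_genes <- n_mod_genes + spec$n_background_genes
  genes <- sprintf("g%04d", seq_len(n_genes))
  module_of <- c(rep(seq_len(spec$n_modules), each = spec$genes_per_module),
                 rep(NA_integer_, spec$n_background_genes))

  matrices <- vector("list", spec$n_datasets)
  clusterings <- vector("list", spec$n_datasets)
  for (d in seq_len(spec$n_datasets)) {
    vals <- with_seed(derive_seed(spec$seed, 7L, d), {
      x <- matrix(0, n_genes, spec$n_samples)
      for (m in seq_len(spec$n_modules)) {
        f <- rnorm(spec$n_samples)
        idx <- which(module_of == m)
        eps <- matrix(rnorm(length(idx) * spec$n_samples), length(idx))
        x[idx, ] <- sqrt(spec$rho) * matrix(f, length(idx), spec$n_samples, byrow = TRUE) +
          sqrt(1 - spec$rho) * spec$noise_sd * eps
      }
      bg <- which(is.na(module_of))
      if (length(bg) > 0L) {
        x[bg, ] <- matrix(rnorm(length(bg) * spec$n_samples), length(bg))
      }
      x
    })
    dimnames(vals) <- list(genes, sprintf("s%03d", seq_len(spec$n_samples)))
    ds_id <- sprintf("ds%02d", d)
    matrices[[d]] <- expression_matrix(vals, ds_id, "microarray")
    clusterings[[d]] <- clustering_solution(
      setNames(module_of[!is.na(module_of)], genes[!is.na(module_of)]),
      clustering_id = "truth", dataset_id = ds_id,
      unclustered = genes[is.na(module_of)]
    )
  }
  configurations <- purrr::map2(matrices, clusterings, configuration)
  list(matrices = matrices, clusterings = clusterings,
       configurations = configurations,
       truth = tibble(gene_id = genes, module = module_of))
}

#' Derive an annotation with held-out members from a planted truth
#'
#' Every planted module yields one "coherent" term containing a random
#' `bait_fraction` of its genes; the remaining members are recorded as
#' held-out true candidates (the "missing pathway genes" the method is meant
#' to recover). `n_random_terms` negative-control terms draw genes uniformly
#' from the whole gene universe, with sizes sampled from `size_range` to
#' match the permutation-null grid.
#'
#' @param truth Truth tibble from [generate_compendium()].
#' @param bait_fraction Fraction of each module annotated, in (0, 1).
#' @param n_random_terms Number of random negative-control terms.
#' @param seed Integer seed.
#' @param size_range Sizes random terms are drawn from (default `5:30`).
#' @return A list with `annotation` (an [annotation_set()]; coherent terms are
#'   `"mod<m>"`, random terms `"rand<k>"`) and `held_out` (named list:
#'   coherent term -> held-out gene ids).
#' @export
make_annotation <- function(truth, bait_fraction = 0.5, n_random_terms = 0L,
                            seed = 1L, size_range = 5:30) {
  if (!is.numeric(bait_fraction) || bait_fraction <= 0 || bait_fraction >= 1) {
    stop_parameter("`bait_fraction` must lie in (0, 1)")
  }
  mods <- sort(unique(truth$module[!is.na(truth$module)]))
  res <- with_seed(seed, {
    held_out <- list()
    rows <- list()
    for (m in mods) {
      members <- truth$gene_id[!is.na(truth$module) & truth$module == m]
      n_bait <- max(1L, round(bait_fraction * length(members)))
      baits <- sort(sample(members, n_bait))
      tid <- sprintf("mod%02d", m)
      rows[[tid]] <- tibble(term_id = tid,
                            description = sprintf("planted module %d", m),
                            genes = list(baits))
      held_out[[tid]] <- setdiff(members, baits)
    }
    if (n_random_terms > 0L) {
      for (k in seq_len(n_random_terms)) {
        sz <- sample(size_range, 1L)
        tid <- sprintf("rand%03d", k)
        rows[[tid]] <- tibble(term_id = tid, description = "random control",
                              genes = list(sort(sample(truth$gene_id, sz))))
      }
    }
    list(rows = rows, held_out = held_out)
  })
  list(annotation = annotation_set(bind_rows(res$rows), source = "custom"),
       held_out = res$held_out)
}

#' Recovery of held-out genes among the top-ranked candidates
#'
#' @param result A `morph_result`.
#' @param held_out Character vector of true candidate gene ids.
#' @param k Rank cutoff (recall at k).
#' @return Fraction of `held_out` found in the top `k` ranked candidates.
#' @export
evaluate_recovery <- function(result, held_out, k = 100L) {
  stopifnot(inherits(result, "morph_result"))
  if (length(held_out) == 0L) stop_parameter("`held_out` must be non-empty")
  top <- result$candidates$gene_id[result$candidates$rank <= k]
  mean(held_out %in% top)
}

#' Write a synthetic compendium to the pipeline's TSV formats
#'
#' @param compendium A [generate_compendium()] result.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files (`dataset_id`, `expression_path`,
#'   `clustering_path`), invisibly.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map2(compendium$matrices, compendium$clusterings, function(m, cl) {
    ep <- file.path(dir, paste0(m$dataset_id, ".expression.tsv"))
    cp <- file.path(dir, paste0(m$dataset_id, ".clusters.tsv"))
    write_expression_matrix(m, ep)
    write_clustering(cl, cp)
    tibble(dataset_id = m$dataset_id, expression_path = ep, clustering_path = cp)
  })
  invisible(bind_rows(rows))
}
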