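# Genome-wide ("bulk") MORPH: job construction from a functional annotation,
# a permutation null over random bait sets, empirical p-values with BH
# correction, extended annotations and database-style record extraction.

#' Build MORPH jobs from a functional annotation
#'
#' Turns each annotation term into a bait set. Terms for which every dataset
#' contains fewer than `min_genes` of the annotated genes are discarded:
#' co-expression GBA gives unreliable results for very small bait sets,
#' especially under module partitioning. One dataset with enough genes
#' suffices to keep a term (model selection can then pick it).
#'
#' @param ann An [annotation_set()].
#' @param configs List of [configuration()] objects (datasets may repeat
#'   across clusterings; presence is counted per dataset).
#' @param min_genes Minimum bait genes required in at least one dataset
#'   (default 5).
#' @return A list of [bait_set()] objects; attribute `"discarded"` is a tibble
#'   of dropped terms with their per-dataset presence counts.
#' @export
build_jobs <- function(ann, configs, min_genes = 5L) {
  stopifnot(inherits(ann, "annotation_set"))
  if (inherits(configs, "configuration")) configs <- list(configs)
  if (length(configs) == 0L) stop_parameter("`configs` must be non-empty")
  datasets <- unique(vapply(configs, function(c) c$matrix$dataset_id, ""))
  universe <- lapply(configs, function(c) gene_ids(c$matrix))
  names(universe) <- vapply(configs, function(c) c$matrix$dataset_id, "")
  universe <- universe[!duplicated(names(universe))]

  counts <- vapply(ann$genes, function(g) {
    vapply(universe, function(u) sum(g %in% u), integer(1))
  }, integer(length(universe)))
  counts <- matrix(counts, nrow = length(universe),
                   dimnames = list(names(universe), ann$term_id))
  keep <- apply(counts, 2L, max) >= min_genes

  if (any(!keep)) {
    inform(sprintf("build_jobs: discarded %d term(s) with < %d genes in all data sets",
                   sum(!keep), min_genes))
  }
  discarded <- tibble(term_id = colnames(counts)[!keep])
  for (d in rownames(counts)) discarded[[paste0("n_", d)]] <- counts[d, !keep]

  jobs <- purrr::pmap(
    list(ann$term_id[keep], ann$genes[keep], ann$description[keep]),
    function(id, g, d) bait_set(id, g, d)
  )
  attr(jobs, "discarded") <- discarded
  jobs
}

#' Permutation null distribution of AUSR values
#'
#' For each bait-set size on the grid and each replicate: pick one dataset
#' uniformly at random, sample that many distinct genes from the chosen pool
#' restricted to that dataset, and run the full MORPH algorithm (model
#' selection included) on the random bait set, recording its AUSR. Replicate
#' streams are derived from the master seed by counters, so the result is
#' reproducible and independent of execution order. A replicate whose random
#' set is unscorable in every configuration records AUSR = 0.
#'
#' @param configs List of [configuration()] objects.
#' @param sizes Integer vector of bait-set sizes (default `5:30`).
#' @param n Replicates per size (default 1000).
#' @param seed Master integer seed.
#' @param gene_pool `"genome"` (all genes of the chosen dataset) or
#'   `"annotated"` (restricted to annotated genes; requires `annotation`).
#'   The two pools give near-identical nulls in practice.
#' @param annotation An [annotation_set()], needed when
#'   `gene_pool = "annotated"`.
#' @param r_max,min_baits_per_module Passed to [run_morph()].
#' @return An object of class `null_distribution`: list with `sizes`,
#'   `values` (named list, one numeric vector of length `n` per size), `n`,
#'   `seed`, `r_max`.
#' @export
random_null <- function(configs, sizes = 5:30, n = 1000L, seed = 1L,
                        gene_pool = c("genome", "annotated"), annotation = NULL,
                        r_max = 1000L, min_baits_per_module = 1L) {
  gene_pool <- match.arg(gene_pool)
  if (inherits(configs, "configuration")) configs <- list(configs)
  if (length(configs) == 0L) stop_parameter("`configs` must be non-empty")
  if (gene_pool == "annotated" && is.null(annotation)) {
    stop_parameter("`annotation` is required when gene_pool = 'annotated'")
  }
  datasets <- vapply(configs, function(c) c$matrix$dataset_id, "")
  uniq <- !duplicated(datasets)
  pool_by_ds <- lapply(configs[uniq], function(c) {
    p <- gene_ids(c$matrix)
    if (gene_pool == "annotated") p <- intersect(p, annotated_genes(annotation))
    p
  })
  names(pool_by_ds) <- datasets[uniq]
  max_size <- max(sizes)
  if (all(lengths(pool_by_ds) < max_size)) {
    stop_parameter(sprintf("no dataset pool holds %d genes", max_size))
  }

  values <- vector("list", length(sizes))
  names(values) <- as.character(sizes)
  for (si in seq_along(sizes)) {
    S <- sizes[si]
    vals <- numeric(n)
    for (j in seq_len(n)) {
      vals[j] <- with_seed(derive_seed(seed, S, j), {
        ok <- names(pool_by_ds)[lengths(pool_by_ds) >= S]
        ds <- ok[sample.int(length(ok), 1L)]
        g <- sample(pool_by_ds[[ds]], S)
        tryCatch(
          run_morph(configs, bait_set("random", g), r_max, min_baits_per_module)$ausr,
          morphr_empty_scorable_error = function(e) 0
        )
      })
    }
    values[[si]] <- vals
  }
  structure(list(sizes = as.integer(sizes), values = values, n = as.integer(n),
                 seed = as.integer(seed), r_max = as.integer(r_max)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> sizes %d..%d, %d replicates/size, r_max %d, seed %d\n",
              min(x$sizes), max(x$sizes), x$n, x$r_max, x$seed))
  invisible(x)
}

#' Empirical p-value of an observed AUSR
#'
#' The fraction of random bait sets of the same size whose AUSR strictly
#' exceeds the observed `AUSR*`. Sizes outside the null grid are clamped to
#' its boundary (conservative above the grid: larger random sets score lower
#' by chance, so the size-30 null overestimates p). A p of exactly 0 is
#' reported as 0 (no pseudocount) unless `pseudocount = TRUE`, which applies
#' the (count + 1)/(n + 1) variant.
#'
#' @param ausr_star Observed AUSR.
#' @param size Bait-set size the AUSR was observed at.
#' @param null A [random_null()] result.
#' @param pseudocount Apply the +1/(n+1) correction (default `FALSE`).
#' @return Empirical p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(ausr_star, size, null, pseudocount = FALSE) {
  stopifnot(inherits(null, "null_distribution"))
  s <- min(max(as.integer(size), min(null$sizes)), max(null$sizes))
  if (!s %in% null$sizes) {
    # non-contiguous grid: snap to nearest available size
    s <- null$sizes[which.min(abs(null$sizes - s))]
  }
  vals <- null$values[[as.character(s)]]
  cnt <- sum(vals > ausr_star)
  if (pseudocount) (cnt + 1) / (length(vals) + 1) else cnt / length(vals)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR correction with monotonicity enforcement; input order
#' preserved. `NA` entries pass through as `NA`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop_parameter("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Run MORPH in bulk over a set of jobs
#'
#' Runs [run_morph()] for every bait set, attaches empirical p-values from the
#' permutation null and BH q-values (computed across the successful jobs of
#' this run; callers wanting separate correction per annotation source run
#' the sources separately). A job for which no configuration is usable is
#' recorded as a failed row, not an error. Deterministic given inputs.
#'
#' @param jobs List of [bait_set()] objects, e.g. from [build_jobs()].
#' @param configs List of [configuration()] objects.
#' @param null A [random_null()] result covering the size grid.
#' @param r_max,min_baits_per_module Passed to [run_morph()].
#' @param pseudocount Passed to [empirical_pvalue()].
#' @return An object of class `bulk_result`: list with `summary` (tibble:
#'   `term_id`, `n_genes_annotated`, `n_baits_used`, `chosen_config_id`,
#'   `ausr`, `p_value`, `q_value`, `status`) and `results` (named list of
#'   `morph_result`s for the successful jobs).
#' @export
run_bulk <- function(jobs, configs, null, r_max = 1000L,
                     min_baits_per_module = 1L, pseudocount = FALSE) {
  stopifnot(inherits(null, "null_distribution"))
  if (inherits(jobs, "bait_set")) jobs <- list(jobs)
  rows <- vector("list", length(jobs))
  results <- list()
  for (i in seq_along(jobs)) {
    job <- jobs[[i]]
    res <- tryCatch(run_morph(configs, job, r_max, min_baits_per_module),
                    morphr_empty_scorable_error = function(e) NULL)
    if (is.null(res)) {
      rows[[i]] <- tibble(term_id = job$term_id,
                          n_genes_annotated = length(job$genes),
                          n_baits_used = NA_integer_,
                          chosen_config_id = NA_character_,
                          ausr = NA_real_, p_value = NA_real_,
                          status = "failed")
    } else {
      results[[job$term_id]] <- res
      rows[[i]] <- tibble(term_id = job$term_id,
                          n_genes_annotated = length(job$genes),
                          n_baits_used = res$n_baits_used,
                          chosen_config_id = res$chosen_config_id,
                          ausr = res$ausr,
                          p_value = empirical_pvalue(res$ausr, length(job$genes),
                                                     null, pseudocount),
                          status = "ok")
    }
  }
  summary <- bind_rows(rows)
  summary$q_value <- bh_adjust(summary$p_value)
  summary <- summary[, c("term_id", "n_genes_annotated", "n_baits_used",
                         "chosen_config_id", "ausr", "p_value", "q_value",
                         "status")]
  structure(list(summary = summary, results = results, r_max = as.integer(r_max)),
            class = "bulk_result")
}

#' @export
print.bulk_result <- function(x, ...) {
  ok <- x$summary$status == "ok"
  cat(sprintf("<bulk_result> %d terms (%d ok, %d failed); %d with p < 0.05\n",
              nrow(x$summary), sum(ok), sum(!ok),
              sum(x$summary$p_value < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Extended functional annotations from significant bulk runs
#'
#' For every term significant after FDR correction (`q_value < q_threshold`),
#' emits the candidates whose co-expression z-score exceeds `z_threshold`
#' (default 1.96, the 97.5% point of the standard-normal null) as new
#' `(gene, term)` annotations with evidence tag `"MORPH"`. Both cutoffs are
#' strict inequalities.
#'
#' @param bulk A [run_bulk()] result.
#' @param q_threshold FDR cutoff (default 0.05).
#' @param z_threshold z-score cutoff (default `qnorm(0.975)` printed as 1.96).
#' @param annotation Optional [annotation_set()]; when given, the attribute
#'   `"n_first_annotation"` counts emitted genes with no prior annotation.
#' @return Tibble with columns `gene_id`, `term_id`, `z`, `evidence`.
#' @export
extend_annotations <- function(bulk, q_threshold = 0.05, z_threshold = 1.96,
                               annotation = NULL) {
  stopifnot(inherits(bulk, "bulk_result"))
  sig <- bulk$summary$term_id[!is.na(bulk$summary$q_value) &
                                bulk$summary$q_value < q_threshold]
  rows <- purrr::map(sig, function(tid) {
    cand <- bulk$results[[tid]]$candidates
    cand <- cand[cand$z > z_threshold, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    tibble(gene_id = cand$gene_id, term_id = tid, z = cand$z, evidence = "MORPH")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(gene_id = character(), term_id = character(),
                  z = numeric(), evidence = character())
  }
  if (!is.null(annotation)) {
    known <- annotated_genes(annotation)
    attr(out, "n_first_annotation") <- length(setdiff(unique(out$gene_id), known))
  }
  out
}

#' Candidate records for database storage
#'
#' For every term with empirical p-value strictly below `p_threshold`
#' (default 0.10), keeps the up-to-`top_k` highest-ranked candidates whose z
#' exceeds `z_threshold` (default 1.28, the 90% point of the standard-normal
#' null) — the storage rule used for cross-species candidate databases.
#'
#' @param bulk A [run_bulk()] result.
#' @param p_threshold Empirical p cutoff (default 0.10, strict).
#' @param top_k Maximum candidates stored per term (default 100).
#' @param z_threshold z cutoff (default 1.28, strict).
#' @return Tibble with `term_id`, `gene_id`, `module_id`, `z`, `rank`, `ausr`,
#'   `p_value`.
#' @export
morphdb_records <- function(bulk, p_threshold = 0.10, top_k = 100L,
                            z_threshold = 1.28) {
  stopifnot(inherits(bulk, "bulk_result"))
  keep <- !is.na(bulk$summary$p_value) & bulk$summary$p_value < p_threshold
  rows <- purrr::map2(bulk$summary$term_id[keep], which(keep), function(tid, i) {
    cand <- bulk$results[[tid]]$candidates
    cand <- cand[cand$z > z_threshold, , drop = FALSE]
    cand <- cand[order(cand$rank), , drop = FALSE]
    cand <- head(cand, top_k)
    if (nrow(cand) == 0L) return(NULL)
    tibble(term_id = tid, gene_id = cand$gene_id, module_id = cand$module_id,
           z = cand$z, rank = cand$rank,
           ausr = bulk$summary$ausr[i], p_value = bulk$summary$p_value[i])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(term_id = character(), gene_id = character(),
                  module_id = integer(), z = numeric(), rank = integer(),
                  ausr = numeric(), p_value = numeric())
  }
  out
}

#' Write a bulk summary table to TSV
#'
#' @param bulk A [run_bulk()] result (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulk_summary <- function(bulk, path) {
  tbl <- if (inherits(bulk, "bulk_result")) bulk$summary else as_tibble(bulk)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
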