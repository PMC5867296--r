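#' Construct a bait set
#'
#' A functional term (GO / MapMan / custom id) together with the genes
#' annotated to it, used as the query for candidate prioritization.
#'
#' @param term_id Term identifier, e.g. `"GO:0006952"`.
#' @param genes Character vector of gene ids (made unique); must be non-empty.
#' @param description Free-text term description.
#' @return An object of class `bait_set`.
#' @export
bait_set <- function(term_id, genes, description = "") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop_validation("a bait set must contain at least one gene")
  structure(list(term_id = as.character(term_id), description = as.character(description),
                 genes = genes),
            class = "bait_set")
}

#' @export
print.bait_set <- function(x, ...) {
  cat(sprintf("<bait_set> %s (%d genes) %s\n", x$term_id, length(x$genes), x$description))
  invisible(x)
}

# Core scorer, kept free of tibble/dplyr overhead because LOOCV and the
# permutation null call it thousands of times.
#
# Returns NULL when no bait is present in any module (the caller decides
# whether that is an error or an UNSCORED outcome), otherwise a list of
# equal-length vectors already in rank order (z descending, ties broken
# lexicographically by gene_id).
score_core <- function(config, bait_genes, min_baits_per_module = 1L) {
  present <- intersect(bait_genes, gene_ids(config$matrix))
  assignment <- config$clustering$assignment
  in_mod <- present[present %in% names(assignment)]
  if (length(in_mod) == 0L) return(NULL)
  mods <- unique(unname(assignment[in_mod]))
  members_all <- module_members(config)

  gene <- character(); module <- integer(); raw <- numeric(); z <- numeric()
  for (mid in mods) {
    members <- members_all[[as.character(mid)]]
    bm <- intersect(members, present)
    if (length(bm) < min_baits_per_module) next
    cands <- setdiff(members, present)
    if (length(cands) == 0L) next
    cm <- module_cor(config, mid, members)
    r <- unname(rowMeans(cm[cands, bm, drop = FALSE]))
    s <- sd(r)
    zz <- if (!is.finite(s) || s < 1e-12) rep(0, length(r)) else (r - mean(r)) / s
    gene <- c(gene, cands)
    module <- c(module, rep(as.integer(mid), length(cands)))
    raw <- c(raw, unname(r))
    z <- c(z, zz)
  }
  if (length(gene) == 0L) {
    # baits reached a module but every member is a bait: scorable yet empty
    return(list(gene_id = character(), module_id = integer(),
                raw_score = numeric(), z = numeric(), rank = integer()))
  }
  o <- order(-z, gene)
  list(gene_id = gene[o], module_id = module[o], raw_score = raw[o], z = z[o],
       rank = seq_along(o))
}

#' Score candidate genes against a bait set
#'
#' The module-partitioned co-expression metric. With `B` the bait genes
#' present in the configuration's matrix: for every module holding at least
#' `min_baits_per_module` of `B`, each module member outside `B` (a
#' candidate) receives the mean Pearson correlation of its expression profile
#' with the in-module baits (`raw_score`), standardized within the module over
#' its candidates to a z-score. Candidates from all scored modules are pooled
#' and ranked by z descending (rank 1 = best; ties broken lexicographically by
#' gene id). Unclustered genes, genes in modules without baits, and bait genes
#' themselves receive no score. Modules whose candidates share a single raw
#' score (SD < 1e-12) get z = 0 throughout.
#'
#' @param config A [configuration()].
#' @param baits A [bait_set()] (or character vector of gene ids).
#' @param min_baits_per_module Minimum baits a module needs to be scored
#'   (default 1).
#' @return A tibble with columns `gene_id`, `module_id`, `raw_score`, `z`,
#'   `rank`, sorted by rank.
#' @export
score_candidates <- function(config, baits, min_baits_per_module = 1L) {
  stopifnot(inherits(config, "configuration"))
  genes <- if (inherits(baits, "bait_set")) baits$genes else unique(as.character(baits))
  res <- score_core(config, genes, min_baits_per_module)
  if (is.null(res)) stop_empty_scorable()
  as_tibble(res)
}

#' Self-rank of a left-out bait gene
#'
#' One leave-one-out cross-validation step: candidates are scored against
#' `G' = G \ {left_out}` and the rank that `left_out` receives as a candidate
#' is returned. `NA` (UNSCORED) is returned when the left-out gene cannot be
#' scored in this configuration: it is absent from the matrix, unclustered,
#' or its module retains no other bait.
#'
#' @inheritParams score_candidates
#' @param left_out A gene id from the bait set.
#' @return Integer rank, or `NA` for UNSCORED.
#' @export
self_rank <- function(config, baits, left_out, min_baits_per_module = 1L) {
  stopifnot(inherits(config, "configuration"))
  genes <- if (inherits(baits, "bait_set")) baits$genes else unique(as.character(baits))
  if (!left_out %in% genes) stop_parameter(sprintf("'%s' is not a bait gene", left_out))
  res <- score_core(config, setdiff(genes, left_out), min_baits_per_module)
  if (is.null(res)) return(NA_integer_)
  hit <- match(left_out, res$gene_id)
  if (is.na(hit)) NA_integer_ else res$rank[hit]
}

# LOOCV over every bait gene; returns a named integer vector (NA = UNSCORED),
# or NULL when the configuration is unusable for this bait set.
loocv_self_ranks <- function(config, genes, min_baits_per_module = 1L) {
  any_scorable <- FALSE
  ranks <- setNames(rep(NA_integer_, length(genes)), genes)
  for (g in genes) {
    res <- score_core(config, setdiff(genes, g), min_baits_per_module)
    if (is.null(res)) next
    any_scorable <- TRUE
    hit <- match(g, res$gene_id)
    if (!is.na(hit)) ranks[g] <- res$rank[hit]
  }
  # also unusable if the full bait set reaches no module at all
  if (!any_scorable && is.null(score_core(config, genes, min_baits_per_module))) {
    return(NULL)
  }
  ranks
}

#' Area under the self-rank curve (AUSR)
#'
#' Summarises a collection of LOOCV self-ranks into a single number in
#' \[0, 1\]: `AUSR = (1 / (|G| * r_max)) * sum_i max(0, r_max - r_i + 1)`,
#' where an UNSCORED gene (`NA`) contributes 0. Equivalently, the mean over
#' thresholds `t = 1..r_max` of the fraction of bait genes with self-rank
#' `<= t`. 1 is a perfect score (every bait recovers itself at rank 1); ranks
#' beyond `r_max` contribute nothing.
#'
#' @param self_ranks Integer vector of ranks, `NA` = UNSCORED; non-empty.
#' @param r_max Rank-threshold ceiling (default 1000).
#' @return AUSR in \[0, 1\].
#' @export
ausr <- function(self_ranks, r_max = 1000L) {
  if (length(self_ranks) == 0L) stop_parameter("`self_ranks` must be non-empty")
  if (!is.numeric(r_max) || length(r_max) != 1L || is.na(r_max) || r_max < 1) {
    stop_parameter("`r_max` must be a positive integer")
  }
  r <- as.numeric(self_ranks)
  credit <- pmax(0, r_max - r + 1)
  credit[is.na(credit)] <- 0
  sum(credit) / (length(r) * as.numeric(r_max))
}

#' Select the best configuration for a bait set
#'
#' Model selection: LOOCV self-ranks and AUSR are computed independently for
#' every configuration; the configuration with maximal AUSR wins, ties broken
#' by input order. Configurations in which no bait is scorable are skipped.
#'
#' @param configs List of [configuration()] objects.
#' @param baits A [bait_set()] (or character vector).
#' @param r_max Rank-threshold ceiling for the AUSR (default 1000).
#' @param min_baits_per_module See [score_candidates()].
#' @return A list with elements `config`, `ausr`, `self_ranks`,
#'   `per_config` (named AUSR vector over usable configurations).
#' @export
select_config <- function(configs, baits, r_max = 1000L, min_baits_per_module = 1L) {
  if (inherits(configs, "configuration")) configs <- list(configs)
  if (length(configs) == 0L) stop_parameter("`configs` must be non-empty")
  genes <- if (inherits(baits, "bait_set")) baits$genes else unique(as.character(baits))
  best <- NULL
  per_config <- numeric()
  for (cfg in configs) {
    ranks <- loocv_self_ranks(cfg, genes, min_baits_per_module)
    if (is.null(ranks)) next
    a <- ausr(ranks, r_max)
    per_config[cfg$config_id] <- a
    if (is.null(best) || a > best$ausr) {
      best <- list(config = cfg, ausr = a, self_ranks = ranks)
    }
  }
  if (is.null(best)) stop_empty_scorable("no configuration can score this bait set")
  best$per_config <- per_config
  best
}

#' Run MORPH for one bait set
#'
#' The full algorithm: model selection by LOOCV/AUSR across configurations,
#' then candidate scoring with the complete bait set on the winning
#' configuration.
#'
#' @inheritParams select_config
#' @return A `morph_result`: list with `term_id`, `chosen_config_id`, `ausr`,
#'   `self_ranks` (named, `NA` = UNSCORED), `candidates` (ranked tibble, see
#'   [score_candidates()]), `n_baits_used`, `r_max`.
#' @export
run_morph <- function(configs, baits, r_max = 1000L, min_baits_per_module = 1L) {
  if (!inherits(baits, "bait_set")) baits <- bait_set("custom", baits)
  sel <- select_config(configs, baits, r_max, min_baits_per_module)
  cand <- score_candidates(sel$config, baits, min_baits_per_module)
  structure(
    list(term_id = baits$term_id,
         chosen_config_id = sel$config$config_id,
         ausr = sel$ausr,
         self_ranks = sel$self_ranks,
         candidates = cand,
         n_baits_used = sum(baits$genes %in% gene_ids(sel$config$matrix)),
         r_max = as.integer(r_max),
         per_config_ausr = sel$per_config),
    class = "morph_result"
  )
}

#' @export
print.morph_result <- function(x, ...) {
  cat(sprintf("<morph_result> %s | config %s | AUSR %.3f | %d baits | %d candidates\n",
              x$term_id, x$chosen_config_id, x$ausr, x$n_baits_used,
              nrow(x$candidates)))
  invisible(x)
}

#' Serialize a MORPH result to TSV
#'
#' Writes the ranked candidate table (`term_id`, `config_id`, `gene_id`,
#' `module_id`, `raw_score`, `z`, `rank`) and, alongside it
#' (`<path>.summary.tsv` unless given), a one-line summary (`term_id`,
#' `config_id`, `n_baits_used`, `ausr`).
#'
#' @param x A `morph_result`.
#' @param path Candidate-table output path.
#' @param summary_path Summary output path.
#' @return `path`, invisibly.
#' @export
write_morph_result <- function(x, path, summary_path = paste0(path, ".summary.tsv")) {
  stopifnot(inherits(x, "morph_result"))
  cand <- dplyr::mutate(x$candidates, term_id = x$term_id,
                        config_id = x$chosen_config_id, .before = 1L)
  readr::write_tsv(cand, path, progress = FALSE)
  readr::write_tsv(
    tibble(term_id = x$term_id, config_id = x$chosen_config_id,
           n_baits_used = x$n_baits_used, ausr = x$ausr),
    summary_path, progress = FALSE
  )
  invisible(path)
}
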