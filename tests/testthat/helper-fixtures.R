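# Fixtures built in code: tiny expression matrices, block-partitioned noise
# compendia, and independent brute-force oracles for scoring and AUSR.

tiny_matrix <- function(values, dataset_id = "tiny", platform = "microarray") {
  expression_matrix(values, dataset_id, platform)
}

rand_matrix <- function(n_genes, n_samples, seed, dataset_id = "rand",
                        platform = "microarray") {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes,
                 dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(vals, dataset_id, platform)
}

# Pure-noise dataset partitioned into contiguous equal-size modules.
noise_config <- function(n_genes, n_samples, n_modules, seed,
                         dataset_id = "noise") {
  m <- rand_matrix(n_genes, n_samples, seed, dataset_id)
  assignment <- setNames(rep(seq_len(n_modules), length.out = n_genes),
                         rownames(m$values))
  cl <- clustering_solution(assignment, "blocks", dataset_id)
  configuration(m, cl)
}

# Independent brute-force implementation of the module-partitioned scoring:
# plain double loops over stats::cor, no shared code with score_candidates.
brute_force_scores <- function(values, assignment, baits, min_baits = 1L) {
  present <- intersect(baits, rownames(values))
  gene <- character(); z_all <- numeric()
  for (mid in unique(unname(assignment))) {
    members <- names(assignment)[assignment == mid]
    bm <- intersect(members, present)
    if (length(bm) < min_baits) next
    cands <- setdiff(members, present)
    if (length(cands) == 0L) next
    raw <- vapply(cands, function(g) {
      mean(vapply(bm, function(b) {
        if (stats::sd(values[g, ]) < 1e-12 || stats::sd(values[b, ]) < 1e-12) {
          return(0)
        }
        stats::cor(values[g, ], values[b, ])
      }, numeric(1)))
    }, numeric(1))
    s <- stats::sd(raw)
    z <- if (!is.finite(s) || s < 1e-12) rep(0, length(raw)) else (raw - mean(raw)) / s
    gene <- c(gene, cands); z_all <- c(z_all, z)
  }
  if (length(gene) == 0L) return(NULL)
  o <- order(-z_all, gene)
  data.frame(gene_id = gene[o], z = z_all[o], rank = seq_along(o),
             stringsAsFactors = FALSE)
}

# Threshold-sum definition of the AUSR: mean over t = 1..r_max of the
# fraction of baits with self-rank <= t, accumulated as an integer numerator.
ausr_threshold_sum <- function(ranks, r_max) {
  num <- 0L
  for (t in seq_len(r_max)) num <- num + sum(!is.na(ranks) & ranks <= t)
  num / (length(ranks) * r_max)
}

# Compendium with one planted coherent module among noise genes.
planted_config <- function(n_module_genes = 12L, n_noise = 24L,
                           n_samples = 40L, rho = 0.9, seed = 1L,
                           dataset_id = "planted") {
  set.seed(seed)
  n <- n_module_genes + n_noise
  f <- rnorm(n_samples)
  vals <- rbind(
    sqrt(rho) * matrix(f, n_module_genes, n_samples, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(n_module_genes * n_samples), n_module_genes),
    matrix(rnorm(n_noise * n_samples), n_noise)
  )
  dimnames(vals) <- list(sprintf("g%04d", seq_len(n)),
                         sprintf("s%03d", seq_len(n_samples)))
  m <- expression_matrix(vals, dataset_id, "microarray")
  assignment <- setNames(c(rep(1L, n_module_genes),
                           rep(2:4, length.out = n_noise)),
                         rownames(vals))
  configuration(m, clustering_solution(assignment, "truth", dataset_id))
}
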