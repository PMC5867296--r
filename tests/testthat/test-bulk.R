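# Genome-wide pipeline: job filtering, permutation null, empirical p-values,
# BH correction, extended annotations and record extraction.

# Compendium whose clustering lumps each planted module with a share of
# background genes, as real clustering solutions do: coherent candidates then
# stand out within their module (high z) instead of competing only against
# each other.
make_bulk_fixture <- function(seed = 1) {
  spec <- synthetic_spec(n_modules = 4, genes_per_module = 10,
                         n_background_genes = 120, n_samples = 30,
                         n_datasets = 2, rho = 0.9, seed = seed)
  comp <- generate_compendium(spec)
  configs <- lapply(comp$matrices, function(m) {
    truth_mod <- comp$truth$module
    bg <- which(is.na(truth_mod))
    asg <- truth_mod
    asg[bg] <- rep(seq_len(spec$n_modules), length.out = length(bg))
    cl <- clustering_solution(setNames(asg, comp$truth$gene_id),
                              "coarse", m$dataset_id)
    configuration(m, cl)
  })
  comp$configurations <- configs
  ann <- make_annotation(comp$truth, bait_fraction = 0.5, n_random_terms = 3,
                         seed = seed + 100, size_range = 5:10)
  list(comp = comp, ann = ann)
}

test_that("jobs with too few genes in every dataset are discarded", {
  fx <- make_bulk_fixture()
  configs <- fx$comp$configurations
  genes <- fx$comp$truth$gene_id

  ann <- annotation_set(tibble::tibble(
    term_id = c("small", "ok", "absent", "partial"),
    genes = list(genes[1:4],                       # 4 genes everywhere -> drop
                 genes[1:5],                       # 5 genes everywhere -> keep
                 paste0("x", 1:6),                 # present nowhere -> drop
                 c(genes[1:5], paste0("x", 1:3)))  # 5 present -> keep
  ))
  jobs <- build_jobs(ann, configs, min_genes = 5)
  expect_setequal(vapply(jobs, function(j) j$term_id, ""), c("ok", "partial"))
  disc <- attr(jobs, "discarded")
  expect_setequal(disc$term_id, c("small", "absent"))
  expect_true(all(disc[disc$term_id == "small", -1] == 4))

  expect_error(build_jobs(ann, list()), class = "morphr_parameter_error")
})

test_that("a term kept by one dataset survives even if another dataset lacks it", {
  fx <- make_bulk_fixture()
  cfg1 <- fx$comp$configurations[[1]]
  # second dataset restricted to genes that exclude the term's members
  m2 <- fx$comp$matrices[[2]]
  drop <- fx$comp$truth$gene_id[1:10]
  keep_genes <- setdiff(rownames(m2$values), drop)
  m2small <- expression_matrix(m2$values[keep_genes, ], "ds02", "microarray")
  cl2 <- clustering_solution(
    fx$comp$clusterings[[2]]$assignment[
      names(fx$comp$clusterings[[2]]$assignment) %in% keep_genes],
    "truth", "ds02",
    intersect(fx$comp$clusterings[[2]]$unclustered, keep_genes))
  cfg2 <- configuration(m2small, cl2)

  ann <- annotation_set(tibble::tibble(term_id = "t", genes = list(drop[1:5])))
  jobs <- build_jobs(ann, list(cfg1, cfg2), min_genes = 5)
  expect_equal(length(jobs), 1L)  # 5 genes in ds01, 0 in ds02 -> kept
})

test_that("the permutation null is reproducible and behaves as a null should", {
  # pure-noise data, several alternative clusterings to select among; the
  # rank ceiling is on the scale of the candidate pool (scaled-down genome)
  m <- rand_matrix(150, 20, seed = 3, dataset_id = "noise")
  configs <- lapply(1:4, function(k) {
    set.seed(100 + k)
    asg <- setNames(sample(rep(1:3, length.out = 150)), rownames(m$values))
    configuration(m, clustering_solution(asg, paste0("cl", k), "noise"))
  })
  null <- random_null(configs, sizes = c(5, 10), n = 50, seed = 11, r_max = 100)
  expect_true(all(unlist(null$values) >= 0 & unlist(null$values) <= 1))
  expect_equal(lengths(null$values), c(`5` = 50L, `10` = 50L))
  # smaller random sets score higher by chance (model selection amplifies
  # the higher sampling variance of small-set AUSRs)
  expect_gte(mean(null$values[["5"]]), mean(null$values[["10"]]))

  null2 <- random_null(configs, sizes = c(5, 10), n = 50, seed = 11, r_max = 100)
  expect_identical(null, null2)

  # genome vs annotated pools: indistinguishable AUSR distributions on noise
  ann <- annotation_set(tibble::tibble(
    term_id = "all", genes = list(rownames(m$values)[1:120])))
  null_ann <- random_null(configs[1], sizes = 10, n = 100, seed = 12,
                          gene_pool = "annotated", annotation = ann)
  null_gen <- random_null(configs[1], sizes = 10, n = 100, seed = 13)
  ks <- suppressWarnings(stats::ks.test(null_ann$values[["10"]],
                                        null_gen$values[["10"]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("empirical p-values count strict exceedances with size clamping", {
  null <- structure(list(sizes = c(5L, 10L),
                         values = list(`5` = c(0.1, 0.2, 0.3), `10` = c(0.5, 0.6, 0.7)),
                         n = 3L, seed = 1L, r_max = 1000L),
                    class = "null_distribution")
  expect_equal(empirical_pvalue(0.25, 5, null), 1 / 3)
  expect_equal(empirical_pvalue(0.95, 5, null), 0)
  expect_equal(empirical_pvalue(-1, 5, null), 1)
  # clamping: size above the grid uses the largest size's null
  expect_equal(empirical_pvalue(0.55, 40, null), 2 / 3)
  expect_equal(empirical_pvalue(0.15, 2, null), 2 / 3)
  # pseudocount variant
  expect_equal(empirical_pvalue(0.95, 5, null, pseudocount = TRUE), 1 / 4)

  # brute-force re-count agreement on random draws
  set.seed(30)
  vals <- runif(200)
  null2 <- structure(list(sizes = 7L, values = list(`7` = vals), n = 200L,
                          seed = 1L, r_max = 1000L),
                     class = "null_distribution")
  for (a in runif(20)) {
    expect_equal(empirical_pvalue(a, 7, null2), sum(vals > a) / 200)
  }
})

test_that("BH adjustment is the standard step-up with order preserved", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(31)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_equal(q, p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "morphr_parameter_error")
})

test_that("run_bulk attaches p and q per term, records failures, and is deterministic", {
  fx <- make_bulk_fixture(seed = 5)
  configs <- fx$comp$configurations
  jobs <- build_jobs(fx$ann$annotation, configs)
  jobs <- c(jobs, list(bait_set("ghost", paste0("zz", 1:6))))
  null <- random_null(configs, sizes = c(5, 6, 7, 8, 9, 10), n = 30, seed = 2)

  bulk <- run_bulk(jobs, configs, null)
  expect_equal(nrow(bulk$summary), length(jobs))
  ok <- bulk$summary$status == "ok"
  expect_true(all(bulk$summary$ausr[ok] >= 0 & bulk$summary$ausr[ok] <= 1))
  expect_true(all(bulk$summary$q_value[ok] >= bulk$summary$p_value[ok]))
  expect_equal(bulk$summary$status[bulk$summary$term_id == "ghost"], "failed")

  # deterministic: identical inputs give byte-identical summaries
  bulk2 <- run_bulk(jobs, configs, null)
  f1 <- tempfile(); f2 <- tempfile()
  write_bulk_summary(bulk, f1); write_bulk_summary(bulk2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # planted terms beat random terms
  planted_p <- bulk$summary$p_value[grepl("^mod", bulk$summary$term_id)]
  random_p <- bulk$summary$p_value[grepl("^rand", bulk$summary$term_id)]
  expect_lt(max(planted_p), 0.05)
  expect_lt(mean(planted_p), mean(random_p))
})

test_that("extended annotations and stored records respect their thresholds", {
  fx <- make_bulk_fixture(seed = 8)
  configs <- fx$comp$configurations
  jobs <- build_jobs(fx$ann$annotation, configs)
  null <- random_null(configs, sizes = 5:10, n = 40, seed = 4)
  bulk <- run_bulk(jobs, configs, null)

  ext <- extend_annotations(bulk, q_threshold = 0.05, z_threshold = 1.96,
                            annotation = fx$ann$annotation)
  # every emitted gene is in its term's candidate table with z above cutoff
  for (i in seq_len(nrow(ext))) {
    cand <- bulk$results[[ext$term_id[i]]]$candidates
    expect_true(ext$gene_id[i] %in% cand$gene_id[cand$z > 1.96])
  }
  expect_true(all(ext$evidence == "MORPH"))
  # a non-significant term contributes nothing
  not_sig <- bulk$summary$term_id[!is.na(bulk$summary$q_value) &
                                    bulk$summary$q_value >= 0.05]
  expect_false(any(ext$term_id %in% not_sig))
  expect_true(is.numeric(attr(ext, "n_first_annotation")))

  # boundary: z exactly at the cutoff is excluded
  fake <- bulk
  tid <- ext$term_id[1]
  fake$results[[tid]]$candidates$z[] <- 1.96
  expect_equal(nrow(extend_annotations(fake, z_threshold = 1.96)[
    extend_annotations(fake, z_threshold = 1.96)$term_id == tid, ]), 0L)

  rec <- morphdb_records(bulk, p_threshold = 0.10, top_k = 3, z_threshold = 1.28)
  expect_true(all(rec$z > 1.28))
  expect_true(all(table(rec$term_id) <= 3))
  by_term <- split(rec, rec$term_id)
  for (tt in by_term) expect_equal(tt$rank, sort(tt$rank))
  # p exactly at the threshold is excluded
  fake2 <- bulk
  fake2$summary$p_value[] <- 0.10
  expect_equal(nrow(morphdb_records(fake2)), 0L)
})

test_that("stricter extension output is nested in the stored-record space when q <= p holds", {
  fx <- make_bulk_fixture(seed = 13)
  configs <- fx$comp$configurations
  jobs <- build_jobs(fx$ann$annotation, configs)
  null <- random_null(configs, sizes = 5:10, n = 40, seed = 9)
  bulk <- run_bulk(jobs, configs, null)
  ext <- extend_annotations(bulk)
  rec <- morphdb_records(bulk, top_k = 10000L)
  # p <= q always (BH), so q < 0.05 implies p < 0.10, and z > 1.96 implies
  # z > 1.28: every extended annotation must be among the stored records
  expect_gt(nrow(ext), 0)
  expect_true(all(paste(ext$term_id, ext$gene_id) %in%
                    paste(rec$term_id, rec$gene_id)))
})
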