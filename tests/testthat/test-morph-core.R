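# The MORPH algorithm: module-partitioned scoring, LOOCV self-ranks, AUSR
# and configuration selection, checked against independent brute-force
# oracles.

test_that("scoring matches a brute-force oracle on random instances", {
  for (seed in 1:10) {
    cfg <- noise_config(30, 10, n_modules = 3, seed = seed)
    set.seed(seed + 1000)
    baits <- sample(rownames(cfg$matrix$values), 5)
    got <- score_candidates(cfg, baits)
    want <- brute_force_scores(cfg$matrix$values, cfg$clustering$assignment, baits)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$rank, want$rank)
    expect_equal(got$z, want$z, tolerance = 1e-9)
  }
})

test_that("a candidate identical to its module's baits tops the ranking", {
  cfg <- planted_config(seed = 4)
  vals <- cfg$matrix$values
  # make g0001 an exact copy of the mean bait profile's module-mates
  baits <- c("g0002", "g0003", "g0004")
  vals["g0001", ] <- vals["g0002", ]
  m <- expression_matrix(vals, "planted", "microarray")
  cfg2 <- configuration(m, cfg$clustering)
  sc <- score_candidates(cfg2, baits)
  expect_equal(sc$gene_id[1], "g0001")
  top <- sc[sc$gene_id == "g0001", ]
  expect_gt(top$raw_score, max(sc$raw_score[-1]) - 1e-12)
  # its correlation with the copied bait is exactly 1
  expect_equal(cor(vals["g0001", ], vals["g0002", ]), 1)
})

test_that("degenerate modules yield z = 0 and baits/unclustered genes get no score", {
  vals <- matrix(rnorm(8 * 6), 8,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  vals[3, ] <- vals[2, ]  # candidates g3, g4 will tie only if identical scores
  m <- expression_matrix(vals, "d", "microarray")
  # module 1 = g1 (bait), g2, g3 with g3 == g2 -> equal raw scores -> SD 0
  vals[2, ] <- vals[3, ]
  m <- expression_matrix(vals, "d", "microarray")
  cl <- clustering_solution(setNames(c(1L, 1L, 1L, 2L, 2L), paste0("g", 1:5)),
                            "c", "d", unclustered = c("g6", "g7", "g8"))
  cfg <- configuration(m, cl)
  sc <- score_candidates(cfg, c("g1", "g6"))
  expect_setequal(sc$gene_id, c("g2", "g3"))   # module 2 has no bait; g6 unclustered
  expect_equal(sc$z, c(0, 0))                  # degenerate-module rule
  expect_equal(sc$rank, 1:2)                   # lexicographic tie break

  expect_error(score_candidates(cfg, "g7"), class = "morphr_empty_scorable_error")
})

test_that("scoring is invariant to positive affine transforms and sample order", {
  cfg <- noise_config(24, 12, n_modules = 2, seed = 8)
  baits <- rownames(cfg$matrix$values)[c(1, 5, 13)]
  base <- score_candidates(cfg, baits)

  vals <- cfg$matrix$values
  set.seed(42)
  vals2 <- vals * runif(nrow(vals), 0.5, 3) + rnorm(nrow(vals))
  cfg2 <- configuration(expression_matrix(vals2, "noise", "microarray"),
                        cfg$clustering)
  affine <- score_candidates(cfg2, baits)
  expect_equal(affine$gene_id, base$gene_id)
  expect_equal(affine$z, base$z, tolerance = 1e-9)

  perm <- sample(ncol(vals))
  cfg3 <- configuration(expression_matrix(vals[, perm], "noise", "microarray"),
                        cfg$clustering)
  shuffled <- score_candidates(cfg3, baits)
  expect_equal(shuffled$z, base$z, tolerance = 1e-12)
  expect_equal(shuffled$gene_id, base$gene_id)
})

test_that("self-rank performs LOOCV with UNSCORED where the left-out gene is unreachable", {
  cfg <- planted_config(seed = 2)
  module1 <- names(cfg$clustering$assignment)[cfg$clustering$assignment == 1]
  baits <- module1[1:4]
  # left-out gene strongly co-expressed with remaining baits -> self-rank 1
  expect_equal(self_rank(cfg, baits, baits[1]), 1L)

  expect_error(self_rank(cfg, baits, "g9999"), class = "morphr_parameter_error")

  # unclustered left-out gene is UNSCORED
  cl <- clustering_solution(
    cfg$clustering$assignment[setdiff(names(cfg$clustering$assignment), baits[1])],
    "partial", "planted", unclustered = baits[1]
  )
  cfg_part <- configuration(cfg$matrix, cl)
  expect_true(is.na(self_rank(cfg_part, baits, baits[1])))

  # sole bait of its module left out -> no bait remains anywhere -> UNSCORED
  expect_true(is.na(self_rank(cfg, module1[1], module1[1])))

  # LOOCV evaluates exactly one leave-out per bait gene
  res <- run_morph(list(cfg), bait_set("t", baits))
  expect_equal(sort(names(res$self_ranks)), sort(baits))
})

test_that("AUSR closed form matches the threshold-sum definition and is monotone", {
  expect_equal(ausr(c(1, 1, 1), r_max = 1000), 1.0)
  expect_equal(ausr(c(1500, NA, 2000), r_max = 1000), 0.0)
  expect_equal(ausr(c(1, 501, NA), r_max = 1000), 0.5)

  set.seed(21)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    r_max <- sample(c(50, 200, 1000), 1)
    ranks <- sample(c(seq_len(2 * r_max), NA), n, replace = TRUE)
    expect_identical(ausr(ranks, r_max), ausr_threshold_sum(ranks, r_max))
  }

  # worsening any single self-rank can never raise the AUSR
  set.seed(22)
  for (i in 1:20) {
    ranks <- sample(1:1200, 6, replace = TRUE)
    j <- sample(6, 1)
    worse <- ranks
    worse[j] <- worse[j] + sample(1:500, 1)
    expect_lte(ausr(worse, 1000), ausr(ranks, 1000))
  }

  expect_error(ausr(integer(0)), class = "morphr_parameter_error")
  expect_error(ausr(c(1, 2), r_max = 0), class = "morphr_parameter_error")
})

test_that("model selection picks the configuration with planted co-expression", {
  planted <- planted_config(seed = 5, dataset_id = "dsA")
  # one shared clustering whose first module mixes the 12 coherent genes with
  # 12 noise genes: on the planted data a left-out bait outranks the noise
  # members, on pure-noise data it ranks arbitrarily
  assignment <- setNames(rep(1:2, each = 18), rownames(planted$matrix$values))
  informative <- configuration(planted$matrix,
                               clustering_solution(assignment, "truth", "dsA"))
  noise_m <- rand_matrix(36, 40, seed = 6, dataset_id = "dsA")
  rownames(noise_m$values) <- rownames(planted$matrix$values)
  noise <- configuration(
    expression_matrix(noise_m$values, "dsA", "microarray"),
    clustering_solution(assignment, "noisecl", "dsA")
  )
  baits <- rownames(planted$matrix$values)[1:5]

  # small candidate pools: use a rank ceiling on the pool's scale so the
  # noise configuration cannot saturate the AUSR
  sel <- select_config(list(noise, informative), baits, r_max = 20)
  expect_equal(sel$config$config_id, informative$config_id)
  expect_gt(sel$per_config[informative$config_id],
            sel$per_config[noise$config_id])

  # single configuration is returned regardless of AUSR
  sel1 <- select_config(list(noise), baits, r_max = 20)
  expect_equal(sel1$config$config_id, noise$config_id)

  # identical configurations: first wins
  twin <- configuration(informative$matrix,
                        clustering_solution(informative$clustering$assignment,
                                            "truth2", "dsA"))
  sel2 <- select_config(list(informative, twin), baits, r_max = 20)
  expect_equal(sel2$config$config_id, informative$config_id)
})

test_that("run_morph is internally consistent and recovers planted module members", {
  cfg <- planted_config(n_module_genes = 14, seed = 9)
  module1 <- names(cfg$clustering$assignment)[cfg$clustering$assignment == 1]
  baits <- bait_set("planted", module1[1:7])
  held_out <- setdiff(module1, baits$genes)

  res <- run_morph(list(cfg), baits)
  expect_s3_class(res, "morph_result")
  expect_equal(res$ausr, ausr(res$self_ranks, res$r_max))
  expect_true(all(res$candidates$rank == seq_len(nrow(res$candidates))))
  # held-out module members occupy the top ranks
  expect_setequal(res$candidates$gene_id[seq_along(held_out)], held_out)

  expect_error(run_morph(list(cfg), bait_set("none", c("x1", "x2"))),
               class = "morphr_empty_scorable_error")

  # serialization round trip
  dir <- withr::local_tempdir()
  p <- file.path(dir, "res.tsv")
  write_morph_result(res, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$gene_id, res$candidates$gene_id)
  summ <- readr::read_tsv(paste0(p, ".summary.tsv"), show_col_types = FALSE)
  expect_equal(summ$ausr, res$ausr)
})

test_that("tidiers and plots expose the result tables", {
  cfg <- planted_config(seed = 10)
  module1 <- names(cfg$clustering$assignment)[cfg$clustering$assignment == 1]
  res <- run_morph(list(cfg), bait_set("t", module1[1:5]))
  td <- tidy(res)
  expect_true(all(c("term_id", "config_id", "gene_id", "z", "rank") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$ausr, res$ausr)
  expect_s3_class(autoplot(res), "ggplot")
})
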