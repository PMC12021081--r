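test_that("simulation is seeded-reproducible and respects the topology", {
  cfg <- sim_config(n_types_shared = 2, n_types_ref_only = 1,
                    n_types_query_only = 1, n_genes = 120,
                    n_marker_genes_per_type = 10,
                    cells_per_type_per_batch = 20, seed = 99)
  s1 <- simulate_atlas(cfg)
  s2 <- simulate_atlas(cfg)
  expect_identical(s1$ref$counts, s2$ref$counts)
  expect_identical(s1$query$counts, s2$query$counts)

  ts <- s1$truth$type_status
  expect_equal(sum(ts$status == "ref_only"), 1)
  expect_equal(sum(ts$status == "query_only"), 1)
  # domain composition: no query-only types in the reference and vice versa
  expect_false(any(grepl("queryonly", s1$ref$label)))
  expect_false(any(s1$truth$query_truth$status == "ref_only"))
  expect_null(s1$query$label)   # no leakage by construction
  expect_true(all(s1$ref$counts >= 0))
})

test_that("fixture presets echo their stated designs", {
  pr <- fixture_presets(seed = 5)
  expect_named(pr, c("easy", "partial_overlap", "resolution_mismatch",
                     "cross_species"))
  expect_equal(pr$easy$batch_effect_sd, 0)
  expect_equal(pr$easy$n_types_ref_only + pr$easy$n_types_query_only, 0L)
  expect_equal(pr$partial_overlap$n_types_ref_only, 1L)
  expect_equal(pr$partial_overlap$n_types_query_only, 1L)
  expect_gt(pr$resolution_mismatch$subtypes_per_type, 1L)
  # cross_species: query-only cells are ~63% of the query population
  cs <- pr$cross_species
  frac <- cs$n_types_query_only / (cs$n_types_query_only + cs$n_types_shared)
  expect_equal(frac, 0.625, tolerance = 0.01)
})

test_that("resolution_mismatch gives fine reference labels with coarse query truth", {
  sim <- simulate_atlas(fixture_presets(seed = 2)$resolution_mismatch)
  # reference labels are subtype-level
  expect_true(all(grepl("\\.s[0-9]+$", sim$ref$label)))
  # query truth records one coarse parent per subtype
  qt <- sim$truth$query_truth
  expect_identical(qt$type, sub("\\.s[0-9]+$", "", qt$subtype))
  expect_lt(length(unique(qt$type)), length(unique(qt$subtype)))
})

test_that("zero batch effect makes same-type batches exchangeable", {
  cfg <- sim_config(n_types_shared = 2, n_types_ref_only = 0,
                    n_types_query_only = 0, n_genes = 150,
                    n_marker_genes_per_type = 10,
                    cells_per_type_per_batch = 80,
                    n_ref_batches = 2, n_query_batches = 1,
                    batch_effect_sd = 0, dispersion = 0.1, seed = 31)
  sim <- simulate_atlas(cfg)
  type1 <- sim$ref$label == "shared_1"
  b <- sim$ref$batch[type1]
  counts <- log1p(as.matrix(sim$ref$counts[type1, ]))
  pvals <- apply(counts, 2, function(g) {
    if (stats::sd(g) == 0) return(1)
    stats::t.test(g[b == "ref_b1"], g[b == "ref_b2"])$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("batch effect strength monotonically raises raw-data overcorrection", {
  # weak markers so the per-batch gene effects can degrade the type
  # signal-to-noise ratio; the log-scale batch shift itself is a per-batch
  # translation and would not mix types on its own
  score_at <- function(sd, seed) {
    cfg <- sim_config(n_types_shared = 2, n_types_ref_only = 0,
                      n_types_query_only = 0, n_genes = 100,
                      n_marker_genes_per_type = 5,
                      cells_per_type_per_batch = 50,
                      n_ref_batches = 2, n_query_batches = 1,
                      batch_effect_sd = sd, dispersion = 0.1,
                      marker_logfc = 0.8, seed = seed)
    sim <- simulate_atlas(cfg)
    overcorrection_score(log1p(as.matrix(sim$ref$counts)),
                         sim$ref$label, k = 10)$score
  }
  for (seed in 1:3) {
    s_lo <- score_at(0, seed)
    s_mid <- score_at(0.6, seed)
    s_hi <- score_at(1.5, seed)
    expect_gte(s_mid, s_lo)
    expect_gt(s_hi, s_lo)
  }
})

test_that("an independent nearest-centroid baseline clears 95% on the easy preset", {
  sim <- simulate_atlas(fixture_presets(seed = 8)$easy)
  ref_log <- log1p(as.matrix(sim$ref$counts))
  query_log <- log1p(as.matrix(sim$query$counts))
  centroids <- rowsum(ref_log, sim$ref$label) /
    as.vector(table(sim$ref$label))
  d2 <- outer(rowSums(query_log^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(query_log, centroids)
  pred <- rownames(centroids)[apply(d2, 1, which.min)]
  truth <- sim$truth$query_truth$type
  expect_gte(accuracy(truth, pred), 0.95)
})

test_that("simulated marker genes are recovered by the HVG selector", {
  # a broad baseline mean spread puts stable genes alongside markers in the
  # high-expression bins, as in real atlases; mean-controlled selection then
  # has genuine within-bin competition to resolve
  sim <- simulate_atlas(sim_config(n_types_shared = 4, n_types_ref_only = 0,
                                   n_types_query_only = 0, n_genes = 300,
                                   n_marker_genes_per_type = 15,
                                   cells_per_type_per_batch = 80,
                                   n_ref_batches = 1, n_query_batches = 1,
                                   batch_effect_sd = 0,
                                   baseline_logmean_sd = 1.2, seed = 12))
  norm <- normalize_log_cpm(sim$ref)
  sel <- select_hvgs(list(norm), n_top = 80)
  markers <- sim$truth$markers$gene
  expect_gte(mean(markers %in% sel), 0.8)
})

test_that("infeasible configurations error out", {
  expect_error(sim_config(n_types_shared = 0, n_types_ref_only = 0),
               "at least one type")
  expect_error(sim_config(n_genes = 50, n_marker_genes_per_type = 20,
                          n_types_shared = 5), "marker blocks")
})
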