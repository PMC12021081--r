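test_that("qc_filter applies thresholds cell-first then gene, matching a brute-force scan", {
  # boundary toy: cell A expresses a single gene
  counts <- rbind(A = c(5, 0, 0, 0), B = c(1, 2, 0, 1),
                  C = c(0, 3, 1, 1), D = c(2, 2, 2, 0), E = c(1, 1, 1, 1))
  mat <- annotated_matrix(counts, paste0("g", 1:4), LETTERS[1:5],
                          batch = rep("b", 5))
  out <- qc_filter(mat, min_genes_per_cell = 2, min_cells_per_gene = 1)
  expect_false("A" %in% out$cell_ids)
  expect_setequal(out$cell_ids, c("B", "C", "D", "E"))

  # random Bernoulli(0.1) matrix vs independent nonzero-count oracle
  set.seed(42)
  counts <- matrix(rbinom(50 * 100, 1, 0.1), 50, 100)
  mat <- annotated_matrix(counts, sprintf("g%03d", 1:100),
                          sprintf("c%02d", 1:50), batch = rep("b", 50))
  out <- qc_filter(mat, min_genes_per_cell = 5, min_cells_per_gene = 2)
  keep_cells <- which(apply(counts > 0, 1, sum) >= 5)
  keep_genes <- which(apply(counts[keep_cells, ] > 0, 2, sum) >= 2)
  expect_identical(out$cell_ids, sprintf("c%02d", keep_cells))
  expect_identical(out$gene_ids, sprintf("g%03d", keep_genes))

  expect_error(qc_filter(mat, min_genes_per_cell = 1000), "removed every cell")
})

test_that("qc_filter is order-stable under cell permutation", {
  mat <- toy_matrix(n_cells = 30, n_genes = 40, seed = 3, lambda = 0.3)
  set.seed(9)
  perm <- sample(30)
  permuted <- subset_cells <- scarmap:::subset_cells(mat, cells = perm)
  a <- qc_filter(mat, 5, 2)
  b <- qc_filter(permuted, 5, 2)
  expect_setequal(a$cell_ids, b$cell_ids)
  expect_identical(a$gene_ids, b$gene_ids)
  # each surviving cell's row is identical regardless of input order
  expect_equal(as.matrix(a$counts[sort(a$cell_ids), ]),
               as.matrix(b$counts[sort(b$cell_ids), ]))
})

test_that("normalize_log_cpm scales each cell to 1e6 then log1p", {
  mat <- annotated_matrix(rbind(c(2, 0, 2), c(1, 1, 1)), paste0("g", 1:3),
                          c("c1", "c2"), batch = c("b", "b"))
  # one extra gene per cell so totals differ from the toy targets? no:
  out <- normalize_log_cpm(mat)
  expect_equal(out["c1", ], c(g1 = log(500001), g2 = 0, g3 = log(500001)))
  mat2 <- annotated_matrix(matrix(1, 1, 4), paste0("g", 1:4), "c1", "b")
  expect_equal(unname(normalize_log_cpm(mat2)[1, ]), rep(log(1 + 250000), 4))

  # oracle: row sums of exp(out) - 1 recover 1e6 for every cell
  big <- toy_matrix(n_cells = 15, n_genes = 25, seed = 5)
  norm <- normalize_log_cpm(big)
  expect_equal(unname(rowSums(exp(norm) - 1)), rep(1e6, 15), tolerance = 1e-8)

  # scale equivariance: scaling a cell's counts leaves its profile unchanged
  sc <- big
  sc$counts[3, ] <- sc$counts[3, ] * 7
  expect_equal(normalize_log_cpm(sc)[3, ], norm[3, ], tolerance = 1e-12)

  zero <- annotated_matrix(rbind(c(0, 0), c(1, 2)), c("g1", "g2"),
                           c("c1", "c2"), c("b", "b"))
  expect_error(normalize_log_cpm(zero), "zero total")
})

test_that("select_hvgs handles degenerate and identical-batch inputs", {
  m <- normalize_log_cpm(toy_matrix(n_cells = 30, n_genes = 20, seed = 2))
  expect_warning(all_genes <- select_hvgs(list(m), n_top = 50),
                 "clamped")
  expect_setequal(all_genes, colnames(m))
  top5 <- select_hvgs(list(m), n_top = 5)
  expect_setequal(select_hvgs(list(m, m), n_top = 5), top5)
  expect_error(select_hvgs(list(), 5), "at least one batch")
})

test_that("select_hvgs recovers genes with inflated type-specific variance", {
  # 500 genes spanning a range of means; 50 of them (spread across that
  # range) flip between two cell groups while keeping their overall mean,
  # so only their dispersion is inflated -- exactly what mean-controlled
  # selection must catch
  set.seed(11)
  n <- 400; G <- 500
  grp <- rep(0:1, each = n / 2)
  lam <- runif(G, 2, 20)
  counts <- sapply(seq_len(G), function(g) rpois(n, lam[g]))
  hv <- sample(G, 50)
  for (g in hv) {
    counts[grp == 0, g] <- rpois(n / 2, 0.2 * lam[g])
    counts[grp == 1, g] <- rpois(n / 2, 1.8 * lam[g])
  }
  mat <- annotated_matrix(counts, sprintf("g%03d", 1:G), sprintf("c%03d", 1:n),
                          batch = rep("b", n))
  sel <- select_hvgs(list(normalize_log_cpm(mat)), n_top = 100)
  expect_gte(sum(sprintf("g%03d", hv) %in% sel), 45)  # >= 90% of 50
})

test_that("assemble_features aligns columns, codes labels, ignores query labels", {
  ref <- toy_matrix(n_cells = 10, n_genes = 8, seed = 1)
  query <- toy_matrix(n_cells = 12, n_genes = 8, seed = 2, labeled = FALSE)
  hv <- c("g002", "g005", "g007")
  fp <- assemble_features(ref, query, hv)
  expect_identical(fp$hvg_ids, hv)
  expect_identical(colnames(fp$ref_features), hv)
  expect_identical(colnames(fp$query_features), hv)
  expect_identical(fp$type_names, c("B", "T"))       # sorted-order convention
  expect_identical(fp$label_codes_ref, match(ref$label, c("B", "T")) - 1L)
  expect_equal(fp$n_batches, 2)

  # permutation oracle: scrambling query gene order leaves features unchanged
  set.seed(4)
  perm <- sample(8)
  query_scrambled <- annotated_matrix(query$counts[, perm],
                                      query$gene_ids[perm], query$cell_ids,
                                      query$batch)
  fp2 <- assemble_features(ref, query_scrambled, hv)
  expect_equal(fp2$query_features, fp$query_features)

  # query labels (held-out truth) must not influence the output
  query_lab <- annotated_matrix(query$counts, query$gene_ids, query$cell_ids,
                                query$batch, label = rep("X", 12))
  fp3 <- assemble_features(ref, query_lab, hv)
  expect_equal(fp3$query_features, fp$query_features)
  expect_identical(fp3$type_names, fp$type_names)

  expect_error(assemble_features(ref, query, c("g002", "nope")), "missing")
})
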