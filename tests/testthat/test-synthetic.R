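test_that("all generators are bit-identical under a fixed seed", {
  a <- generate_paired_expression(n_genes = 200, n_tissues = 4,
                                  samples_per_tissue = 20, seed = 1)
  b <- generate_paired_expression(n_genes = 200, n_tissues = 4,
                                  samples_per_tissue = 20, seed = 1)
  expect_identical(a$expr_a$values, b$expr_a$values)
  expect_identical(a$expr_b$values, b$expr_b$values)
  expect_identical(a$truth$diverged_gene_ids, b$truth$diverged_gene_ids)
  c1 <- generate_paired_expression(n_genes = 200, n_tissues = 4,
                                   samples_per_tissue = 20, seed = 2)
  expect_false(identical(a$expr_a$values, c1$expr_a$values))
  g1 <- generate_gwas_markers(n_markers = 1000, n_genes = 100, seed = 5)
  g2 <- generate_gwas_markers(n_markers = 1000, n_genes = 100, seed = 5)
  expect_identical(g1$markers$b, g2$markers$b)
  expect_identical(g1$truth$enriched_gene_set, g2$truth$enriched_gene_set)
  s1 <- generate_segmentation(g1$annotation, g1$genome_sizes, seed = 6)
  s2 <- generate_segmentation(g1$annotation, g1$genome_sizes, seed = 6)
  expect_identical(s1$intervals, s2$intervals)
})

test_that("generated data honours its structural invariants", {
  sim <- generate_paired_expression(n_genes = 300, n_tissues = 3,
                                    samples_per_tissue = c(10, 8), seed = 3)
  expect_true(all(sim$expr_a$values >= 0))
  expect_true(all(sim$expr_b$values >= 0))
  expect_equal(ncol(sim$expr_a$values), 30L)
  expect_equal(ncol(sim$expr_b$values), 24L)
  tr <- sim$truth
  expect_length(intersect(tr$diverged_gene_ids,
                          tr$variance_shifted_gene_ids), 0)
  expect_true(all(c(tr$diverged_gene_ids, tr$variance_shifted_gene_ids)
                  %in% sim$orthologs$gene_a))
  expect_length(tr$diverged_gene_ids, 30L)
  # infeasible parameter combinations fail fast
  expect_error(generate_paired_expression(n_genes = 300,
                                          frac_diverged = 0.6,
                                          frac_variance_shifted = 0.6),
               "disjoint")
  expect_error(generate_paired_expression(n_genes = 50, n_modules = 20),
               "10 \\* n_modules")
  expect_error(generate_gwas_markers(n_markers = 50, n_genes = 100),
               "n_markers >= n_genes")
  expect_error(generate_gwas_markers(enrichment_ratio = 0.5),
               ">= 1")
})

test_that("generated segmentation tiles the genome with no gaps or overlaps", {
  gw <- generate_gwas_markers(n_markers = 1000, n_genes = 100,
                              n_chroms = 2, seed = 7)
  seg <- generate_segmentation(gw$annotation, gw$genome_sizes,
                               tss_bias = 3, seed = 8)
  iv <- seg$intervals
  for (cc in names(gw$genome_sizes)) {
    sub <- iv[iv$chrom == cc, ]
    sub <- sub[order(sub$start), ]
    expect_equal(sum(sub$end - sub$start), unname(gw$genome_sizes[cc]))
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])  # contiguous tiling
  }
  expect_true(all(nchar(iv$state) > 0))
})

test_that("marker effects are inflated only inside the enriched gene set", {
  gw <- generate_gwas_markers(enrichment_ratio = 25,
                              background_effect_sd = 0.1, seed = 9)
  b_in <- gw$markers$b[gw$truth$enriched_marker_mask]
  b_out <- gw$markers$b[!gw$truth$enriched_marker_mask]
  expect_equal(length(b_in), 500L)  # 50 genes x ~10 markers each
  expect_gt(var(b_in) / var(b_out), 5)
  expect_lt(abs(sd(b_out) / 0.1 - 1), 0.1)
})

test_that("null generator keeps between-species DE flags at nominal level", {
  rates <- vapply(1:20, function(s) {
    sim <- generate_paired_expression(n_genes = 300, n_tissues = 1,
                                      samples_per_tissue = 20,
                                      frac_diverged = 0,
                                      frac_variance_shifted = 0, seed = s)
    de <- differential_expression(sim$expr_a, sim$expr_b, sim$orthologs)
    mean(de$significant)
  }, numeric(1))
  mc_sd <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 2 * mc_sd)
})

test_that("unenriched marker sets give uniform-mean permutation p-values", {
  gw <- generate_gwas_markers(enrichment_ratio = 1, seed = 10)
  set.seed(101)
  ps <- vapply(1:500, function(i) {
    set <- sample(gw$annotation$gene_id, 50)
    mask <- assign_markers(gw$annotation, gw$markers, set,
                           extension_bp = 0)
    cyclical_permutation_test(gw$markers$b, mask, n_perm = 200)$p_empirical
  }, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("a TSS-favoured state shows fold > 1 around TSSs", {
  gw <- generate_gwas_markers(n_markers = 1000, n_genes = 200,
                              n_chroms = 2, seed = 11)
  seg <- generate_segmentation(gw$annotation, gw$genome_sizes,
                               tss_bias = 10, seed = 12)
  se <- chromatin_state_enrichment(seg, gw$annotation,
                                   gw$annotation$gene_id)
  expect_gt(se$fold[se$state == "E1"], 1)
})
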