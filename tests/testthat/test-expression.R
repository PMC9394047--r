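test_that("log transform maps TPM onto log2(TPM + 0.25)", {
  expect_equal(log_tpm(c(0, 0.75, 3.75)), c(-2, 0, 2))
  expect_error(log_tpm(-1), "non-negative")
})

test_that("tissue summary computes median, MAD, CV and the expressed flag", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(0.05, 0.05, 0.05),
                g3 = c(2, 2, 2))
  colnames(vals) <- c("s1", "s2", "s3")
  ts <- tissue_summary(make_expr(vals, tissues = rep("liver", 3)))
  r1 <- ts[ts$gene_id == "g1", ]
  expect_equal(r1$median_tpm, 2)
  lg <- log2(c(1, 2, 3) + 0.25)
  expect_equal(r1$mad_log2, median(abs(lg - median(lg))))  # unscaled MAD
  expect_equal(r1$cv, sd(c(1, 2, 3)) / mean(c(1, 2, 3)))
  expect_false(ts[ts$gene_id == "g2", "expressed"])  # median 0.05
  r3 <- ts[ts$gene_id == "g3", ]
  expect_equal(r3$cv, 0)
  expect_equal(r3$mad_log2, 0)
  # a tissue with < 2 samples is named in the error
  expect_error(
    tissue_summary(make_expr(vals, tissues = c("liver", "liver", "lone"))),
    "lone")
})

test_that("expressed-gene counting uses a strict median TPM > 0.1 cut", {
  vals <- rbind(g1 = c(0, 0), g2 = c(1, 1), g3 = c(0.1, 0.1))
  colnames(vals) <- c("s1", "s2")
  ts <- tissue_summary(make_expr(vals, tissues = c("t1", "t1")))
  expect_equal(count_expressed(ts, "t1"), 1L)  # exactly 0.1 not counted
  expect_error(count_expressed(ts, "t9"), "unknown tissue")
  all_zero <- tissue_summary(make_expr(vals * 0, tissues = c("t1", "t1")))
  expect_equal(count_expressed(all_zero, "t1"), 0L)
})

test_that("shared window fraction handles identity, reversal and remainders", {
  genes <- sprintf("g%02d", 1:20)
  ident <- shared_window_fraction(genes, genes)
  expect_true(all(ident$overlap_pct == 100))
  rev20 <- shared_window_fraction(genes, rev(genes))
  expect_true(all(rev20$overlap_pct == 0))  # exhaustive: all windows disjoint
  # window size floor(n / 10); remainder genes dropped from the bottom
  g23 <- sprintf("g%02d", 1:23)
  w <- shared_window_fraction(g23, g23)
  expect_equal(unique(w$window_size), 2L)
  expect_equal(sum(w$window_size), 23 - 23 %% 10)
  expect_error(shared_window_fraction(genes, genes[c(1:19, 1)]),
               "permutations")
})

test_that("tau spans ubiquitous to single-tissue and is scale-invariant", {
  expect_equal(tau_score(c(5, 5, 5, 5)), 0)
  expect_equal(tau_score(c(7, 0, 0, 0)), 1)
  expect_equal(tau_score(c(1, 0.5)), 0.5)
  expect_warning(expect_true(is.na(tau_score(c(0, 0, 0)))), "all-zero")
  set.seed(11)
  for (i in 1:25) {
    x <- runif(sample(2:12, 1), 0, 50)
    tau <- tau_score(x)
    expect_gte(tau, 0); expect_lte(tau, 1)
    expect_equal(tau_score(3.7 * x), tau)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)) >= 0))  # monotone on sorted input
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("between-species DE reproduces Welch t and its thresholds", {
  # identical groups: t = 0, p = 1
  tpm <- function(lg) 2^lg - 0.25
  va <- rbind(g1 = tpm(c(4, 5, 6)))
  vb <- rbind(h1 = tpm(c(4, 5, 6)))
  colnames(va) <- paste0("a", 1:3); colnames(vb) <- paste0("b", 1:3)
  om <- ortholog_map("g1", "h1")
  de <- differential_expression(make_expr(va), make_expr(vb, "B"), om)
  expect_equal(de$t_stat, 0)
  expect_equal(de$p, 1)
  expect_equal(de$log2fc, 0)
  # textbook Welch oracle (stats::t.test) on a hand-picked fixture
  a_lg <- c(2.0, 2.1, 1.9, 2.0); b_lg <- c(1.0, 1.1, 0.9, 1.0)
  va <- rbind(g1 = tpm(a_lg)); vb <- rbind(h1 = tpm(b_lg))
  colnames(va) <- paste0("a", 1:4); colnames(vb) <- paste0("b", 1:4)
  de <- differential_expression(make_expr(va), make_expr(vb, "B"), om)
  oracle <- t.test(a_lg, b_lg)
  expect_equal(de$log2fc, 1)
  expect_equal(de$t_stat, unname(oracle$statistic))
  expect_equal(de$df, unname(oracle$parameter))
  expect_equal(de$p, oracle$p.value)
  expect_true(de$significant)  # |log2fc| > log2(1.2) and FDR < 0.05
  # degenerate: zero variance both sides, unequal means
  va <- rbind(g1 = rep(tpm(3), 3)); vb <- rbind(h1 = rep(tpm(1), 3))
  colnames(va) <- paste0("a", 1:3); colnames(vb) <- paste0("b", 1:3)
  expect_warning(
    de <- differential_expression(make_expr(va), make_expr(vb, "B"), om),
    "zero variance")
  expect_equal(de$p, .Machine$double.xmin)
  expect_true(de$degenerate)
})

test_that("vectorised Welch agrees with stats::t.test across random genes", {
  set.seed(42)
  n <- 30
  va <- matrix(rexp(n * 6), n, dimnames = list(sprintf("g%02d", 1:n),
                                               paste0("a", 1:6)))
  vb <- matrix(rexp(n * 9), n, dimnames = list(sprintf("h%02d", 1:n),
                                               paste0("b", 1:9)))
  om <- ortholog_map(rownames(va), rownames(vb))
  de <- differential_expression(make_expr(va), make_expr(vb, "B"), om)
  for (i in c(1, 7, 18, 30)) {
    o <- t.test(log2(va[i, ] + 0.25), log2(vb[i, ] + 0.25))
    expect_equal(de$p[i], o$p.value)
    expect_equal(de$t_stat[i], unname(o$statistic))
  }
  expect_equal(de$fdr, p.adjust(de$p, "BH"))
})

test_that("tissue-specific DE flags one-tissue elevation and nothing else", {
  set.seed(7)
  n_per <- 8
  tissues <- rep(c("target", "rest1", "rest2"), each = n_per)
  lg <- matrix(rnorm(3 * 3 * n_per, 2, 0.3), nrow = 3)
  lg[1, tissues == "target"] <- lg[1, tissues == "target"] + 4  # specific
  lg[3, tissues == "rest1"] <- lg[3, tissues == "rest1"] + 4    # wrong tissue
  vals <- 2^lg - 0.25
  dimnames(vals) <- list(c("spec", "flat", "other"),
                         sprintf("s%02d", seq_along(tissues)))
  de <- tissue_specific_de(make_expr(vals, tissues = tissues), "target")
  expect_true(de$significant[de$gene_id == "spec"])
  expect_false(de$significant[de$gene_id == "flat"])
  expect_false(de$significant[de$gene_id == "other"])
  expect_error(tissue_specific_de(make_expr(vals, tissues = tissues), "x"),
               ">= 2 samples")
})

test_that("tissue clustering follows complete linkage on 1 - Pearson r", {
  profiles <- rbind(liver = c(1, 2, 3, 4, 5),
                    liver2 = c(1, 2, 3, 4, 5),
                    brain = c(5, 4, 3, 2, 1))
  hc <- cluster_tissues(profiles)
  expect_equal(hc$height[1], 0)  # identical profiles merge first at 0
  expect_setequal(-hc$merge[1, ], match(c("liver", "liver2"), hc$labels))
  # 4-tissue fixture against a brute-force agglomeration oracle
  set.seed(5)
  m <- matrix(rnorm(4 * 30), 4, dimnames = list(paste0("t", 1:4), NULL))
  hc4 <- cluster_tissues(m)
  d <- 1 - cor(t(m))
  expect_equal(hc4$height, oracle_complete_linkage_heights(d))
  m[2, ] <- 1
  expect_error(cluster_tissues(m), "t2")
})
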