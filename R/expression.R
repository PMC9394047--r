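#' @title Expression-level conservation statistics
#' @description Tissue summaries, expressed-gene counts, tau
#'   tissue-specificity, between-species and one-vs-rest differential
#'   expression (Welch t on log2(TPM + 0.25)), decile-window overlap and
#'   tissue clustering.
#' @name orthoconserve-expression
NULL

#' Log-transform TPM
#'
#' The pipeline's single expression transform: `log2(tpm + 0.25)`, so that
#' TPM 0 maps to -2.
#'
#' @param tpm Non-negative numeric vector of TPM values.
#' @return `log2(tpm + 0.25)`.
#' @examples
#' log_tpm(c(0, 0.75, 3.75))  # -2, 0, 2
#' @export
log_tpm <- function(tpm) {
  if (anyNA(tpm) || any(tpm < 0))
    stop("TPM must be non-negative", call. = FALSE)
  log2(tpm + 0.25)
}

row_vars <- function(x) {
  n <- ncol(x)
  ctr <- x - rowMeans(x)
  rowSums(ctr * ctr) / (n - 1L)
}

#' Per-gene, per-tissue expression summaries
#'
#' For each gene in each tissue: median TPM, mean and (unscaled) median
#' absolute deviation of log2(TPM + 0.25), coefficient of variation of
#' linear TPM (n-1 sd / mean; NA when the mean is 0), the expressed flag
#' (median TPM > 0.1) and the sample count. Every tissue needs at least two
#' samples.
#'
#' @param expr An [expression_matrix()] object.
#' @return A data.frame of class `TissueSummary` with one row per
#'   (gene, tissue): columns `gene_id`, `tissue`, `median_tpm`,
#'   `mean_log2`, `mad_log2`, `cv`, `expressed`, `n_samples`.
#' @export
tissue_summary <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  tissues <- sort(unique(expr$tissues))
  counts <- table(expr$tissues)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("tissue(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  res <- lapply(tissues, function(tt) {
    m <- expr$values[, expr$tissues == tt, drop = FALSE]
    lg <- log2(m + 0.25)
    med <- apply(m, 1L, stats::median)
    mean_tpm <- rowMeans(m)
    sd_tpm <- sqrt(row_vars(m))
    cv <- ifelse(mean_tpm > 0, sd_tpm / mean_tpm, NA_real_)
    data.frame(gene_id = rownames(m), tissue = tt,
               median_tpm = med,
               mean_log2 = rowMeans(lg),
               mad_log2 = apply(lg, 1L, function(v)
                 stats::median(abs(v - stats::median(v)))),
               cv = cv,
               expressed = med > 0.1,
               n_samples = ncol(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("TissueSummary", "data.frame")
  out
}

#' Count expressed genes in a tissue
#'
#' A gene is expressed when its median TPM across the tissue's samples is
#' strictly greater than 0.1.
#'
#' @param summary A `TissueSummary` from [tissue_summary()].
#' @param tissue Tissue label.
#' @return Integer count of expressed genes.
#' @export
count_expressed <- function(summary, tissue) {
  stopifnot(inherits(summary, "TissueSummary"))
  if (!tissue %in% summary$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  sum(summary$expressed[summary$tissue == tissue])
}

#' Per-window overlap of two gene rankings
#'
#' Both rankings (largest score first) are cut into `n_windows` windows of
#' `floor(n / n_windows)` genes; the `n %% n_windows` lowest-ranked genes
#' are dropped. The overlap of window i is
#' `|A_i intersect B_i| / window_size * 100`.
#'
#' @param ranked_a,ranked_b Character vectors: the same gene set in two
#'   ranked orders.
#' @param n_windows Number of windows (default 10, deciles).
#' @return A data.frame with columns `window`, `window_size`,
#'   `overlap_pct`.
#' @export
shared_window_fraction <- function(ranked_a, ranked_b, n_windows = 10L) {
  if (!setequal(ranked_a, ranked_b) ||
      length(ranked_a) != length(ranked_b) ||
      anyDuplicated(ranked_a) || anyDuplicated(ranked_b))
    stop("rankings must be permutations of the same gene set", call. = FALSE)
  n <- length(ranked_a)
  w <- n %/% n_windows
  if (w < 1L) stop("fewer genes than windows", call. = FALSE)
  idx <- rep(seq_len(n_windows), each = w)
  a <- ranked_a[seq_len(w * n_windows)]
  b <- ranked_b[seq_len(w * n_windows)]
  ov <- vapply(seq_len(n_windows), function(i)
    length(intersect(a[idx == i], b[idx == i])), integer(1L))
  data.frame(window = seq_len(n_windows), window_size = w,
             overlap_pct = 100 * ov / w)
}

#' Tau tissue-specificity index
#'
#' `tau = sum_i(1 - x_i / max(x)) / (N - 1)` over per-tissue expression
#' summaries (median TPM here): 0 for ubiquitous, 1 for single-tissue
#' expression. All-zero input is undefined and returns NA with a warning.
#'
#' @param x Non-negative numeric vector of length >= 2 (one value per
#'   tissue).
#' @return Tau in [0, 1], or NA for an all-zero vector.
#' @examples
#' tau_score(c(5, 5, 5, 5))  # 0
#' tau_score(c(7, 0, 0, 0))  # 1
#' @export
tau_score <- function(x) {
  if (length(x) < 2L) stop("tau needs >= 2 tissues", call. = FALSE)
  if (anyNA(x) || any(x < 0))
    stop("tau input must be non-negative", call. = FALSE)
  mx <- max(x)
  if (mx == 0) {
    warning("tau undefined for an all-zero expression vector")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, clipped to 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Row-wise Welch two-sample t-test on two matrices with aligned rows.
# Zero variance on both sides: equal means -> p = 1; unequal means ->
# p = smallest positive double, flagged `degenerate` (keeps ranking total).
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("Welch test needs >= 2 samples per group", call. = FALSE)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- row_vars(a); vb <- row_vars(b)
  sea <- va / na; seb <- vb / nb
  se2 <- sea + seb
  diff <- ma - mb
  tt <- ifelse(se2 > 0, diff / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (sea^2 / (na - 1L) + seb^2 / (nb - 1L)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
  degen <- se2 == 0 & diff != 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero variance in both groups but ",
            "unequal means; p set to the smallest positive double")
    p[degen] <- .Machine$double.xmin
    tt[degen] <- sign(diff[degen]) * Inf
  }
  list(diff = diff, t = tt, df = df, p = p, degenerate = degen)
}

de_table <- function(gene_id, w, lfc_threshold, two_sided_fc = TRUE) {
  fdr <- bh_fdr(w$p)
  pass_fc <- if (two_sided_fc) abs(w$diff) > lfc_threshold
             else w$diff > lfc_threshold
  out <- data.frame(gene_id = gene_id,
                    log2fc = w$diff, t_stat = w$t, df = w$df, p = w$p,
                    fdr = fdr,
                    direction = ifelse(w$diff > 0, "up",
                                       ifelse(w$diff < 0, "down", "none")),
                    significant = pass_fc & fdr < 0.05,
                    degenerate = w$degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DiffExpressionTable", "data.frame")
  out
}

#' Between-species differential expression over orthologs
#'
#' Welch two-sample t-test per ortholog pair on log2(TPM + 0.25), species A
#' samples versus species B samples (typically restricted to one tissue via
#' [subset_tissue()]). `log2fc = mean_A - mean_B` on the log scale; a gene
#' is significant when `|log2fc| > log2(1.2)` and BH FDR < 0.05.
#'
#' @param expr_a,expr_b [expression_matrix()] objects for the two species.
#' @param orthologs An [ortholog_map()]; `gene_a` ids index `expr_a`,
#'   `gene_b` ids index `expr_b`.
#' @return A data.frame of class `DiffExpressionTable` with one row per
#'   ortholog pair (columns `gene_id` = species-A id, `gene_id_b`,
#'   `log2fc`, `t_stat`, `df`, `p`, `fdr`, `direction`, `significant`,
#'   `degenerate`).
#' @export
differential_expression <- function(expr_a, expr_b, orthologs) {
  stopifnot(inherits(expr_a, "ExpressionMatrix"),
            inherits(expr_b, "ExpressionMatrix"),
            inherits(orthologs, "OrthologMap"))
  miss_a <- setdiff(orthologs$gene_a, gene_ids(expr_a))
  miss_b <- setdiff(orthologs$gene_b, gene_ids(expr_b))
  if (length(miss_a) || length(miss_b))
    stop("ortholog ids absent from expression matrices: ",
         paste(utils::head(c(miss_a, miss_b), 5L), collapse = ", "),
         call. = FALSE)
  a <- log2(expr_a$values[orthologs$gene_a, , drop = FALSE] + 0.25)
  b <- log2(expr_b$values[orthologs$gene_b, , drop = FALSE] + 0.25)
  w <- row_welch(a, b)
  out <- de_table(orthologs$gene_a, w, lfc_threshold = log2(1.2))
  out$gene_id_b <- orthologs$gene_b
  out
}

#' Tissue-specific differential expression (one vs rest)
#'
#' Welch t-test of the target tissue's samples against all remaining
#' samples, per gene, on log2(TPM + 0.25). A gene is tissue-specific when
#' `log2fc > 1.5` (upregulated in the target tissue) and BH FDR < 0.05.
#'
#' @param expr An [expression_matrix()] object covering several tissues.
#' @param tissue Target tissue label.
#' @return A `DiffExpressionTable`; `log2fc` is target minus rest.
#' @export
tissue_specific_de <- function(expr, tissue) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  in_t <- expr$tissues == tissue
  if (sum(in_t) < 2L || sum(!in_t) < 2L)
    stop("need >= 2 samples in '", tissue, "' and in the rest",
         call. = FALSE)
  lg <- log2(expr$values + 0.25)
  w <- row_welch(lg[, in_t, drop = FALSE], lg[, !in_t, drop = FALSE])
  de_table(rownames(lg), w, lfc_threshold = 1.5, two_sided_fc = FALSE)
}

#' Hierarchically cluster tissues by profile correlation
#'
#' Agglomerative clustering of tissue profiles (e.g. per-tissue median or
#' MAD vectors over genes) with distance 1 - Pearson r and complete
#' linkage.
#'
#' @param profiles Numeric matrix, tissues in rows (rownames = tissue
#'   labels), genes in columns. Rows must be non-constant.
#' @return An object of class [stats::hclust].
#' @export
cluster_tissues <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L)
    stop("need a matrix with >= 2 tissue rows", call. = FALSE)
  if (is.null(rownames(profiles)))
    stop("tissue profiles must have rownames", call. = FALSE)
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant profile for tissue(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "),
         call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  stats::hclust(d, method = "complete")
}
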