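#' @title Differential variability between species
#' @description F-test comparing per-gene expression variance on the log2
#'   scale between two species within a tissue: `f = s1^2 / s2^2` with
#'   `f ~ F(n - 1, m - 1)` under the null of equal variances.
#' @name orthoconserve-variability
NULL

#' F-test of differential variability for one gene
#'
#' `f = s1^2 / s2^2` (n-1 denominator sample variances) of the two log2
#' expression vectors; the two-sided p doubles the smaller tail of
#' `F(n - 1, m - 1)`. Degenerate cases: `s2^2 = 0` with `s1^2 > 0` gives
#' `f = Inf` and p = the smallest positive double; both variances zero
#' gives `f = NA`, p = 1. Both are flagged.
#'
#' @param x_a,x_b Numeric vectors of log2 expression, length >= 2 each
#'   (species A = numerator, species B = denominator).
#' @return List with `f`, `p`, `s1_sq`, `s2_sq`, `n`, `m`, `degenerate`.
#' @export
var_f_test <- function(x_a, x_b) {
  n <- length(x_a); m <- length(x_b)
  if (n < 2L || m < 2L)
    stop("F-test needs >= 2 samples per group", call. = FALSE)
  s1 <- stats::var(x_a); s2 <- stats::var(x_b)
  if (s1 == 0 && s2 == 0) {
    return(list(f = NA_real_, p = 1, s1_sq = 0, s2_sq = 0, n = n, m = m,
                degenerate = TRUE))
  }
  if (s2 == 0) {
    return(list(f = Inf, p = .Machine$double.xmin, s1_sq = s1, s2_sq = 0,
                n = n, m = m, degenerate = TRUE))
  }
  f <- s1 / s2
  lo <- stats::pf(f, n - 1L, m - 1L)
  p <- min(1, 2 * min(lo, 1 - lo))
  list(f = f, p = p, s1_sq = s1, s2_sq = s2, n = n, m = m,
       degenerate = FALSE)
}

#' Differential variability over all ortholog pairs
#'
#' Applies the variance F-test per ortholog pair to log2(TPM + 0.25)
#' values, with BH FDR across genes. Species A is the numerator.
#'
#' @param expr_a,expr_b [expression_matrix()] objects (typically one
#'   tissue each, via [subset_tissue()]).
#' @param orthologs An [ortholog_map()] aligning the two.
#' @return A data.frame of class `DiffVariabilityTable` with columns
#'   `gene_id` (species-A id), `gene_id_b`, `s1_sq`, `s2_sq`, `f`, `n`,
#'   `m`, `p`, `fdr`, `degenerate`.
#' @export
differential_variability <- function(expr_a, expr_b, orthologs) {
  stopifnot(inherits(expr_a, "ExpressionMatrix"),
            inherits(expr_b, "ExpressionMatrix"),
            inherits(orthologs, "OrthologMap"))
  a <- log2(expr_a$values[orthologs$gene_a, , drop = FALSE] + 0.25)
  b <- log2(expr_b$values[orthologs$gene_b, , drop = FALSE] + 0.25)
  n <- ncol(a); m <- ncol(b)
  if (n < 2L || m < 2L)
    stop("F-test needs >= 2 samples per group", call. = FALSE)
  s1 <- row_vars(a); s2 <- row_vars(b)
  f <- ifelse(s2 > 0, s1 / s2, ifelse(s1 > 0, Inf, NA_real_))
  lo <- stats::pf(f, n - 1L, m - 1L)
  p <- pmin(1, 2 * pmin(lo, 1 - lo))
  degen <- s2 == 0
  p[degen & s1 > 0] <- .Machine$double.xmin
  p[degen & s1 == 0] <- 1
  out <- data.frame(gene_id = orthologs$gene_a,
                    gene_id_b = orthologs$gene_b,
                    s1_sq = s1, s2_sq = s2, f = f, n = n, m = m, p = p,
                    fdr = bh_fdr(p), degenerate = degen,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("DiffVariabilityTable", "data.frame")
  out
}
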