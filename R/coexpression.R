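#' @title Co-expression conservation
#' @description The corCor statistic (correlation, across the gene
#'   background, between a gene's vector of co-expression correlations in
#'   two expression matrices), weighted-network soft connectivity, and the
#'   cross-species connectivity correlation used to score module
#'   conservation.
#' @name orthoconserve-coexpression
NULL

as_gene_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x) || is.null(rownames(x)))
    stop("expected a numeric genes x samples matrix with rownames",
         call. = FALSE)
  x
}

#' Correlation of correlations (corCor) per gene
#'
#' For each gene g over the n aligned genes: vector A holds the Spearman
#' correlations of g with the other n - 1 genes in `expr_1`; vector A' the
#' same in `expr_2` (same gene order, e.g. ortholog order for a
#' cross-species comparison); corCor(g) is the Pearson correlation of A
#' with A'. Genes constant in either matrix have undefined Spearman
#' entries; they are flagged, get NA, and are excluded from every
#' background vector.
#'
#' @param expr_1,expr_2 Numeric genes x samples matrices (or
#'   `ExpressionMatrix` objects) with >= 4 samples each; rows aligned so
#'   row i of both matrices is the same gene/ortholog pair.
#' @param gene_order Optional character vector of ids naming the aligned
#'   rows (defaults to rownames of `expr_1`).
#' @param scenario Free-text label recorded with the result (e.g.
#'   "within-tissue-between-species").
#' @return A data.frame of class `CorCorTable` with columns `gene_id`,
#'   `corcor`, `n_background`, `flagged`, `scenario`.
#' @export
corcor <- function(expr_1, expr_2, gene_order = NULL, scenario = NA_character_) {
  x1 <- as_gene_matrix(expr_1)
  x2 <- as_gene_matrix(expr_2)
  if (nrow(x1) != nrow(x2))
    stop("matrices must be aligned to the same genes", call. = FALSE)
  if (ncol(x1) < 4L || ncol(x2) < 4L)
    stop("corCor needs >= 4 samples per matrix", call. = FALSE)
  if (is.null(gene_order)) gene_order <- rownames(x1)
  n <- nrow(x1)
  if (n < 3L) stop("corCor needs >= 3 genes", call. = FALSE)
  const <- row_vars(x1) == 0 | row_vars(x2) == 0
  valid <- which(!const)
  cc <- rep(NA_real_, n)
  if (length(valid) >= 3L) {
    s1 <- stats::cor(t(x1[valid, , drop = FALSE]), method = "spearman")
    s2 <- stats::cor(t(x2[valid, , drop = FALSE]), method = "spearman")
    for (i in seq_along(valid)) {
      a <- s1[-i, i]
      b <- s2[-i, i]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next  # stays NA, flagged
      cc[valid[i]] <- stats::cor(a, b)
    }
  }
  out <- data.frame(gene_id = gene_order, corcor = cc,
                    n_background = length(valid) - 1L,
                    flagged = is.na(cc), scenario = scenario,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("CorCorTable", "data.frame")
  out
}

#' Soft connectivity of a weighted co-expression network
#'
#' Adjacency `a_ij = |Pearson r(i, j)|^beta` (i != j); connectivity
#' `k_i = sum_j a_ij`. Genes with zero variance get NA.
#'
#' @param expr Numeric genes x samples matrix (or `ExpressionMatrix`),
#'   >= 4 samples.
#' @param beta Positive integer soft-thresholding power (default 6, the
#'   usual choice for signed-magnitude weighted networks).
#' @return Named numeric vector of per-gene connectivities.
#' @export
soft_connectivity <- function(expr, beta = 6L) {
  x <- as_gene_matrix(expr)
  if (ncol(x) < 4L) stop("need >= 4 samples", call. = FALSE)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  const <- row_vars(x) == 0
  k <- stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
  valid <- which(!const)
  if (length(valid) >= 2L) {
    a <- abs(stats::cor(t(x[valid, , drop = FALSE])))^beta
    diag(a) <- 0
    k[valid] <- rowSums(a)
  }
  k
}

#' Cross-species correlation of connectivities over a gene set
#'
#' Pearson correlation of two per-gene connectivity vectors restricted to
#' a gene set (e.g. one co-expression module); high values indicate a
#' conserved module wiring.
#'
#' @param k_a,k_b Named numeric vectors from [soft_connectivity()] (names
#'   aligned, e.g. species-A ids for both after ortholog matching).
#' @param gene_set Character vector of >= 3 member ids.
#' @return Pearson r, or NA with a warning when a restricted vector is
#'   constant.
#' @export
connectivity_correlation <- function(k_a, k_b, gene_set) {
  gene_set <- as.character(gene_set)
  if (length(gene_set) < 3L)
    stop("gene set must have >= 3 members", call. = FALSE)
  missing <- gene_set[!(gene_set %in% names(k_a) & gene_set %in% names(k_b))]
  if (length(missing))
    stop("connectivity undefined for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  a <- k_a[gene_set]; b <- k_b[gene_set]
  if (anyNA(a) || anyNA(b))
    stop("connectivity undefined (NA) for some gene-set members",
         call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant connectivity vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}
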