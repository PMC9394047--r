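#' @title GWAS-signal and chromatin-state enrichment
#' @description The sum-of-squared-effects statistic `T_sum`, its
#'   cyclical-permutation null (rotation of the genome-ordered effect
#'   vector against a fixed marker mask), the hypergeometric gene-set
#'   overlap test, and the (C/A)/(B/D) chromatin-state enrichment fold in
#'   TSS windows.
#' @name orthoconserve-enrichment
NULL

#' Sum of squared marker effects over a masked set
#'
#' `T_sum = sum over masked markers of b^2`, the GWAS-signal statistic of
#' a gene set's markers.
#'
#' @param effects_b Numeric vector of per-marker effects in genome order.
#' @param mask Logical vector over markers, or integer indices.
#' @return Non-negative scalar; an empty mask returns 0 with a warning.
#' @examples
#' tsum(c(0.1, 0.2, 0.3), c(TRUE, TRUE, TRUE))  # 0.14
#' @export
tsum <- function(effects_b, mask) {
  if (is.logical(mask)) {
    if (length(mask) != length(effects_b))
      stop("logical mask must cover every marker", call. = FALSE)
    mask <- which(mask)
  }
  if (length(mask) && (min(mask) < 1L || max(mask) > length(effects_b)))
    stop("mask indexes outside the marker vector", call. = FALSE)
  if (!length(mask)) {
    warning("empty marker mask; T_sum = 0")
    return(0)
  }
  sum(effects_b[mask]^2)
}

#' Cyclical-permutation enrichment test for a marker set
#'
#' Builds the null for `T_sum` by rotating the genome-ordered effect
#' vector by a uniformly drawn offset in `1..(M-1)` (with replacement,
#' offset 0 excluded) while holding the marker mask fixed; this preserves
#' the local correlation structure of effects and the set's size/spacing.
#' The one-tailed empirical p is
#' `(1 + #\{T_perm >= T_obs\}) / (n_perm + 1)`; with
#' `pseudocount = FALSE` the pure proportion
#' `#\{T_perm >= T_obs\} / n_perm` is reported instead (which can be 0).
#' Ties count against significance.
#'
#' @param effects_b Numeric vector of effects in genome order (length
#'   >= 2).
#' @param mask Logical vector or integer indices of the gene set's
#'   markers.
#' @param n_perm Number of rotations (default 10000).
#' @param seed Optional integer seed for the offset draws.
#' @param pseudocount Add-one correction (default TRUE).
#' @param keep_null Keep the full null vector (default FALSE; summaries
#'   are always kept).
#' @return A list of class `EnrichmentResult`: `t_sum_obs`, `m_f`,
#'   `n_perm`, `p_empirical`, `null_mean`, `null_sd`, `null_quantiles`,
#'   `seed`, and `null_sums` if kept.
#' @export
cyclical_permutation_test <- function(effects_b, mask, n_perm = 10000L,
                                      seed = NULL, pseudocount = TRUE,
                                      keep_null = FALSE) {
  M <- length(effects_b)
  if (M < 2L) stop("need >= 2 markers", call. = FALSE)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (is.logical(mask)) {
    if (length(mask) != M)
      stop("logical mask must cover every marker", call. = FALSE)
    idx <- which(mask)
  } else idx <- as.integer(mask)
  if (!length(idx)) stop("empty marker mask", call. = FALSE)
  if (length(idx) == M)
    warning("mask covers all markers; T_sum is rotation-invariant, p = 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  b2 <- effects_b^2
  t_obs <- sum(b2[idx])
  offsets <- sample.int(M - 1L, n_perm, replace = TRUE)
  idx0 <- idx - 1L
  null_sums <- vapply(offsets, function(o) sum(b2[(idx0 + o) %% M + 1L]),
                      numeric(1L))
  n_ge <- sum(null_sums >= t_obs)
  p <- if (pseudocount) (1 + n_ge) / (n_perm + 1) else n_ge / n_perm
  res <- list(t_sum_obs = t_obs, m_f = length(idx), n_perm = n_perm,
              p_empirical = p,
              null_mean = mean(null_sums), null_sd = stats::sd(null_sums),
              null_quantiles = stats::quantile(null_sums,
                                               c(0.025, 0.5, 0.975)),
              seed = seed)
  if (keep_null) res$null_sums <- null_sums
  class(res) <- "EnrichmentResult"
  res
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: T_sum = %.4g over %d markers, p = %.4g (%d rotations)\n",
              x$t_sum_obs, x$m_f, x$p_empirical, x$n_perm))
  invisible(x)
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability `P(X >= k)` that two gene sets of sizes `set_a`
#' and `set_b` drawn from a universe of `universe_n` genes share at least
#' `overlap_k` members.
#'
#' @param overlap_k Observed overlap (<= min of the set sizes).
#' @param set_a,set_b Set sizes (each <= `universe_n`).
#' @param universe_n Universe size.
#' @return The upper-tail p-value.
#' @examples
#' hypergeometric_overlap(165, 639, 337, 17315)  # < 2.2e-16
#' @export
hypergeometric_overlap <- function(overlap_k, set_a, set_b, universe_n) {
  if (overlap_k < 0 || set_a < 0 || set_b < 0 ||
      set_a > universe_n || set_b > universe_n ||
      overlap_k > min(set_a, set_b))
    stop("inconsistent overlap counts", call. = FALSE)
  stats::phyper(overlap_k - 1, set_a, universe_n - set_a, set_b,
                lower.tail = FALSE)
}

#' Chromatin-state enrichment folds around TSSs of a gene set
#'
#' For each state: `A` = bases in the state genome-wide, `B` = unique
#' bases in the TSS +/- `window_bp` universe of the gene set, `C` = bases
#' in both, `D` = genome size; fold = `(C/A) / (B/D)`. The TSS is the
#' annotated start for `+` strand genes and the end for `-` strand genes;
#' windows are clamped to chromosome bounds and merged before counting
#' (no double-counted bases).
#'
#' @param seg A [chromatin_segmentation()] object.
#' @param annotation A [gene_annotation()] object.
#' @param gene_set Character vector of gene ids (must all be annotated).
#' @param window_bp Half-width of the TSS window (default 2000).
#' @return A data.frame of class `StateEnrichment`: `state`, `A`, `B`,
#'   `C`, `D`, `fold` (NA-flagged when `A` = 0).
#' @export
chromatin_state_enrichment <- function(seg, annotation, gene_set,
                                       window_bp = 2000L) {
  stopifnot(inherits(seg, "ChromatinSegmentation"),
            inherits(annotation, "GeneAnnotation"))
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, annotation$gene_id)
  if (length(missing))
    stop("gene id(s) absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann <- annotation[annotation$gene_id %in% gene_set, , drop = FALSE]
  sizes <- seg$genome_sizes
  tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  lo <- pmax(0, tss - window_bp)
  hi <- pmin(sizes[ann$chrom], tss + window_bp)
  windows <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = lo + 1L, end = hi)))
  b_bases <- sum(as.numeric(GenomicRanges::width(windows)))
  d_bases <- sum(sizes)
  iv <- seg$intervals
  seg_gr <- GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  states <- sort(unique(iv$state))
  rows <- lapply(states, function(st) {
    gr <- seg_gr[iv$state == st]
    a <- sum(as.numeric(GenomicRanges::width(gr)))
    cc <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(gr, windows, ignore.strand = TRUE))))
    fold <- if (a == 0 || b_bases == 0) NA_real_
            else (cc / a) / (b_bases / d_bases)
    data.frame(state = st, A = a, B = b_bases, C = cc, D = d_bases,
               fold = fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("StateEnrichment", "data.frame")
  out
}
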