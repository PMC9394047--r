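#' @title Ranking, decile windows and conserved/diverged partitions
#' @description Turns per-gene conservation scores into a stable ranking,
#'   decile windows, top/bottom gene sets, and a marker mask mapping genes
#'   to GWAS markers through extended gene windows.
#' @name orthoconserve-partition
NULL

#' Rank genes by a score column
#'
#' Stable total order: by score (descending by default), ties broken
#' lexicographically by gene id, genes with undefined (NA) scores sink to
#' the bottom (ordered among themselves by id).
#'
#' @param score_table data.frame with a `gene_id` column and the score
#'   column named by `key`.
#' @param key Name of the score column (e.g. `"neglog10_p"`).
#' @param descending Largest score first (default TRUE).
#' @return Character vector of gene ids, best rank first.
#' @export
rank_genes <- function(score_table, key, descending = TRUE) {
  if (!"gene_id" %in% colnames(score_table))
    stop("score table needs a gene_id column", call. = FALSE)
  if (!key %in% colnames(score_table))
    stop("no such score column: ", key, call. = FALSE)
  s <- score_table[[key]]
  s[!is.finite(s) & !is.na(s)] <- ifelse(
    s[!is.finite(s) & !is.na(s)] > 0, .Machine$double.xmax,
    -.Machine$double.xmax)
  ord <- order(if (descending) -s else s, score_table$gene_id,
               na.last = TRUE)
  as.character(score_table$gene_id[ord])
}

#' Top and bottom fraction of a ranking
#'
#' Cuts `floor(fraction * n)` genes from each end of a ranking. Which end
#' is "conserved" depends on the metric (the top of a divergence ranking
#' is diverged; the top of a corCor ranking is conserved) and is decided
#' by the caller.
#'
#' @param ranked Character vector from [rank_genes()].
#' @param fraction Fraction in (0, 0.5] (default 0.10).
#' @return List with `top` and `bottom` character vectors, each of size
#'   `floor(fraction * length(ranked))`.
#' @export
top_bottom_sets <- function(ranked, fraction = 0.10) {
  n <- length(ranked)
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  k <- floor(fraction * n)
  if (k < 1L) stop("fraction * n < 1: no genes per set", call. = FALSE)
  list(top = ranked[seq_len(k)], bottom = ranked[seq.int(n - k + 1L, n)])
}

#' Decile-window assignment of a ranking
#'
#' Windows of `floor(n / n_windows)` genes from the top of the ranking;
#' the `n %% n_windows` lowest-ranked genes are dropped (window NA).
#'
#' @param ranked Character vector from [rank_genes()].
#' @param n_windows Number of windows (default 10).
#' @return Integer vector of window indices (1..n_windows, NA = dropped),
#'   named by gene id, in rank order.
#' @export
window_assignment <- function(ranked, n_windows = 10L) {
  n <- length(ranked)
  w <- n %/% n_windows
  if (w < 1L) stop("fewer genes than windows", call. = FALSE)
  idx <- c(rep(seq_len(n_windows), each = w),
           rep(NA_integer_, n - w * n_windows))
  stats::setNames(idx, ranked)
}

#' Build a full conservation partition for one tissue and metric
#'
#' Ranks genes by a divergence or conservation score, assigns decile
#' windows, and cuts the conserved and diverged sets (each
#' `floor(fraction * n)` genes, computed directly from the fraction, not
#' from the windows). For divergence scores (differential expression
#' -log10 p, differential variability -log10 FDR) the top of the ranking
#' is diverged; for corCor the top is conserved — set `top_is` accordingly.
#'
#' @param score_table data.frame with `gene_id` and the score column.
#' @param key Score column name.
#' @param metric Label: one of `"mean_expression_de"`, `"variability"`,
#'   `"corcor"` (free-form allowed).
#' @param tissue Tissue label recorded with the partition.
#' @param top_is `"diverged"` (default; divergence rankings) or
#'   `"conserved"` (corCor).
#' @param fraction Fraction per set (default 0.10).
#' @param n_windows Number of windows (default 10).
#' @return A list of class `ConservationPartition`: `tissue`, `metric`,
#'   `ranked`, `window` (named integer vector), `conserved`, `diverged`,
#'   `fraction`.
#' @export
conservation_partition <- function(score_table, key, metric, tissue = NA,
                                   top_is = c("diverged", "conserved"),
                                   fraction = 0.10, n_windows = 10L) {
  top_is <- match.arg(top_is)
  ranked <- rank_genes(score_table, key)
  sets <- top_bottom_sets(ranked, fraction)
  conserved <- if (top_is == "conserved") sets$top else sets$bottom
  diverged <- if (top_is == "conserved") sets$bottom else sets$top
  structure(list(tissue = tissue, metric = metric, ranked = ranked,
                 window = window_assignment(ranked, n_windows),
                 conserved = conserved, diverged = diverged,
                 fraction = fraction),
            class = "ConservationPartition")
}

#' @export
print.ConservationPartition <- function(x, ...) {
  cat(sprintf("ConservationPartition [%s%s]: %d genes ranked, %d conserved, %d diverged\n",
              x$metric, if (is.na(x$tissue)) "" else paste0(", ", x$tissue),
              length(x$ranked), length(x$conserved), length(x$diverged)))
  invisible(x)
}

#' Mask markers falling in extended gene windows of a gene set
#'
#' A marker is included when its position lies within
#' `[start - extension_bp, end + extension_bp]` (1-based inclusive bounds;
#' a marker exactly `extension_bp` past the gene end is included) of ANY
#' gene in the set, on the gene's chromosome. The mask indexes the
#' genome-ordered marker table; overlapping genes claim markers once (the
#' mask is a union).
#'
#' @param annotation A [gene_annotation()] object.
#' @param markers A [marker_table()] object.
#' @param gene_set Character vector of gene ids (must all be annotated).
#' @param extension_bp Non-negative extension in bp (the cis-regulatory
#'   window; 50 kb in heritability partitioning use).
#' @return Logical vector over the rows of `markers`.
#' @export
assign_markers <- function(annotation, markers, gene_set,
                           extension_bp = 50000) {
  stopifnot(inherits(annotation, "GeneAnnotation"),
            inherits(markers, "MarkerTable"))
  if (extension_bp < 0) stop("extension_bp must be >= 0", call. = FALSE)
  gene_set <- as.character(gene_set)
  missing <- setdiff(gene_set, annotation$gene_id)
  if (length(missing))
    stop("gene id(s) absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann <- annotation[annotation$gene_id %in% gene_set, , drop = FALSE]
  # annotation is 0-based half-open; 1-based inclusive window is
  # [start0 + 1 - ext, end0 + ext], clamped below at 1
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = pmax(1, ann$start + 1 - extension_bp),
                              end = ann$end + extension_bp))
  mk <- GenomicRanges::GRanges(
    seqnames = markers$chrom,
    ranges = IRanges::IRanges(start = markers$pos, end = markers$pos))
  GenomicRanges::countOverlaps(mk, gr) > 0L
}
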