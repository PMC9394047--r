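#' @title Domain containers for the conservation pipeline
#' @description Lightweight S3 containers holding validated inputs:
#'   expression matrices, ortholog maps, gene annotations, GWAS marker
#'   tables and chromatin segmentations.
#' @name orthoconserve-classes
NULL

#' Construct a validated expression matrix
#'
#' Bundles a genes x samples TPM matrix with its species label and the
#' tissue of every sample. TPM values must be non-negative, finite and
#' dense; gene and sample identifiers must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids). Values are TPM.
#' @param species Single character label for the species.
#' @param tissues Character vector of tissue labels, one per sample, either
#'   named by sample id or in column order.
#' @return An object of class `ExpressionMatrix`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "human", c(s1 = "liver", s2 = "brain"))
#' @export
expression_matrix <- function(values, species, tissues) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("TPM values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("TPM values must be non-negative", call. = FALSE)
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("`species` must be a single non-empty label", call. = FALSE)
  tissues <- as.character(tissues)
  if (length(tissues) != ncol(values))
    stop("need one tissue label per sample", call. = FALSE)
  if (!is.null(names(tissues))) {
    missing <- setdiff(colnames(values), names(tissues))
    if (length(missing))
      stop("samples without a tissue label: ",
           paste(missing, collapse = ", "), call. = FALSE)
    tissues <- tissues[colnames(values)]
  } else {
    names(tissues) <- colnames(values)
  }
  if (anyNA(tissues) || any(!nzchar(tissues)))
    stop("every sample needs a non-empty tissue label", call. = FALSE)
  structure(list(values = values, species = species, tissues = tissues),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, species '%s', %d tissues\n",
              nrow(x$values), ncol(x$values), x$species,
              length(unique(x$tissues))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene ids of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene identifiers in row order.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rownames(x$values)
}

#' Restrict an expression matrix to samples from one tissue
#' @param x An `ExpressionMatrix`.
#' @param tissue Tissue label present in `x`.
#' @return An `ExpressionMatrix` with only that tissue's samples.
#' @export
subset_tissue <- function(x, tissue) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep <- names(x$tissues)[x$tissues == tissue]
  if (!length(keep))
    stop("tissue not present: ", tissue, call. = FALSE)
  expression_matrix(x$values[, keep, drop = FALSE], x$species,
                    x$tissues[keep])
}

#' Construct a one-to-one ortholog map
#'
#' @param gene_a,gene_b Character vectors of equal length pairing gene ids
#'   of species A with their one-to-one orthologs in species B. Each id may
#'   appear at most once on its side (the map is bijective).
#' @return A data.frame of class `OrthologMap` with columns `gene_a`,
#'   `gene_b`.
#' @export
ortholog_map <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (length(gene_a) != length(gene_b))
    stop("ortholog columns differ in length", call. = FALSE)
  if (length(gene_a)) {
    if (any(!nzchar(gene_a)) || any(!nzchar(gene_b)) ||
        anyNA(gene_a) || anyNA(gene_b))
      stop("ortholog ids must be non-empty", call. = FALSE)
    if (anyDuplicated(gene_a) || anyDuplicated(gene_b))
      stop("ortholog map must be one-to-one: duplicated id", call. = FALSE)
  }
  structure(data.frame(gene_a = gene_a, gene_b = gene_b,
                       stringsAsFactors = FALSE),
            class = c("OrthologMap", "data.frame"))
}

#' Construct a gene annotation table
#'
#' Coordinates are stored 0-based half-open internally; the TSV reader
#' converts from the 1-based inclusive on-disk convention.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param chrom Chromosome label per gene.
#' @param start,end 0-based half-open interval per gene (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @return A data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in annotation", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end))
    stop("annotation requires 0 <= start < end", call. = FALSE)
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  structure(data.frame(gene_id = gene_id, chrom = as.character(chrom),
                       start = start, end = end, strand = strand,
                       stringsAsFactors = FALSE),
            class = c("GeneAnnotation", "data.frame"))
}

#' Construct a genome-ordered GWAS marker table
#'
#' Rows are sorted to genome order: chromosomes in the order given by
#' `chrom_order` (or first appearance), positions ascending. Genome order is
#' load-bearing: the cyclical permutation null rotates effects along it.
#'
#' @param marker_id Character vector of marker names.
#' @param chrom Chromosome label per marker.
#' @param pos Base-pair position per marker.
#' @param b Finite numeric per-marker GWAS effect.
#' @param chrom_order Optional character vector fixing the chromosome order;
#'   defaults to order of first appearance.
#' @return A data.frame of class `MarkerTable` with attribute
#'   `was_sorted` (TRUE if the input was already in genome order).
#' @export
marker_table <- function(marker_id, chrom, pos, b, chrom_order = NULL) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  b <- as.numeric(b)
  if (anyNA(b) || any(!is.finite(b)))
    stop("marker effects must be finite numbers", call. = FALSE)
  if (anyNA(pos))
    stop("marker positions must be numeric", call. = FALSE)
  if (is.null(chrom_order)) chrom_order <- unique(chrom)
  if (!all(chrom %in% chrom_order))
    stop("marker chromosome missing from chrom_order", call. = FALSE)
  ord <- order(match(chrom, chrom_order), pos)
  out <- data.frame(marker_id = as.character(marker_id)[ord],
                    chrom = chrom[ord], pos = pos[ord], b = b[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("MarkerTable", "data.frame"),
            chrom_order = chrom_order,
            was_sorted = identical(ord, seq_along(ord)))
}

#' Construct a chromatin segmentation
#'
#' Intervals are 0-based half-open, must not overlap within a chromosome,
#' and must fit inside the declared chromosome lengths.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param state State label per interval (a finite label set, e.g. 15
#'   hidden-Markov chromatin states).
#' @param genome_sizes Named numeric vector of chromosome lengths.
#' @return A list of class `ChromatinSegmentation` with elements
#'   `intervals` (data.frame) and `genome_sizes`.
#' @export
chromatin_segmentation <- function(chrom, start, end, state, genome_sizes) {
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  state <- as.character(state)
  if (is.null(names(genome_sizes)) || anyNA(genome_sizes))
    stop("genome_sizes must be a named numeric vector", call. = FALSE)
  if (any(start < 0) || any(start >= end))
    stop("segmentation requires 0 <= start < end", call. = FALSE)
  unknown <- setdiff(unique(chrom), names(genome_sizes))
  if (length(unknown))
    stop("interval chromosome absent from genome_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(end > genome_sizes[chrom]))
    stop("interval extends past chromosome end", call. = FALSE)
  df <- data.frame(chrom = chrom, start = start, end = end, state = state,
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, names(genome_sizes)), df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  for (cc in unique(df$chrom)) {
    sub <- df[df$chrom == cc, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping intervals on chromosome ", cc, call. = FALSE)
  }
  structure(list(intervals = df,
                 genome_sizes = genome_sizes),
            class = "ChromatinSegmentation")
}

#' @export
print.ChromatinSegmentation <- function(x, ...) {
  cat(sprintf("ChromatinSegmentation: %d intervals, %d states, %d chromosomes\n",
              nrow(x$intervals), length(unique(x$intervals$state)),
              length(x$genome_sizes)))
  invisible(x)
}
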