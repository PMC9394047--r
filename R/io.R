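#' @title Readers and writers for on-disk formats
#' @description Strictly validating TSV/BED readers for every format the
#'   pipeline touches, plus canonical writers. The annotation TSV is 1-based
#'   inclusive on disk (GFF-like) and converted to 0-based half-open on
#'   load; BED is already 0-based half-open.
#' @name orthoconserve-io
NULL

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a TPM expression matrix with its sample sheet
#'
#' The expression TSV has a header of sample ids and gene ids in the first
#' column. The sample sheet maps each sample to a tissue (columns `sample`,
#' `tissue`); every matrix sample must appear in it.
#'
#' @param path Path to the expression TSV.
#' @param species Species label to attach.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, species, sample_sheet) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene id column plus >= 1 sample",
         call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("expression TSV contains non-numeric or missing TPM cells",
         call. = FALSE)
  rownames(vals) <- genes
  sheet <- read_tsv_strict(sample_sheet, c("sample", "tissue"),
                           "sample sheet")
  missing <- setdiff(colnames(vals), as.character(sheet$sample))
  if (length(missing))
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tissues <- stats::setNames(as.character(sheet$tissue),
                             as.character(sheet$sample))
  expression_matrix(vals, species, tissues[colnames(vals)])
}

#' Write an expression matrix and sample sheet as canonical TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path for the expression TSV.
#' @param sample_sheet Output path for the sample-sheet TSV.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sample_sheet) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample = names(x$tissues), tissue = unname(x$tissues),
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a one-to-one ortholog map
#'
#' Two-column TSV with a header; a duplicated id on either side is an
#' error. An empty body yields a valid empty map.
#'
#' @param path Path to the TSV.
#' @return An [ortholog_map()] object.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("ortholog map must have two columns", call. = FALSE)
  ortholog_map(df[[1L]], df[[2L]])
}

#' @rdname read_ortholog_map
#' @param x An `OrthologMap` to write.
#' @export
write_ortholog_map <- function(x, path) {
  stopifnot(inherits(x, "OrthologMap"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a gene annotation TSV (1-based inclusive on disk)
#'
#' Columns `gene_id`, `chrom`, `start`, `end`, `strand`. Disk coordinates
#' are 1-based inclusive and converted to 0-based half-open internally:
#' `start - 1`, `end` unchanged.
#'
#' @param path Path to the TSV.
#' @return A [gene_annotation()] object (0-based half-open).
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_strict(path, c("gene_id", "chrom", "start", "end", "strand"),
                        "gene annotation")
  start1 <- as.numeric(df$start)
  if (anyNA(start1) || any(start1 < 1))
    stop("annotation start must be >= 1 (1-based on disk)", call. = FALSE)
  gene_annotation(df$gene_id, df$chrom, start1 - 1, as.numeric(df$end),
                  df$strand)
}

#' @rdname read_gene_annotation
#' @param x A `GeneAnnotation` to write (converted back to 1-based
#'   inclusive).
#' @export
write_gene_annotation <- function(x, path) {
  stopifnot(inherits(x, "GeneAnnotation"))
  out <- data.frame(gene_id = x$gene_id, chrom = x$chrom,
                    start = x$start + 1, end = x$end, strand = x$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a two-column genome-sizes file
#'
#' Headerless TSV of chromosome name and length; chromosome order in this
#' file defines genome order downstream.
#'
#' @param path Path to the file.
#' @return Named numeric vector of chromosome lengths, in file order.
#' @export
read_genome_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || !is.numeric(df[[2L]]))
    stop("genome sizes file must be <chrom>\t<length>", call. = FALSE)
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

#' Read a GWAS marker table
#'
#' TSV with columns `marker`, `chrom`, `pos`, `b`. Rows are sorted to
#' genome order (chromosomes by `chrom_order`, then position ascending);
#' whether the file was already sorted is recorded in the `was_sorted`
#' attribute.
#'
#' @param path Path to the TSV.
#' @param chrom_order Optional chromosome order (e.g. from
#'   [read_genome_sizes()]); defaults to order of first appearance.
#' @return A [marker_table()] object.
#' @export
read_marker_table <- function(path, chrom_order = NULL) {
  df <- read_tsv_strict(path, c("marker", "chrom", "pos", "b"),
                        "marker table")
  b <- suppressWarnings(as.numeric(df$b))
  if (anyNA(b))
    stop("marker table: non-numeric effect size b", call. = FALSE)
  marker_table(df$marker, df$chrom, df$pos, b, chrom_order = chrom_order)
}

#' @rdname read_marker_table
#' @param x A `MarkerTable` to write.
#' @export
write_marker_table <- function(x, path) {
  stopifnot(inherits(x, "MarkerTable"))
  out <- data.frame(marker = x$marker_id, chrom = x$chrom, pos = x$pos,
                    b = x$b, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a chromatin segmentation (BED4) with genome sizes
#'
#' BED4: chrom, start, end, state; headerless, 0-based half-open. Intervals
#' must be non-overlapping per chromosome and lie inside the declared
#' chromosome lengths.
#'
#' @param path Path to the BED file.
#' @param genome_sizes Either a path to a genome-sizes file or a named
#'   numeric vector of chromosome lengths.
#' @return A [chromatin_segmentation()] object.
#' @export
read_segmentation <- function(path, genome_sizes) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.character(genome_sizes) && length(genome_sizes) == 1L &&
      is.null(names(genome_sizes)))
    genome_sizes <- read_genome_sizes(genome_sizes)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("segmentation BED needs 4 columns (chrom, start, end, state)",
         call. = FALSE)
  chromatin_segmentation(df[[1L]], df[[2L]], df[[3L]], df[[4L]],
                         genome_sizes)
}

#' @rdname read_segmentation
#' @param x A `ChromatinSegmentation` to write as BED4.
#' @export
write_segmentation <- function(x, path) {
  stopifnot(inherits(x, "ChromatinSegmentation"))
  utils::write.table(x$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}
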