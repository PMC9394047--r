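#' @title Synthetic paired two-species data with known ground truth
#' @description Seeded generators emulating the structure of large paired
#'   expression compendia (two species, shared tissues, one-to-one
#'   orthologs), genome-ordered GWAS marker tables with an enriched gene
#'   set, and chromatin segmentations with a TSS-favoured state. Each
#'   generator returns the ground truth alongside the data so downstream
#'   stages have a parameter-recovery surface.
#' @name orthoconserve-synthetic
NULL

# One global seed, split into fixed per-generator substreams so adding a
# generator never shifts an existing stream.
.substream <- c(paired_expression = 1L, gwas_markers = 2L, segmentation = 3L)

derive_seed <- function(seed, generator) {
  offset <- .substream[[generator]]
  (as.integer(seed) %% 100000L) * 7919L + offset
}

.tissue_names <- c(
  "adipose", "blood", "brain", "colon", "heart", "ileum", "kidney",
  "liver", "lung", "lymph_node", "mammary", "muscle", "ovary", "pituitary",
  "salivary_gland", "skin", "spleen", "stomach", "testis", "uterus")

#' Generate paired two-species expression matrices with ground truth
#'
#' Simulates log2-scale expression with shared tissue baselines between
#' species, then derives TPM as `pmax(2^x - 0.25, 0)` (the inverse of the
#' pipeline's log2(TPM + 0.25) transform). Structure injected, recorded in
#' the returned truth:
#' \itemize{
#'   \item diverged genes: a fixed `mean_shift_log2` added in species B,
#'     sign drawn per gene (divergence goes both ways);
#'   \item variance-shifted genes (disjoint from diverged): the centred
#'     deviation (module factor + noise) in species B scaled by
#'     `sqrt(variance_ratio)`, so the between-species variance ratio
#'     equals `variance_ratio` exactly in expectation;
#'   \item co-expression: every gene belongs to one of `n_modules` latent
#'     factor modules, `x += lambda_g * f_m` with
#'     `lambda_g ~ +/- Uniform(0.5, 1)`; scrambled modules redraw lambda
#'     independently in species B (module wiring lost, margins kept);
#'   \item tissue-specific genes: elevated by `tissue_shift_log2` in
#'     exactly one tissue, in both species.
#' }
#' Defaults mirror a 17,315-ortholog, 20-tissue paired compendium with
#' per-tissue sample counts of 541 (species A) and 243 (species B).
#'
#' @param n_genes Number of ortholog pairs (default 17315).
#' @param n_tissues Number of shared tissues (default 20, max 20).
#' @param samples_per_tissue Samples per tissue: scalar or length-2
#'   `c(A, B)` (default `c(541, 243)`).
#' @param frac_diverged Fraction of mean-diverged genes (default 0.10).
#' @param mean_shift_log2 Between-species shift for diverged genes, log2
#'   units (default 2).
#' @param frac_variance_shifted Fraction of variance-shifted genes
#'   (default 0.10); must satisfy
#'   `frac_diverged + frac_variance_shifted <= 1`.
#' @param variance_ratio Species-B/species-A variance ratio for shifted
#'   genes (default 4).
#' @param n_modules Number of co-expression modules (default 20; needs
#'   `n_genes >= 10 * n_modules`).
#' @param frac_modules_scrambled Fraction of modules whose loadings are
#'   redrawn in species B (default 0.25).
#' @param noise_sd_log2 Residual SD on the log2 scale (default 1).
#' @param frac_tissue_specific Fraction of genes elevated in one tissue
#'   (default 0.10).
#' @param tissue_shift_log2 Elevation of tissue-specific genes (default 4).
#' @param seed Integer seed (substream 1 of the global scheme).
#' @return List with `expr_a`, `expr_b` ([expression_matrix()]),
#'   `orthologs` ([ortholog_map()]) and `truth` (class `SyntheticTruth`:
#'   `diverged_gene_ids`, `diverged_sign`, `variance_shifted_gene_ids`,
#'   `variance_ratio`, `module_of_gene`, `scrambled_module_ids`,
#'   `tissue_specific_assignments`, `seed`, `params`). Truth ids are
#'   species-A ids.
#' @export
generate_paired_expression <- function(n_genes = 17315L, n_tissues = 20L,
                                       samples_per_tissue = c(541L, 243L),
                                       frac_diverged = 0.10,
                                       mean_shift_log2 = 2,
                                       frac_variance_shifted = 0.10,
                                       variance_ratio = 4,
                                       n_modules = 20L,
                                       frac_modules_scrambled = 0.25,
                                       noise_sd_log2 = 1,
                                       frac_tissue_specific = 0.10,
                                       tissue_shift_log2 = 4,
                                       seed = 1L) {
  fr <- c(frac_diverged, frac_variance_shifted, frac_modules_scrambled,
          frac_tissue_specific)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (frac_diverged + frac_variance_shifted > 1)
    stop("frac_diverged + frac_variance_shifted > 1: disjoint truth sets ",
         "are infeasible", call. = FALSE)
  if (n_genes < 10L * n_modules)
    stop("need n_genes >= 10 * n_modules", call. = FALSE)
  if (n_tissues > length(.tissue_names))
    stop("at most ", length(.tissue_names), " tissues supported",
         call. = FALSE)
  if (length(samples_per_tissue) == 1L)
    samples_per_tissue <- rep(samples_per_tissue, 2L)
  if (any(samples_per_tissue < 2L))
    stop("need >= 2 samples per tissue", call. = FALSE)

  set.seed(derive_seed(seed, "paired_expression"))
  tissues <- .tissue_names[seq_len(n_tissues)]
  ids_a <- sprintf("A_%05d", seq_len(n_genes))
  ids_b <- sprintf("B_%05d", seq_len(n_genes))

  # shared log2-scale baselines
  mu <- stats::rnorm(n_genes, mean = 3, sd = 1.5)
  delta <- matrix(stats::rnorm(n_genes * n_tissues, 0, 0.5),
                  n_genes, n_tissues)

  # truth sets: diverged and variance-shifted are disjoint
  n_div <- floor(frac_diverged * n_genes)
  n_var <- floor(frac_variance_shifted * n_genes)
  pick <- sample.int(n_genes, n_div + n_var)
  div_idx <- pick[seq_len(n_div)]
  var_idx <- pick[n_div + seq_len(n_var)]
  div_sign <- sample(c(-1, 1), n_div, replace = TRUE)
  n_ts <- floor(frac_tissue_specific * n_genes)
  ts_idx <- sample.int(n_genes, n_ts)
  ts_tissue <- sample.int(n_tissues, n_ts, replace = TRUE)

  # module structure
  module_of_gene <- ((seq_len(n_genes) - 1L) %% n_modules) + 1L
  n_scr <- round(frac_modules_scrambled * n_modules)
  scrambled <- sort(sample.int(n_modules, n_scr))
  lam_a <- stats::runif(n_genes, 0.5, 1) * sample(c(-1, 1), n_genes, TRUE)
  lam_b <- lam_a
  redraw <- module_of_gene %in% scrambled
  lam_b[redraw] <- stats::runif(sum(redraw), 0.5, 1) *
    sample(c(-1, 1), sum(redraw), TRUE)

  build_species <- function(n_per_tissue, lambda, species_tag, ids,
                            diverge, var_shift) {
    n_samples <- n_per_tissue * n_tissues
    tissue_of_sample <- rep(tissues, each = n_per_tissue)
    sample_ids <- sprintf("%s_%s_%03d", species_tag, tissue_of_sample,
                          rep(seq_len(n_per_tissue), times = n_tissues))
    base <- mu + if (diverge) {
      shift <- numeric(n_genes); shift[div_idx] <- div_sign * mean_shift_log2
      shift
    } else 0
    x <- matrix(base, n_genes, n_samples)
    x <- x + delta[, match(tissue_of_sample, tissues), drop = FALSE]
    if (n_ts)
      for (k in seq_len(n_ts))
        x[ts_idx[k], tissue_of_sample == tissues[ts_tissue[k]]] <-
          x[ts_idx[k], tissue_of_sample == tissues[ts_tissue[k]]] +
          tissue_shift_log2
    f <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    dev <- lambda * f[module_of_gene, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd_log2),
             n_genes, n_samples)
    if (var_shift && length(var_idx))
      dev[var_idx, ] <- dev[var_idx, , drop = FALSE] * sqrt(variance_ratio)
    x <- x + dev
    tpm <- pmax(2^x - 0.25, 0)
    dimnames(tpm) <- list(ids, sample_ids)
    expression_matrix(tpm, species_tag,
                      stats::setNames(tissue_of_sample, sample_ids))
  }

  expr_a <- build_species(samples_per_tissue[1L], lam_a, "A", ids_a,
                          diverge = FALSE, var_shift = FALSE)
  expr_b <- build_species(samples_per_tissue[2L], lam_b, "B", ids_b,
                          diverge = TRUE, var_shift = TRUE)

  truth <- structure(list(
    diverged_gene_ids = ids_a[div_idx],
    diverged_sign = stats::setNames(div_sign, ids_a[div_idx]),
    variance_shifted_gene_ids = ids_a[var_idx],
    variance_ratio = stats::setNames(rep(variance_ratio, n_var),
                                     ids_a[var_idx]),
    conserved_gene_ids = ids_a[-c(div_idx, var_idx)],
    module_of_gene = stats::setNames(module_of_gene, ids_a),
    scrambled_module_ids = scrambled,
    tissue_specific_assignments = stats::setNames(tissues[ts_tissue],
                                                  ids_a[ts_idx]),
    seed = seed,
    params = list(n_genes = n_genes, n_tissues = n_tissues,
                  samples_per_tissue = samples_per_tissue,
                  frac_diverged = frac_diverged,
                  mean_shift_log2 = mean_shift_log2,
                  frac_variance_shifted = frac_variance_shifted,
                  variance_ratio = variance_ratio, n_modules = n_modules,
                  frac_modules_scrambled = frac_modules_scrambled,
                  noise_sd_log2 = noise_sd_log2,
                  frac_tissue_specific = frac_tissue_specific,
                  tissue_shift_log2 = tissue_shift_log2)),
    class = "SyntheticTruth")

  list(expr_a = expr_a, expr_b = expr_b,
       orthologs = ortholog_map(ids_a, ids_b), truth = truth)
}

#' Generate a genome-ordered GWAS marker table with an enriched gene set
#'
#' Genes are laid out evenly along `n_chroms` chromosomes (`gene i` starts
#' at `(i - 1) * gene_annotation_spacing` within its chromosome, body
#' length `gene_length_bp`, alternating strand); markers are evenly spaced
#' along each chromosome. Effects are `b ~ Normal(0, background_effect_sd^2)`,
#' multiplied by `sqrt(enrichment_ratio)` for markers inside the bodies of
#' a randomly chosen enriched gene set. Markers are emitted in genome
#' order.
#'
#' @param n_markers Total markers (default 10000; must be >= `n_genes`).
#' @param n_chroms Chromosomes (default 5).
#' @param gene_annotation_spacing Distance between successive gene starts,
#'   bp (default 10000).
#' @param enriched_gene_set_size Genes in the enriched set (default 50).
#' @param background_effect_sd SD of background effects (default 0.1).
#' @param enrichment_ratio Variance inflation inside enriched genes,
#'   >= 1 (default 1 = no enrichment).
#' @param n_genes Total genes (default 1000).
#' @param gene_length_bp Gene body length (default =
#'   `gene_annotation_spacing`, so gene bodies tile the genome and a
#'   50-gene set covers ~500 of 10,000 markers at the defaults).
#' @param seed Integer seed (substream 2).
#' @return List with `markers` ([marker_table()]), `annotation`
#'   ([gene_annotation()]), `genome_sizes` (named numeric) and `truth`
#'   (list: `enriched_gene_set`, `enriched_marker_mask`, `seed`, `params`).
#' @export
generate_gwas_markers <- function(n_markers = 10000L, n_chroms = 5L,
                                  gene_annotation_spacing = 10000L,
                                  enriched_gene_set_size = 50L,
                                  background_effect_sd = 0.1,
                                  enrichment_ratio = 1,
                                  n_genes = 1000L,
                                  gene_length_bp = gene_annotation_spacing,
                                  seed = 1L) {
  if (enrichment_ratio < 1)
    stop("enrichment_ratio must be >= 1", call. = FALSE)
  if (n_markers < n_genes)
    stop("need n_markers >= n_genes", call. = FALSE)
  if (enriched_gene_set_size > n_genes)
    stop("enriched set larger than gene universe", call. = FALSE)
  if (gene_length_bp > gene_annotation_spacing)
    stop("gene_length_bp must not exceed the spacing (genes must not ",
         "overlap)", call. = FALSE)
  set.seed(derive_seed(seed, "gwas_markers"))

  genes_per_chrom <- diff(round(seq(0, n_genes, length.out = n_chroms + 1L)))
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  chrom_of_gene <- rep(chroms, times = genes_per_chrom)
  idx_in_chrom <- unlist(lapply(genes_per_chrom, seq_len))
  start0 <- (idx_in_chrom - 1L) * gene_annotation_spacing
  end0 <- start0 + gene_length_bp
  gene_ids <- sprintf("A_%05d", seq_len(n_genes))
  annotation <- gene_annotation(
    gene_ids, chrom_of_gene, start0, end0,
    strand = rep_len(c("+", "-"), n_genes))
  genome_sizes <- stats::setNames(
    as.numeric(genes_per_chrom) * gene_annotation_spacing, chroms)

  markers_per_chrom <- diff(round(
    seq(0, n_markers, length.out = n_chroms + 1L)))
  mk <- do.call(rbind, lapply(seq_len(n_chroms), function(ci) {
    mc <- markers_per_chrom[ci]
    step <- genome_sizes[ci] / mc
    data.frame(chrom = chroms[ci],
               pos = pmax(1, round(step * (seq_len(mc) - 0.5))),
               stringsAsFactors = FALSE)
  }))
  mk$marker_id <- sprintf("m_%06d", seq_len(nrow(mk)))
  mk$b <- stats::rnorm(nrow(mk), 0, background_effect_sd)

  enriched <- sort(sample(gene_ids, enriched_gene_set_size))
  markers <- marker_table(mk$marker_id, mk$chrom, mk$pos, mk$b,
                          chrom_order = chroms)
  in_enriched <- assign_markers(annotation, markers, enriched,
                                extension_bp = 0)
  markers$b[in_enriched] <- markers$b[in_enriched] * sqrt(enrichment_ratio)

  list(markers = markers, annotation = annotation,
       genome_sizes = genome_sizes,
       truth = list(enriched_gene_set = enriched,
                    enriched_marker_mask = in_enriched,
                    seed = seed,
                    params = list(n_markers = n_markers,
                                  n_chroms = n_chroms,
                                  gene_annotation_spacing = gene_annotation_spacing,
                                  enriched_gene_set_size = enriched_gene_set_size,
                                  background_effect_sd = background_effect_sd,
                                  enrichment_ratio = enrichment_ratio,
                                  n_genes = n_genes,
                                  gene_length_bp = gene_length_bp)))
}

#' Generate a chromatin segmentation with a TSS-favoured state
#'
#' Tiles every chromosome in 200-bp windows (last window truncated to the
#' chromosome end, so every base is covered exactly once) and assigns each
#' window a state by weighted sampling: all states have weight 1, except
#' that `state_near_tss` has weight `tss_bias` for windows overlapping
#' TSS +/- 2 kb of any annotated gene.
#'
#' @param annotation A [gene_annotation()] object (TSS = start for `+`
#'   strand genes, end for `-` strand).
#' @param genome_sizes Named numeric vector of chromosome lengths.
#' @param state_near_tss Label of the TSS-favoured state (default "E1").
#' @param background_states Labels of the remaining states (default
#'   `E2..E15`, giving the usual 15-state alphabet).
#' @param tss_bias Odds multiplier near TSSs, >= 1 (default 1 = unbiased).
#' @param window_bp Tiling window size (default 200).
#' @param tss_window_bp Half-width of the TSS neighbourhood (default 2000).
#' @param seed Integer seed (substream 3).
#' @return A [chromatin_segmentation()] object.
#' @export
generate_segmentation <- function(annotation, genome_sizes,
                                  state_near_tss = "E1",
                                  background_states = sprintf("E%d", 2:15),
                                  tss_bias = 1, window_bp = 200L,
                                  tss_window_bp = 2000L, seed = 1L) {
  stopifnot(inherits(annotation, "GeneAnnotation"))
  if (tss_bias < 1) stop("tss_bias must be >= 1", call. = FALSE)
  set.seed(derive_seed(seed, "segmentation"))
  states <- c(state_near_tss, background_states)
  tss <- ifelse(annotation$strand == "+", annotation$start, annotation$end)
  segs <- lapply(names(genome_sizes), function(cc) {
    len <- genome_sizes[[cc]]
    starts <- seq(0, len - 1, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    t_cc <- tss[annotation$chrom == cc]
    near <- rep(FALSE, length(starts))
    if (length(t_cc)) {
      lo <- pmax(0, t_cc - tss_window_bp)
      hi <- pmin(len, t_cc + tss_window_bp)
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = starts + 1L, end = ends),
        IRanges::reduce(IRanges::IRanges(start = lo + 1L, end = hi)))
      near[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    pick <- integer(length(starts))
    probs_near <- c(tss_bias, rep(1, length(background_states)))
    probs_far <- rep(1, length(states))
    pick[near] <- sample.int(length(states), sum(near), replace = TRUE,
                             prob = probs_near)
    pick[!near] <- sample.int(length(states), sum(!near), replace = TRUE,
                              prob = probs_far)
    data.frame(chrom = cc, start = starts, end = ends,
               state = states[pick], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, segs)
  chromatin_segmentation(df$chrom, df$start, df$end, df$state, genome_sizes)
}
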