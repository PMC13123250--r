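#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each gene expressed in all
#' samples, the geometric mean across samples is the reference; a sample's
#' size factor is the median over those genes of count / reference. Genes
#' with a zero in any sample are excluded from the reference set.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stop("no gene has nonzero counts in all samples; cannot normalize")
  logc <- log(counts[keep, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(col) exp(median(col - loggeo)))
  setNames(sf, colnames(counts))
}

#' Variance-flattening log transform of normalized counts
#'
#' log2(count / size_factor + 1): a monotone, variance-flattening
#' approximation to a full variance-stabilizing transformation. It is not
#' a dispersion-trend VST; it preserves the rank and induction structure
#' the downstream scoring uses.
#'
#' @param counts Genes x samples count matrix.
#' @param sf Positive per-sample size factors (default computed by
#'   [size_factors()]).
#' @return Real matrix of the same shape.
#' @export
vst_like_transform <- function(counts, sf = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  if (length(sf) != ncol(counts)) stop("one size factor per sample required")
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' A BGC gene set for induction scoring
#'
#' @param gcf_id Family label the BGC belongs to.
#' @param genes Ordered character vector of gene ids of one BGC.
#' @param backbone Character vector of backbone (core synthase/synthetase)
#'   gene ids; must be a subset of `genes`.
#' @return Object of class `bgc_gene_set`.
#' @export
bgc_gene_set <- function(gcf_id, genes, backbone = character(0)) {
  genes <- as.character(genes)
  if (!length(genes)) stop("gene set must be non-empty")
  if (!all(backbone %in% genes)) stop("backbone genes must be a subset of genes")
  structure(list(gcf_id = gcf_id, genes = genes,
                 backbone = as.character(backbone)),
            class = "bgc_gene_set")
}

#' Infection-induction scores for BGC genes
#'
#' Per-gene score: mean transformed expression in infection samples minus
#' mean in saprophytic controls (per host where hosts are annotated, and
#' pooled). Per-BGC score: mean over member genes. Backbone genes are
#' flagged in the output. Genes absent from the matrix are skipped with a
#' warning and counted.
#'
#' @param transformed Real matrix from [vst_like_transform()].
#' @param metadata Sample metadata: `sample_id`, `condition`
#'   (`"infection"`/`"saprophytic_control"`), optional `host`.
#' @param gene_set A [bgc_gene_set()].
#' @return Object of class `induction_scores`: list with `per_gene` (data
#'   frame gene_id, is_backbone, score plus per-host columns), `per_bgc`
#'   (pooled mean over genes), `gcf_id`, `n_skipped`.
#' @export
bgc_induction_scores <- function(transformed, metadata, gene_set) {
  stopifnot(all(c("sample_id", "condition") %in% names(metadata)))
  m <- match(metadata$sample_id, colnames(transformed))
  if (anyNA(m)) stop("metadata sample missing from matrix")
  infected <- metadata$condition == "infection"
  control <- metadata$condition == "saprophytic_control"
  if (!any(infected)) stop("no infection samples")
  if (!any(control)) stop("no control samples")
  present <- gene_set$genes %in% rownames(transformed)
  n_skipped <- sum(!present)
  if (n_skipped)
    warning(n_skipped, " gene(s) absent from the matrix skipped: ",
            paste(head(gene_set$genes[!present], 5), collapse = ", "))
  genes <- gene_set$genes[present]
  if (!length(genes)) stop("no gene of the set is present in the matrix")
  x <- transformed[genes, m, drop = FALSE]
  score_group <- function(cols_inf, cols_ctl)
    rowMeans(x[, cols_inf, drop = FALSE]) - rowMeans(x[, cols_ctl, drop = FALSE])
  per_gene <- data.frame(gene_id = genes,
                         is_backbone = genes %in% gene_set$backbone,
                         score = score_group(which(infected), which(control)),
                         stringsAsFactors = FALSE)
  if ("host" %in% names(metadata)) {
    for (h in sort(unique(metadata$host[infected]))) {
      gi <- which(infected & metadata$host == h)
      if (length(gi))
        per_gene[[paste0("score_", h)]] <- score_group(gi, which(control))
    }
  }
  rownames(per_gene) <- NULL
  structure(list(per_gene = per_gene,
                 per_bgc = mean(per_gene$score),
                 gcf_id = gene_set$gcf_id,
                 n_skipped = n_skipped),
            class = "induction_scores")
}

#' @export
print.induction_scores <- function(x, ...) {
  cat(sprintf("Induction scores for %s: per-BGC score %.3f over %d genes",
              x$gcf_id, x$per_bgc, nrow(x$per_gene)))
  if (x$n_skipped) cat(sprintf(" (%d skipped)", x$n_skipped))
  cat("\n")
  bb <- x$per_gene[x$per_gene$is_backbone, , drop = FALSE]
  if (nrow(bb))
    cat("  backbone:", paste(sprintf("%s %.3f", bb$gene_id, bb$score),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Export per-BGC heatmap matrices
#'
#' One TSV per BGC gene set: rows are genes (backbone marked with a
#' trailing `*`), columns are samples ordered by (host, timepoint),
#' values the transformed expression. Column order is stable under input
#' shuffling.
#'
#' @param transformed Real matrix from [vst_like_transform()].
#' @param gene_sets List of [bgc_gene_set()] objects.
#' @param metadata Sample metadata with `sample_id` and optionally
#'   `host`, `timepoint`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
heatmap_matrix_export <- function(transformed, gene_sets, metadata, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ord <- order(if ("host" %in% names(metadata)) metadata$host else
    rep("", nrow(metadata)),
    if ("timepoint" %in% names(metadata)) metadata$timepoint else
      rep("", nrow(metadata)),
    metadata$sample_id)
  samples <- metadata$sample_id[ord]
  paths <- character(0)
  for (gs in gene_sets) {
    genes <- gs$genes[gs$genes %in% rownames(transformed)]
    m <- transformed[genes, samples, drop = FALSE]
    lab <- ifelse(genes %in% gs$backbone, paste0(genes, "*"), genes)
    df <- data.frame(gene = lab, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    path <- file.path(dir, paste0("heatmap_", gsub("[^A-Za-z0-9_.-]", "_",
                                                   gs$gcf_id), ".tsv"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
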