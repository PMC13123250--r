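#' Summarize a BGC inventory by product class
#'
#' Counts BGCs in each of the seven classes, per genome and aggregated.
#' The total always equals the number of records; an empty input yields an
#' all-zero summary.
#'
#' @param records A `bgc_table` (may have zero rows).
#' @return An object of class `class_summary`: list with `counts` (named
#'   integer vector over [BGC_CLASSES]), `total`, `smallest_class`,
#'   `largest_class`, `per_genome` (genome x class count table) and
#'   `mean_per_genome`.
#' @export
summarize_by_class <- function(records) {
  validate_bgc_table(records)
  cls <- factor(records$bgc_class, levels = BGC_CLASSES)
  counts <- table(cls)
  counts <- setNames(as.integer(counts), names(counts))
  per_genome <- if (nrow(records))
    table(genome = records$genome_id, class = cls)
  else
    table(genome = character(0), class = cls)
  nz <- counts[counts > 0]
  structure(list(
    counts = counts,
    total = sum(counts),
    smallest_class = if (length(nz)) names(nz)[which.min(nz)] else NA_character_,
    largest_class = if (length(nz)) names(nz)[which.max(nz)] else NA_character_,
    per_genome = per_genome,
    mean_per_genome = if (nrow(per_genome)) mean(rowSums(per_genome)) else NA_real_
  ), class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("BGC class summary:", x$total, "BGCs\n")
  print(x$counts)
  if (!is.na(x$smallest_class))
    cat("largest class:", x$largest_class,
        " smallest class:", x$smallest_class, "\n")
  if (!is.na(x$mean_per_genome))
    cat(sprintf("genomes: %d  mean BGCs per genome: %.2f\n",
                nrow(x$per_genome), x$mean_per_genome))
  invisible(x)
}

#' Association between genome size and BGC count
#'
#' Ordinary least-squares regression of BGC count on genome size (Mb) with
#' Pearson's correlation and its two-sided p-value, as used to ask whether
#' larger genomes harbour more clusters.
#'
#' @param genomes Data frame with columns `genome_size_mb` and `n_bgcs`
#'   (e.g. from [read_genome_meta()] joined with per-genome counts).
#' @return Object of class `bgc_assoc`: list with `pearson_r`, `slope`,
#'   `intercept`, `p_value`, `n`.
#' @export
genome_bgc_association <- function(genomes) {
  stopifnot(is.data.frame(genomes),
            all(c("genome_size_mb", "n_bgcs") %in% names(genomes)))
  x <- genomes$genome_size_mb
  y <- genomes$n_bgcs
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 genomes")
  if (any(x <= 0)) stop("genome_size_mb must be positive")
  if (length(unique(x)) < 2L || stats::var(y) == 0)
    stop("correlation undefined: constant genome size or BGC count")
  fit <- lm(y ~ x)
  ct <- cor.test(x, y, method = "pearson")
  structure(list(pearson_r = unname(ct$estimate),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = ct$p.value,
                 n = length(x)),
            class = "bgc_assoc")
}

#' @export
print.bgc_assoc <- function(x, ...) {
  cat(sprintf(
    "Genome size vs BGC count (n = %d): r = %.3f, p = %.3g\n  fit: n_bgcs = %.3f + %.3f * size_mb\n",
    x$n, x$pearson_r, x$p_value, x$intercept, x$slope))
  invisible(x)
}
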