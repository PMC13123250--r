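#' Classify gene cluster families by taxonomic specificity
#'
#' Three mutually exclusive categories: `singleton` (one member),
#' `genus_specific` (two or more members, all one genus), `multi_genus`
#' (members from at least two genera).
#'
#' @param assignment A `gcf_assignment`.
#' @param records The `bgc_table` the assignment was computed from.
#' @return Object of class `specificity_table`: list with `per_gcf` (data
#'   frame: gcf_id, size, n_genera, category, genera) and `counts` (named
#'   vector over the three categories).
#' @export
classify_specificity <- function(assignment, records) {
  ids <- names(assignment$membership)
  hit <- match(ids, records$bgc_id)
  if (anyNA(hit))
    stop("assigned bgc_id not resolvable to a record: ",
         paste(head(ids[is.na(hit)], 5), collapse = ", "))
  genus <- records$genus[hit]
  by_gcf <- split(genus, assignment$membership[ids])
  per_gcf <- data.frame(
    gcf_id = names(by_gcf),
    size = lengths(by_gcf),
    n_genera = vapply(by_gcf, function(g) length(unique(g)), integer(1)),
    stringsAsFactors = FALSE)
  per_gcf$category <- ifelse(per_gcf$size == 1L, "singleton",
                             ifelse(per_gcf$n_genera == 1L, "genus_specific",
                                    "multi_genus"))
  per_gcf$genera <- vapply(by_gcf, function(g)
    paste(sort(unique(g)), collapse = ";"), character(1))
  rownames(per_gcf) <- NULL
  counts <- vapply(c("singleton", "genus_specific", "multi_genus"),
                   function(ca) sum(per_gcf$category == ca), integer(1))
  structure(list(per_gcf = per_gcf, counts = counts),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  total <- sum(x$counts)
  cat("GCF taxonomic specificity (", total, "families ):\n")
  for (ca in names(x$counts))
    cat(sprintf("  %-15s %6d  (%.1f%%)\n", ca, x$counts[[ca]],
                100 * x$counts[[ca]] / max(total, 1)))
  invisible(x)
}

#' Chi-square goodness-of-fit test on specificity categories
#'
#' Pearson goodness-of-fit of the three observed category counts against
#' expected proportions (uniform by default; the null is a parameter, not
#' an assertion). Always df = 2 for the three-category table.
#'
#' @param table A `specificity_table` or a named 3-vector of counts.
#' @param null Expected proportions over the three categories (sum 1).
#' @return List with `chi2`, `df`, `p_value`, `observed`, `expected`.
#' @export
specificity_chi_square <- function(table, null = rep(1 / 3, 3)) {
  counts <- if (inherits(table, "specificity_table")) table$counts
  else as.numeric(table)
  if (length(counts) != 3L) stop("expected three category counts")
  if (sum(counts) < 1) stop("total count must be >= 1")
  if (abs(sum(null) - 1) > 1e-9) stop("null proportions must sum to 1")
  expected <- sum(counts) * null
  if (any(expected == 0)) stop("expected count of zero under the null")
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE),
       observed = counts, expected = expected)
}

#' Find gene cluster families exclusive to entomopathogenic genera
#'
#' Families whose members span at least `min_genera` distinct
#' entomopathogenic genera and include no member from a
#' non-entomopathogenic genus. Hits are sorted by descending genus count,
#' then gcf_id.
#'
#' @param assignment A `gcf_assignment`.
#' @param records `bgc_table` carrying `is_entomopathogen` flags.
#' @param min_genera Minimum number of distinct entomopathogenic genera.
#' @return Data frame: `gcf_id`, `n_entomo_genera`, `genera`
#'   (semicolon-joined), `n_members`, `member_ids` (semicolon-joined).
#' @export
find_lifestyle_exclusive_gcfs <- function(assignment, records,
                                          min_genera = 3L) {
  ids <- names(assignment$membership)
  hit <- match(ids, records$bgc_id)
  if (anyNA(hit)) stop("assigned bgc_id not resolvable to a record")
  df <- data.frame(gcf = unname(assignment$membership[ids]),
                   bgc_id = ids,
                   genus = records$genus[hit],
                   ento = records$is_entomopathogen[hit],
                   stringsAsFactors = FALSE)
  by_gcf <- split(df, df$gcf)
  keep <- vapply(by_gcf, function(d)
    all(d$ento) && length(unique(d$genus)) >= min_genera, logical(1))
  hits <- by_gcf[keep]
  if (!length(hits))
    return(data.frame(gcf_id = character(0), n_entomo_genera = integer(0),
                      genera = character(0), n_members = integer(0),
                      member_ids = character(0)))
  out <- do.call(rbind, lapply(hits, function(d) data.frame(
    gcf_id = d$gcf[1],
    n_entomo_genera = length(unique(d$genus)),
    genera = paste(sort(unique(d$genus)), collapse = ";"),
    n_members = nrow(d),
    member_ids = paste(sort(d$bgc_id), collapse = ";"),
    stringsAsFactors = FALSE)))
  out <- out[order(-out$n_entomo_genera, out$gcf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genus co-occurrence among exclusivity hits
#'
#' Counts, for each unordered genus pair, the number of hits in which both
#' genera occur — identifying the most frequently co-occurring
#' entomopathogenic genera among shared families.
#'
#' @param hits Result of [find_lifestyle_exclusive_gcfs()].
#' @return Data frame `genus_a`, `genus_b`, `n_gcfs`, sorted by
#'   descending count then genus pair.
#' @export
genus_cooccurrence <- function(hits) {
  empty <- data.frame(genus_a = character(0), genus_b = character(0),
                      n_gcfs = integer(0))
  if (nrow(hits) == 0L) return(empty)
  tallies <- new.env(parent = emptyenv())
  for (g in strsplit(hits$genera, ";", fixed = TRUE)) {
    g <- sort(unique(g))
    if (length(g) < 2L) next
    for (i in seq_len(length(g) - 1L)) for (j in seq.int(i + 1L, length(g))) {
      key <- paste(g[i], g[j], sep = "\t")
      tallies[[key]] <- (if (is.null(tallies[[key]])) 0L else tallies[[key]]) + 1L
    }
  }
  keys <- ls(tallies)
  if (!length(keys)) return(empty)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(genus_a = vapply(parts, `[[`, character(1), 1),
                    genus_b = vapply(parts, `[[`, character(1), 2),
                    n_gcfs = vapply(keys, function(k) tallies[[k]], integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_gcfs, out$genus_a, out$genus_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
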