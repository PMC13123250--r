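# Union-find with path halving; used for thresholded components and for
# the incremental cutoff sweep (edges sorted by distance once, partition
# snapshots taken at each grid point). Returns the component root per node.
uf_union_all <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Assign BGCs to gene cluster families at a distance cutoff
#'
#' Builds the threshold graph over one class's BGCs (edges where
#' `distance <= cutoff`) and takes connected components as families.
#' Singletons are components of size 1. Family ids are
#' `"<class>_<integer>"`, numbered in ascending order of each family's
#' smallest member id, so numbering is deterministic.
#'
#' @param edges Distance edges for one class (columns `bgc_a`, `bgc_b`,
#'   `distance`), or a multi-class edge table plus `bgc_class` column —
#'   classes are then processed independently.
#' @param bgc_ids Character vector of all BGC ids to assign (singletons
#'   included); either a vector (single class, class name taken from
#'   `class_label`) or a named split by class.
#' @param cutoff Distance cutoff in (0, 1).
#' @param class_label Class name used in family ids when `edges` has no
#'   `bgc_class` column.
#' @return Object of class `gcf_assignment`: list with `cutoff`,
#'   `membership` (named character vector bgc_id -> gcf_id) and `sizes`
#'   (data frame gcf_id, bgc_class, size).
#' @export
assign_gcfs <- function(edges, bgc_ids, cutoff, class_label = "ALL") {
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  if (is.list(bgc_ids) && !is.data.frame(bgc_ids)) {
    classes <- names(bgc_ids)
    parts <- lapply(classes, function(cl) {
      e <- edges[edges$bgc_class == cl, , drop = FALSE]
      assign_gcfs(e, bgc_ids[[cl]], cutoff, class_label = cl)
    })
    membership <- do.call(c, lapply(parts, `[[`, "membership"))
    sizes <- do.call(rbind, lapply(parts, `[[`, "sizes"))
    return(structure(list(cutoff = cutoff, membership = membership,
                          sizes = sizes),
                     class = "gcf_assignment"))
  }
  bgc_ids <- as.character(bgc_ids)
  n <- length(bgc_ids)
  if (n == 0L)
    return(structure(list(cutoff = cutoff,
                          membership = setNames(character(0), character(0)),
                          sizes = data.frame(gcf_id = character(0),
                                             bgc_class = character(0),
                                             size = integer(0))),
                     class = "gcf_assignment"))
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$bgc_a, edges$bgc_b)), bgc_ids)
    if (length(unknown))
      stop("edge references unknown bgc_id: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  keep <- edges$distance <= cutoff
  comp <- uf_union_all(n,
                       match(edges$bgc_a[keep], bgc_ids),
                       match(edges$bgc_b[keep], bgc_ids))
  membership_from_components(comp, bgc_ids, class_label, cutoff)
}

# turn a component root vector into a gcf_assignment; families numbered by
# ascending smallest member id
membership_from_components <- function(comp, bgc_ids, class_label, cutoff) {
  min_id <- tapply(bgc_ids, comp, min)
  ord <- rank(min_id[as.character(sort(unique(comp)))])
  fam_num <- ord[match(comp, sort(unique(comp)))]
  gcf <- sprintf("%s_%d", class_label, as.integer(fam_num))
  membership <- setNames(gcf, bgc_ids)
  tab <- table(gcf)
  sizes <- data.frame(gcf_id = names(tab), bgc_class = class_label,
                      size = as.integer(tab), stringsAsFactors = FALSE)
  sizes <- sizes[order(as.integer(sub("^.*_", "", sizes$gcf_id))), ]
  rownames(sizes) <- NULL
  structure(list(cutoff = cutoff, membership = membership, sizes = sizes),
            class = "gcf_assignment")
}

#' @export
print.gcf_assignment <- function(x, ...) {
  cat(sprintf("GCF assignment at cutoff %.2f: %d BGCs in %d families (%d singletons)\n",
              x$cutoff, length(x$membership), nrow(x$sizes),
              sum(x$sizes$size == 1L)))
  invisible(x)
}

#' Sweep clustering cutoffs
#'
#' Recomputes families over a grid of cutoffs (default 0.1 to 0.9 by 0.1)
#' and reports, per class and pooled, the number of families, the number
#' of singletons, and the mean family size. Components are built
#' incrementally: edges are sorted by distance once and merged into a
#' union-find structure, with a partition snapshot at each grid point, so
#' the partitions are nested by construction.
#'
#' @param edges Multi-class distance edge table (as from
#'   [pairwise_distances()]).
#' @param bgc_ids Named list: class -> character vector of ids, or a
#'   `bgc_table` from which it is derived.
#' @param grid Strictly increasing cutoffs in (0, 1).
#' @return Object of class `sweep_result`: data frame with columns
#'   `bgc_class` (including a pooled `"ALL"` row set), `cutoff`, `n_gcfs`,
#'   `n_singletons`, `mean_gcf_size`, plus attribute `assignments` (list of
#'   per-cutoff `gcf_assignment`s).
#' @export
sweep_cutoffs <- function(edges, bgc_ids, grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0L) stop("cutoff grid must be non-empty")
  if (any(diff(grid) <= 0) || any(grid <= 0 | grid >= 1))
    stop("grid must be strictly increasing within (0, 1)")
  if (is.data.frame(bgc_ids) && inherits(bgc_ids, "bgc_table"))
    bgc_ids <- split(bgc_ids$bgc_id, bgc_ids$bgc_class)
  bgc_ids <- bgc_ids[lengths(bgc_ids) > 0L]
  classes <- names(bgc_ids)
  rows <- list()
  assignments <- vector("list", length(grid))
  names(assignments) <- as.character(grid)
  per_cut_members <- vector("list", length(grid))
  for (cl in classes) {
    ids <- sort(as.character(bgc_ids[[cl]]))
    n <- length(ids)
    e <- edges[edges$bgc_class == cl, , drop = FALSE]
    e <- e[order(e$distance), , drop = FALSE]
    ia <- match(e$bgc_a, ids)
    ib <- match(e$bgc_b, ids)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    k <- 1L
    for (g in seq_along(grid)) {
      while (k <= nrow(e) && e$distance[k] <= grid[g]) {
        ra <- find(ia[k]); rb <- find(ib[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        k <- k + 1L
      }
      comp <- vapply(seq_len(n), find, integer(1))
      asg <- membership_from_components(comp, ids, cl, grid[g])
      per_cut_members[[g]] <- c(per_cut_members[[g]], list(asg))
      sz <- asg$sizes$size
      rows[[length(rows) + 1L]] <-
        data.frame(bgc_class = cl, cutoff = grid[g],
                   n_gcfs = length(sz), n_singletons = sum(sz == 1L),
                   mean_gcf_size = n / length(sz),
                   stringsAsFactors = FALSE)
    }
  }
  for (g in seq_along(grid)) {
    parts <- per_cut_members[[g]]
    membership <- do.call(c, lapply(parts, `[[`, "membership"))
    sizes <- do.call(rbind, lapply(parts, `[[`, "sizes"))
    assignments[[g]] <- structure(
      list(cutoff = grid[g], membership = membership, sizes = sizes),
      class = "gcf_assignment")
    sz <- sizes$size
    rows[[length(rows) + 1L]] <-
      data.frame(bgc_class = "ALL", cutoff = grid[g],
                 n_gcfs = length(sz), n_singletons = sum(sz == 1L),
                 mean_gcf_size = if (length(sz)) sum(sz) / length(sz) else NaN,
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, assignments = assignments,
            class = c("sweep_result", "data.frame"))
}

#' Select a clustering cutoff from a sweep
#'
#' Two policies. `"fixed"` returns the supplied cutoff unchanged (with a
#' warning if it is not a grid point). `"knee"` locates the elbow of the
#' pooled mean-family-size curve: the grid point with maximal perpendicular
#' distance to the chord joining the curve's endpoints — the largest cutoff
#' before family sizes explode through merging of dissimilar BGCs. Ties
#' break to the smaller cutoff.
#'
#' @param sweep A `sweep_result`.
#' @param policy `"fixed"` or `"knee"`.
#' @param cutoff The value returned under the fixed policy.
#' @return The selected cutoff (numeric scalar).
#' @export
select_cutoff <- function(sweep, policy = c("knee", "fixed"), cutoff = 0.6) {
  policy <- match.arg(policy)
  if (nrow(sweep) == 0L) stop("empty sweep")
  if (policy == "fixed") {
    if (!any(abs(sweep$cutoff - cutoff) < 1e-12))
      warning("fixed cutoff ", cutoff, " is not a grid point; returned unchanged")
    return(cutoff)
  }
  pooled <- sweep[sweep$bgc_class == "ALL", , drop = FALSE]
  if (nrow(pooled) == 0L) pooled <- sweep
  pooled <- pooled[order(pooled$cutoff), , drop = FALSE]
  x <- pooled$cutoff
  y <- pooled$mean_gcf_size
  if (length(x) == 1L) return(x)
  # perpendicular distance from each point to the endpoint chord
  x0 <- x[1]; y0 <- y[1]; x1 <- x[length(x)]; y1 <- y[length(y)]
  num <- abs((y1 - y0) * x - (x1 - x0) * y + x1 * y0 - y1 * x0)
  d <- num / sqrt((y1 - y0)^2 + (x1 - x0)^2)
  # ties (within numerical noise) break to the smaller cutoff
  tol <- 1e-9 * (1 + max(abs(y)))
  x[which(d >= max(d) - tol)[1]]
}

#' Family size lists per class
#'
#' Sizes of all families of an assignment, optionally restricted to
#' families containing at least one BGC with a MiBIG hit (the
#' experimentally characterized subset).
#'
#' @param assignment A `gcf_assignment`.
#' @param records The `bgc_table` the assignment was computed from
#'   (needed for the MiBIG flags; optional when `mibig_only = FALSE`).
#' @param mibig_only Keep only families with a MiBIG-flagged member.
#' @return Named list: class -> integer vector of family sizes.
#' @export
gcf_size_table <- function(assignment, records = NULL, mibig_only = FALSE) {
  sizes <- assignment$sizes
  if (mibig_only) {
    if (is.null(records)) stop("records required for mibig_only filter")
    hit_ids <- records$bgc_id[records$has_mibig_hit]
    hit_fams <- unique(assignment$membership[names(assignment$membership) %in% hit_ids])
    sizes <- sizes[sizes$gcf_id %in% hit_fams, , drop = FALSE]
  }
  split(sizes$size, sizes$bgc_class)
}
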