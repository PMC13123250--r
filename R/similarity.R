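#' Similarity component weights
#'
#' Weights for combining the Jaccard (domain presence), adjacency (domain
#' order) and DSS (copy sequence similarity) components into one BGC-BGC
#' similarity. Defaults (0.2, 0.05, 0.75) put most weight on copy-level
#' similarity, mirroring the emphasis of domain-architecture clustering
#' tools; all three are explicit configuration.
#'
#' @param w_jaccard,w_adjacency,w_dss Non-negative reals summing to 1.
#' @return Object of class `similarity_weights`.
#' @export
similarity_weights <- function(w_jaccard = 0.2, w_adjacency = 0.05,
                               w_dss = 0.75) {
  w <- c(jaccard = w_jaccard, adjacency = w_adjacency, dss = w_dss)
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  structure(as.list(w), class = "similarity_weights")
}

#' Jaccard index of two domain-type sets
#'
#' Presence component: |a intersect b| / |a union b|.
#'
#' @param a,b Character vectors of domain types (duplicates ignored).
#' @return Real in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("domain-type sets must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

# unordered adjacent pairs of an ordered token list, as canonical strings
adjacent_pairs <- function(types) {
  n <- length(types)
  if (n < 2L) return(character(0))
  a <- types[-n]; b <- types[-1L]
  unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
}

#' Adjacency index of two ordered domain lists
#'
#' Order component: Jaccard index over the sets of unordered adjacent
#' domain-type pairs. When one list has fewer than 2 domains and the other
#' at least 2, the index is 0; when both are single domains it is 1 for
#' equal types and 0 otherwise.
#'
#' @param a,b Character vectors of ordered domain types.
#' @return Real in \[0, 1\].
#' @export
adjacency_index <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("domain lists must be non-empty")
  if (length(a) < 2L && length(b) < 2L)
    return(as.numeric(a[1] == b[1]))
  pa <- adjacent_pairs(a); pb <- adjacent_pairs(b)
  if (length(pa) == 0L || length(pb) == 0L) return(0)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# similarity of two domain-copy sequences: 1 - normalized edit distance;
# 1 if both sequences are absent (type identity is all we can score)
copy_similarity <- function(sa, sb) {
  if (is.na(sa) && is.na(sb)) return(1)
  if (is.na(sa) || is.na(sb)) return(0)
  dmax <- max(nchar(sa), nchar(sb))
  if (dmax == 0L) return(1)
  1 - as.numeric(adist(sa, sb)) / dmax
}

#' Domain sequence similarity (DSS) of two BGCs
#'
#' Copy-level component. For each domain type shared by the two BGCs,
#' copies are matched greedily by descending pairwise similarity (1 minus
#' normalized edit distance of the copy sequences; 1 when both copies lack
#' sequences). Unmatched copies — excess copies of shared types and all
#' copies of types unique to one BGC — contribute 0. The score is the sum
#' of matched-pair similarities divided by (number of matched pairs +
#' number of unmatched copies). Greedy ties break by input order of the
#' copies, for reproducibility.
#'
#' @param a,b [domain_copies()] objects.
#' @return Real in \[0, 1\].
#' @export
domain_seq_similarity <- function(a, b) {
  if (length(a$domain_type) == 0L || length(b$domain_type) == 0L)
    stop("domain lists must be non-empty")
  shared <- intersect(a$domain_type, b$domain_type)
  n_unique <- sum(!(a$domain_type %in% shared)) +
    sum(!(b$domain_type %in% shared))
  if (length(shared) == 0L)
    return(0)
  total_sim <- 0
  n_matched <- 0
  n_excess <- 0
  for (ty in shared) {
    ia <- which(a$domain_type == ty)
    ib <- which(b$domain_type == ty)
    na <- length(ia); nb <- length(ib)
    nm <- min(na, nb)
    n_excess <- n_excess + (na - nm) + (nb - nm)
    sim <- outer(ia, ib, Vectorize(function(i, j)
      copy_similarity(a$sequence[i], b$sequence[j])))
    # greedy: repeatedly take the best remaining pair; ties by input order
    for (k in seq_len(nm)) {
      best <- which(sim == max(sim), arr.ind = TRUE)[1, , drop = TRUE]
      total_sim <- total_sim + sim[best[1], best[2]]
      sim[best[1], ] <- -Inf
      sim[, best[2]] <- -Inf
      n_matched <- n_matched + 1L
    }
  }
  total_sim / (n_matched + n_excess + n_unique)
}

#' Combined distance between two BGCs
#'
#' distance = 1 - (w_J * jaccard + w_A * adjacency + w_D * dss). Only
#' within-class pairs are ever formed; a class mismatch is an error.
#'
#' @param a,b Single-row `bgc_table` slices (or lists with `bgc_id`,
#'   `bgc_class`, `domains` fields).
#' @param w A [similarity_weights()] object.
#' @return One-row data frame (a `DistanceEdge`): `bgc_a`, `bgc_b`,
#'   `jaccard`, `adjacency`, `dss`, `distance`.
#' @export
bgc_distance <- function(a, b, w = similarity_weights()) {
  da <- if (is.data.frame(a)) a$domains[[1]] else a$domains
  db <- if (is.data.frame(b)) b$domains[[1]] else b$domains
  ca <- if (is.data.frame(a)) a$bgc_class[1] else a$bgc_class
  cb <- if (is.data.frame(b)) b$bgc_class[1] else b$bgc_class
  if (!identical(ca, cb))
    stop("cross-class BGC pairs are never formed (", ca, " vs ", cb, ")")
  ja <- jaccard_index(da$domain_type, db$domain_type)
  ad <- adjacency_index(da$domain_type, db$domain_type)
  ds <- domain_seq_similarity(da, db)
  data.frame(
    bgc_a = if (is.data.frame(a)) a$bgc_id[1] else a$bgc_id,
    bgc_b = if (is.data.frame(b)) b$bgc_id[1] else b$bgc_id,
    jaccard = ja, adjacency = ad, dss = ds,
    distance = 1 - (w$jaccard * ja + w$adjacency * ad + w$dss * ds),
    stringsAsFactors = FALSE)
}

#' All within-class pairwise BGC distances
#'
#' Computes every unordered within-class pair; no cross-class edges. Edge
#' order is deterministic: classes in vocabulary order, pairs lexicographic
#' by (bgc_a, bgc_b) with bgc_a < bgc_b.
#'
#' @param records A validated `bgc_table`.
#' @param w A [similarity_weights()] object.
#' @return Data frame of distance edges with a `bgc_class` column.
#' @export
pairwise_distances <- function(records, w = similarity_weights()) {
  validate_bgc_table(records)
  out <- list()
  for (cl in BGC_CLASSES) {
    idx <- which(records$bgc_class == cl)
    if (length(idx) < 2L) next
    idx <- idx[order(records$bgc_id[idx])]
    ids <- records$bgc_id[idx]
    doms <- records$domains[idx]
    tsets <- lapply(doms, function(d) unique(d$domain_type))
    psets <- lapply(doms, function(d) adjacent_pairs(d$domain_type))
    n <- length(idx)
    rows <- vector("list", n * (n - 1L) / 2L)
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        k <- k + 1L
        ninter <- length(intersect(tsets[[i]], tsets[[j]]))
        if (ninter == 0L) {
          # disjoint domain content: all components vanish
          rows[[k]] <- c(0, 0, 0, 1)
          next
        }
        ja <- ninter / length(union(tsets[[i]], tsets[[j]]))
        ad <- if (length(psets[[i]]) == 0L && length(psets[[j]]) == 0L)
          as.numeric(tsets[[i]][1] == tsets[[j]][1])
        else if (length(psets[[i]]) == 0L || length(psets[[j]]) == 0L) 0
        else length(intersect(psets[[i]], psets[[j]])) /
          length(union(psets[[i]], psets[[j]]))
        ds <- domain_seq_similarity(doms[[i]], doms[[j]])
        rows[[k]] <- c(ja, ad, ds,
                       1 - (w$jaccard * ja + w$adjacency * ad + w$dss * ds))
      }
    }
    m <- do.call(rbind, rows)
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)))
    out[[cl]] <- data.frame(bgc_class = cl,
                            bgc_a = ids[pair_i], bgc_b = ids[pair_j],
                            jaccard = m[, 1], adjacency = m[, 2],
                            dss = m[, 3], distance = m[, 4],
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(bgc_class = character(0), bgc_a = character(0),
                      bgc_b = character(0), jaccard = numeric(0),
                      adjacency = numeric(0), dss = numeric(0),
                      distance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a distance edge list as TSV
#'
#' @param edges Result of [pairwise_distances()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
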