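# Independent oracles and fixture builders used across the suite.

# breadth-first connected components: the reference for union-find results
bfs_components <- function(n, from, to) {
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (comp[w] == 0L) {
        comp[w] <- cur
        queue <- c(queue, w)
      }
    }
  }
  comp
}

# exhaustive optimal copy matching for the DSS: per shared type, maximize
# the summed pair similarity over all assignments (permutation search)
brute_force_dss <- function(a, b) {
  shared <- intersect(a$domain_type, b$domain_type)
  n_unique <- sum(!(a$domain_type %in% shared)) +
    sum(!(b$domain_type %in% shared))
  if (length(shared) == 0L) return(0)
  sim_fun <- function(sa, sb) {
    if (is.na(sa) && is.na(sb)) return(1)
    if (is.na(sa) || is.na(sb)) return(0)
    dmax <- max(nchar(sa), nchar(sb))
    if (dmax == 0) return(1)
    1 - as.numeric(utils::adist(sa, sb)) / dmax
  }
  total <- 0; n_matched <- 0; n_excess <- 0
  for (ty in shared) {
    sa <- a$sequence[a$domain_type == ty]
    sb <- b$sequence[b$domain_type == ty]
    if (length(sa) > length(sb)) { tmp <- sa; sa <- sb; sb <- tmp }
    # rows = smaller side; try every injective assignment into the larger
    sim <- outer(seq_along(sa), seq_along(sb),
                 Vectorize(function(i, j) sim_fun(sa[i], sb[j])))
    perms <- gtools_permutations(length(sb), length(sa))
    best <- -Inf
    for (r in seq_len(nrow(perms))) {
      s <- sum(sim[cbind(seq_along(sa), perms[r, ])])
      if (s > best) best <- s
    }
    total <- total + best
    n_matched <- n_matched + length(sa)
    n_excess <- n_excess + length(sb) - length(sa)
  }
  total / (n_matched + n_excess + n_unique)
}

# all ordered arrangements of r items out of n (base-R permutation helper)
gtools_permutations <- function(n, r) {
  if (r == 0L) return(matrix(integer(0), 1, 0))
  if (r == 1L) return(matrix(seq_len(n), ncol = 1))
  out <- list()
  for (i in seq_len(n)) {
    sub <- gtools_permutations(n - 1L, r - 1L)
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }
  do.call(rbind, out)
}

# a tiny hand-built record table for IO / similarity / specificity tests
toy_records <- function() {
  bgc_table(
    bgc_id = c("B1", "B2", "B3", "B4", "B5", "B6"),
    genome_id = c("g1", "g1", "g2", "g3", "g4", "g5"),
    genus = c("Beauveria", "Beauveria", "Cordyceps", "Fusarium",
              "Metarhizium", "Akanthomyces"),
    bgc_class = c("NRPS", "NRPS", "NRPS", "PKSI", "PKSI", "NRPS"),
    domains = list(
      domain_copies(c("KS", "AT", "PP")),
      domain_copies(c("KS", "AT", "PP")),
      domain_copies(c("KS", "AT", "MT")),
      domain_copies(c("C", "A", "T")),
      domain_copies(c("C", "A", "E")),
      domain_copies(c("KS", "AT", "PP"))),
    has_mibig_hit = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

# random domain_copies with controlled copies-per-type multiplicity
random_copies <- function(n_types, max_copies = 2, seq_len = 8,
                          alphabet = sprintf("T%02d", 1:12)) {
  types <- unlist(lapply(sample(alphabet, n_types), function(t)
    rep(t, sample.int(max_copies, 1))))
  domain_copies(types, vapply(seq_along(types), function(i)
    paste(sample(LETTERS[1:6], seq_len, replace = TRUE), collapse = ""),
    character(1)))
}

# small synthetic config used by property suites (keeps runtimes short)
small_sim_config <- function(seed, ...) {
  sim_config(n_genera = 6, species_per_genus = 2, n_ancestral_gcfs = 10,
             gcf_size_law = list(law = "lognormal", mu = 0.8, sigma = 0.7),
             orphan_rate = 0.5, seq_length = 12, seed = seed, ...)
}
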