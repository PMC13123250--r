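#' Simulation configuration
#'
#' Parameters of the synthetic BGC inventory generator. Defaults describe a
#' scaled-down Hypocreales-like community: a dozen genera (about 40%
#' entomopathogenic, matching 7 lifestyle-flagged genera out of the order's
#' well-sampled genera), a few species per genus, heavy-tailed family
#' sizes, and mostly genus-faithful family placement.
#'
#' @param n_genera Number of genera.
#' @param entomopathogen_fraction Fraction of genera flagged
#'   entomopathogenic.
#' @param species_per_genus Species (= genomes) per genus.
#' @param n_ancestral_gcfs Number of planted ancestral families.
#' @param gcf_size_law Family-size law: `list(law = "powerlaw", alpha =)`
#'   or `list(law = "lognormal", mu =, sigma =)`.
#' @param class_probs Probability vector over [BGC_CLASSES] (defaults
#'   proportional to the observed class abundances of Hypocreales BGC
#'   surveys).
#' @param domain_alphabet_size Number of distinct domain-type tokens.
#' @param prototype_length_range Integer pair: domain copies per prototype.
#' @param mutation_rate Per-token substitution probability (applied to both
#'   token identity and sequence residues).
#' @param indel_rate Per-position indel probability on the domain list.
#' @param orphan_rate Expected orphan BGCs per genome (Poisson).
#' @param genus_fidelity Probability that a family member lands in the
#'   family's home genus.
#' @param min_separation Minimum distance required between family
#'   prototypes of the same class (enforced by construction/rejection).
#' @param mibig_rate Probability that a family is flagged as having a
#'   known (MiBIG) representative.
#' @param seq_length Residue-sequence length per domain copy.
#' @param seed Integer seed; the generator is deterministic under it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genera = 12,
                       entomopathogen_fraction = 0.4,
                       species_per_genus = 4,
                       n_ancestral_gcfs = 40,
                       gcf_size_law = list(law = "lognormal", mu = 1, sigma = 0.8),
                       class_probs = c(NRPS = 4950, PKSI = 2899,
                                       PKSOTHER = 211, `PKS-NRP_HYBRIDS` = 1156,
                                       TERPENE = 2314, RIPPS = 40,
                                       OTHERS = 1398) / 12968,
                       domain_alphabet_size = 400,
                       prototype_length_range = c(5, 12),
                       mutation_rate = 0.03,
                       indel_rate = 0.01,
                       orphan_rate = 1,
                       genus_fidelity = 0.85,
                       min_separation = 0.8,
                       mibig_rate = 0.1,
                       seq_length = 30,
                       seed = 1) {
  class_probs <- class_probs[BGC_CLASSES]
  if (anyNA(class_probs) || abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must cover the seven classes and sum to 1")
  rates <- c(mutation_rate, indel_rate, entomopathogen_fraction,
             genus_fidelity, mibig_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (orphan_rate < 0) stop("orphan_rate must be non-negative")
  if (n_ancestral_gcfs == 0 && orphan_rate == 0)
    stop("infeasible config: no ancestral families and no orphans")
  law <- gcf_size_law$law
  if (!law %in% c("powerlaw", "lognormal"))
    stop("gcf_size_law$law must be 'powerlaw' or 'lognormal'")
  if (law == "powerlaw" && gcf_size_law$alpha <= 1)
    stop("power-law alpha must exceed 1")
  if (law == "lognormal" && gcf_size_law$sigma <= 0)
    stop("lognormal sigma must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Draw family sizes from a discrete heavy-tail law
#'
#' Power-law sizes are drawn by inverse CDF on the zeta-normalized pmf
#' p(k) = k^-alpha / zeta(alpha) over k >= 1 (truncated far in the tail
#' with the remaining mass lumped on the truncation point); lognormal
#' sizes by rounding continuous draws, floored at 1.
#'
#' @param law `list(law = "powerlaw", alpha =)` or
#'   `list(law = "lognormal", mu =, sigma =)`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`, all values >= 1.
#' @export
simulate_gcf_sizes <- function(law, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (law$law == "powerlaw") {
    alpha <- law$alpha
    if (alpha <= 1) stop("power-law alpha must exceed 1 (non-normalizable)")
    kmax <- 1e6L
    k <- seq_len(kmax)
    pmf <- k^(-alpha)
    pmf <- pmf / hurwitz_zeta(alpha, 1)
    cdf <- cumsum(pmf)
    u <- runif(n)
    sz <- findInterval(u, cdf) + 1L  # inverse CDF; u > cdf[kmax] -> kmax + 1
    pmin(sz, kmax)
  } else if (law$law == "lognormal") {
    if (law$sigma <= 0) stop("lognormal sigma must be positive")
    pmax(1L, as.integer(round(rlnorm(n, law$mu, law$sigma))))
  } else stop("unknown size law: ", law$law)
}

# sample one element of a vector (safe for length-1 vectors, where
# sample() would treat the value as a range)
sample1 <- function(v) v[sample.int(length(v), 1L)]

# random residue sequence over the 20-letter amino-acid alphabet
random_seq <- function(len) {
  paste(sample(LETTERS[c(1:20)], len, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate) {
  if (rate == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(LETTERS[1:20], sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# mutate a prototype's domain copies: token substitutions, residue
# substitutions, and per-position indels on the domain list
mutate_prototype <- function(proto, cfg, alphabet) {
  types <- proto$domain_type
  seqs <- proto$sequence
  sub_hit <- runif(length(types)) < cfg$mutation_rate
  if (any(sub_hit)) {
    types[sub_hit] <- sample(alphabet, sum(sub_hit), replace = TRUE)
    seqs[sub_hit] <- vapply(seqs[sub_hit], function(s)
      random_seq(nchar(s)), character(1))
  }
  seqs <- vapply(seqs, mutate_seq, character(1), rate = cfg$mutation_rate)
  if (cfg$indel_rate > 0) {
    del <- runif(length(types)) < cfg$indel_rate / 2
    if (any(del) && sum(!del) >= 1L) {
      types <- types[!del]; seqs <- seqs[!del]
    }
    if (runif(1) < cfg$indel_rate * length(types) / 2) {
      pos <- sample(length(types) + 1L, 1L)
      types <- append(types, sample(alphabet, 1L), after = pos - 1L)
      seqs <- append(seqs, random_seq(cfg$seq_length), after = pos - 1L)
    }
  }
  domain_copies(types, seqs)
}

#' Simulate a BGC inventory with known family ground truth
#'
#' Plants `n_ancestral_gcfs` ancestral families. Each family gets a class,
#' a home genus, and a prototype domain architecture whose tokens are
#' drawn without replacement from the class's token pool, so prototypes of
#' the same class share no domain types and inter-family distance is 1 (a
#' rejection check enforces `min_separation` regardless). A target size is
#' drawn from the configured law; members are placed in the home genus
#' with probability `genus_fidelity` (else a random genus) and are mutated
#' copies of the prototype. Orphan BGCs with fresh random architectures
#' are injected per genome at rate `orphan_rate`. Genome sizes get a weak
#' positive link to BGC count.
#'
#' @param config A [sim_config()].
#' @return List with `records` (a `bgc_table`), `genomes` (a
#'   `GenomeMeta` data frame), and `truth` (list: `family` named vector
#'   bgc_id -> true family, `family_genera` list of genus sets,
#'   `induced_genes` reserved for the expression simulator).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  n_ento <- round(cfg$entomopathogen_fraction * cfg$n_genera)
  ento <- setNames(rep(FALSE, cfg$n_genera), genera)
  if (n_ento > 0) ento[seq_len(n_ento)] <- TRUE
  genomes <- expand.grid(sp = seq_len(cfg$species_per_genus),
                         genus = genera, stringsAsFactors = FALSE)
  genomes$genome_id <- sprintf("%s_g%d", genomes$genus, genomes$sp)
  alphabet <- sprintf("DOM%04d", seq_len(cfg$domain_alphabet_size))

  classes <- sample(BGC_CLASSES, cfg$n_ancestral_gcfs, replace = TRUE,
                    prob = cfg$class_probs)
  # per-class token pools; prototype tokens drawn without replacement so
  # same-class prototypes are disjoint in domain content
  pools <- setNames(lapply(BGC_CLASSES, function(cl) sample(alphabet)),
                    BGC_CLASSES)
  protos <- vector("list", cfg$n_ancestral_gcfs)
  w <- similarity_weights()
  for (f in seq_len(cfg$n_ancestral_gcfs)) {
    cl <- classes[f]
    len <- sample1(seq(cfg$prototype_length_range[1],
                       cfg$prototype_length_range[2]))
    if (length(pools[[cl]]) < len)
      stop("domain alphabet too small for the requested families")
    toks <- pools[[cl]][seq_len(len)]
    pools[[cl]] <- pools[[cl]][-seq_len(len)]
    protos[[f]] <- domain_copies(toks, vapply(seq_len(len), function(i)
      random_seq(cfg$seq_length), character(1)))
  }
  # rejection check on prototype separation (guaranteed by construction,
  # verified defensively)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) < 2L) next
    for (i in idx[-length(idx)]) for (j in idx[idx > i]) {
      d <- bgc_distance(list(bgc_id = "a", bgc_class = cl, domains = protos[[i]]),
                        list(bgc_id = "b", bgc_class = cl, domains = protos[[j]]),
                        w)$distance
      if (d < cfg$min_separation)
        stop("prototype separation violated; increase domain_alphabet_size")
    }
  }

  home_genus <- sample(genera, cfg$n_ancestral_gcfs, replace = TRUE)
  fam_sizes <- simulate_gcf_sizes(cfg$gcf_size_law, cfg$n_ancestral_gcfs)
  fam_mibig <- runif(cfg$n_ancestral_gcfs) < cfg$mibig_rate

  rows <- list()
  truth <- character(0)
  counter <- 0L
  for (f in seq_len(cfg$n_ancestral_gcfs)) {
    for (m in seq_len(fam_sizes[f])) {
      g <- if (runif(1) < cfg$genus_fidelity) home_genus[f]
      else sample(genera, 1L)
      gi <- sample1(which(genomes$genus == g))
      counter <- counter + 1L
      id <- sprintf("BGC%05d", counter)
      rows[[counter]] <- list(
        bgc_id = id, genome_id = genomes$genome_id[gi], genus = g,
        bgc_class = classes[f],
        domains = mutate_prototype(protos[[f]], cfg, alphabet),
        has_mibig_hit = fam_mibig[f] && m == 1L,
        truth = sprintf("FAM%04d", f))
    }
  }
  # orphans: fresh random architectures, unique truth labels
  n_orph <- rpois(nrow(genomes), cfg$orphan_rate)
  for (gi in seq_len(nrow(genomes))) {
    for (o in seq_len(n_orph[gi])) {
      counter <- counter + 1L
      len <- sample1(seq(cfg$prototype_length_range[1],
                         cfg$prototype_length_range[2]))
      rows[[counter]] <- list(
        bgc_id = sprintf("BGC%05d", counter),
        genome_id = genomes$genome_id[gi], genus = genomes$genus[gi],
        bgc_class = sample(BGC_CLASSES, 1L, prob = cfg$class_probs),
        domains = domain_copies(sample(alphabet, len),
                                vapply(seq_len(len), function(i)
                                  random_seq(cfg$seq_length), character(1))),
        has_mibig_hit = FALSE,
        truth = sprintf("ORPHAN%05d", counter))
    }
  }
  if (length(rows) == 0L) stop("empty simulation; check config")
  records <- bgc_table(
    bgc_id = vapply(rows, `[[`, character(1), "bgc_id"),
    genome_id = vapply(rows, `[[`, character(1), "genome_id"),
    genus = vapply(rows, `[[`, character(1), "genus"),
    bgc_class = vapply(rows, `[[`, character(1), "bgc_class"),
    domains = lapply(rows, `[[`, "domains"),
    is_entomopathogen = ento[vapply(rows, `[[`, character(1), "genus")],
    has_mibig_hit = vapply(rows, `[[`, logical(1), "has_mibig_hit"))
  truth <- setNames(vapply(rows, `[[`, character(1), "truth"),
                    records$bgc_id)

  n_bgcs <- as.integer(table(factor(records$genome_id,
                                    levels = genomes$genome_id)))
  genome_meta <- data.frame(
    genome_id = genomes$genome_id, genus = genomes$genus,
    genome_size_mb = pmax(20, 30 + 0.15 * n_bgcs + rnorm(nrow(genomes), 0, 4)),
    n_bgcs = n_bgcs, stringsAsFactors = FALSE)

  fam_lab <- truth[!startsWith(truth, "ORPHAN")]
  family_genera <- lapply(split(records$genus[match(names(fam_lab),
                                                    records$bgc_id)],
                                fam_lab), unique)
  list(records = records, genomes = genome_meta,
       truth = list(family = truth, family_genera = family_genera,
                    induced_genes = character(0)))
}

#' Simulate a negative-binomial RNA-seq count matrix with planted induction
#'
#' Gene baselines are lognormal; counts are negative binomial with the
#' given dispersion (variance = mu + dispersion * mu^2). Genes in
#' `induced_genes` have their mean multiplied by `2^log2fc` in infection
#' samples.
#'
#' @param n_genes Number of genes (ids `gene0001`...).
#' @param samples Data frame with columns `sample_id`, `condition`
#'   (`"infection"` / `"saprophytic_control"`), and optionally `host`,
#'   `timepoint`.
#' @param induced_genes Character vector of induced gene ids.
#' @param log2fc Planted log2 fold change.
#' @param dispersion NB dispersion (> 0).
#' @param baseline_mean Mean of the lognormal baseline (0 gives an
#'   all-zero matrix).
#' @param seed Optional integer seed.
#' @return Integer matrix genes x samples with dimnames.
#' @export
simulate_counts_matrix <- function(n_genes, samples, induced_genes = character(0),
                                   log2fc = 0, dispersion = 0.05,
                                   baseline_mean = 200, seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be positive")
  stopifnot(all(c("sample_id", "condition") %in% names(samples)))
  infected <- samples$condition == "infection"
  if (!any(infected) || !all(xor(infected, samples$condition == "saprophytic_control")))
    stop("need at least one infection and one saprophytic_control sample")
  if (!any(!infected)) stop("need at least one control sample")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  if (baseline_mean == 0) {
    m <- matrix(0L, n_genes, nrow(samples),
                dimnames = list(genes, samples$sample_id))
    return(m)
  }
  base <- rlnorm(n_genes, log(baseline_mean), 0.8)
  mu <- matrix(base, n_genes, nrow(samples))
  mu[genes %in% induced_genes, infected] <-
    mu[genes %in% induced_genes, infected] * 2^log2fc
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                n_genes, nrow(samples),
                dimnames = list(genes, samples$sample_id))
  storage.mode(cnt) <- "integer"
  cnt
}
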