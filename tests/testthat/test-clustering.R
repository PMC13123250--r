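mk_edges <- function(a, b, d, class = "NRPS") {
  data.frame(bgc_class = class, bgc_a = a, bgc_b = b, distance = d,
             stringsAsFactors = FALSE)
}

test_that("families are transitive closures of the threshold graph", {
  e <- mk_edges(c("1", "2", "1"), c("2", "3", "3"), c(0.3, 0.3, 0.9))
  asg <- assign_gcfs(e, c("1", "2", "3"), cutoff = 0.6, class_label = "NRPS")
  expect_length(unique(asg$membership), 1)
  expect_equal(asg$sizes$size, 3L)
  # below every edge: all singletons
  asg2 <- assign_gcfs(e, c("1", "2", "3"), cutoff = 0.2, class_label = "NRPS")
  expect_length(unique(asg2$membership), 3)
  expect_true(all(asg2$sizes$size == 1L))
  # empty input
  asg0 <- assign_gcfs(e[0, ], character(0), cutoff = 0.5)
  expect_length(asg0$membership, 0)
  expect_error(assign_gcfs(mk_edges("1", "99", 0.1), c("1", "2"), 0.5),
               "unknown")
  expect_error(assign_gcfs(e, c("1", "2", "3"), cutoff = 1.2), "cutoff")
})

test_that("family ids are deterministic and partition all BGCs", {
  sim <- simulate_dataset(small_sim_config(seed = 51))
  edges <- pairwise_distances(sim$records)
  ids <- split(sim$records$bgc_id, sim$records$bgc_class)
  asg <- assign_gcfs(edges, ids, cutoff = 0.6)
  expect_setequal(names(asg$membership), sim$records$bgc_id)
  expect_equal(sum(asg$sizes$size), nrow(sim$records))
  expect_true(all(grepl("^[A-Za-z_-]+_[0-9]+$", asg$membership)))
  # per-class family sizes sum to per-class record counts
  per_class <- table(sim$records$bgc_class)
  for (cl in names(per_class))
    expect_equal(sum(asg$sizes$size[asg$sizes$bgc_class == cl]),
                 unname(per_class[[cl]]))
})

test_that("sweep metrics are monotone along the default grid", {
  sim <- simulate_dataset(small_sim_config(seed = 52))
  edges <- pairwise_distances(sim$records)
  sw <- sweep_cutoffs(edges, sim$records)
  for (cl in unique(sw$bgc_class)) {
    rows <- sw[sw$bgc_class == cl, ]
    rows <- rows[order(rows$cutoff), ]
    expect_equal(nrow(rows), 9)  # 0.1 ... 0.9
    expect_true(all(diff(rows$n_gcfs) <= 0))
    expect_true(all(diff(rows$n_singletons) <= 0))
    expect_true(all(diff(rows$mean_gcf_size) >= 0))
    expect_true(all(rows$n_singletons <= rows$n_gcfs))
  }
  expect_error(sweep_cutoffs(edges, sim$records, grid = numeric(0)), "grid")
  expect_error(sweep_cutoffs(edges, sim$records, grid = c(0.5, 0.3)), "grid")
})

test_that("a sweep with no mergeable pairs keeps every BGC a singleton", {
  ids <- sprintf("b%02d", 1:8)
  pairs <- t(combn(ids, 2))
  e <- mk_edges(pairs[, 1], pairs[, 2], rep(0.95, nrow(pairs)))
  sw <- sweep_cutoffs(e, list(NRPS = ids))
  per_class <- sw[sw$bgc_class == "NRPS", ]
  expect_true(all(per_class$n_gcfs == 8))
  expect_true(all(per_class$n_singletons == 8))
})

test_that("partitions are nested along the cutoff grid", {
  for (seed in c(61, 62)) {
    sim <- simulate_dataset(small_sim_config(seed = seed))
    edges <- pairwise_distances(sim$records)
    sw <- sweep_cutoffs(edges, sim$records)
    asgs <- attr(sw, "assignments")
    for (g in seq_len(length(asgs) - 1)) {
      fine <- asgs[[g]]$membership
      coarse <- asgs[[g + 1]]$membership[names(fine)]
      # each fine family lies inside exactly one coarse family
      for (fam in split(names(fine), fine))
        expect_length(unique(coarse[fam]), 1)
    }
  }
})

test_that("union-find components agree with a BFS oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    ids <- sprintf("n%03d", seq_len(n))
    n_e <- sample(0:(2 * n), 1)
    from <- sample(n, n_e, replace = TRUE)
    to <- sample(n, n_e, replace = TRUE)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    d <- runif(length(from), 0, 0.5)
    e <- mk_edges(ids[from], ids[to], d)
    asg <- assign_gcfs(e, ids, cutoff = 0.6, class_label = "NRPS")
    oracle <- bfs_components(n, from, to)
    # same partition up to labels
    expect_equal(length(unique(asg$membership)), length(unique(oracle)))
    expect_true(all(tapply(asg$membership[ids], oracle,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("union-find components agree with igraph", {
  skip_if_not_installed("igraph")
  set.seed(78)
  n <- 120
  ids <- sprintf("n%03d", 1:n)
  from <- sample(n, 150, replace = TRUE)
  to <- sample(n, 150, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  e <- mk_edges(ids[from], ids[to], runif(length(from), 0, 0.3))
  asg <- assign_gcfs(e, ids, cutoff = 0.5, class_label = "NRPS")
  g <- igraph::graph_from_data_frame(data.frame(ids[from], ids[to]),
                                     directed = FALSE,
                                     vertices = ids)
  comp <- igraph::components(g)$membership[ids]
  expect_equal(length(unique(asg$membership)), max(comp))
  expect_true(all(tapply(asg$membership[ids], comp,
                         function(x) length(unique(x))) == 1))
})

test_that("cutoff selection policies behave as documented", {
  mk_sweep <- function(mean_sizes) {
    structure(data.frame(bgc_class = "ALL", cutoff = seq(0.1, 0.9, 0.1),
                         n_gcfs = 10, n_singletons = 2,
                         mean_gcf_size = mean_sizes),
              class = c("sweep_result", "data.frame"))
  }
  flat_then_explode <- mk_sweep(c(2, 2.1, 2.2, 2.3, 2.4, 2.5, 5, 10, 20))
  expect_equal(select_cutoff(flat_then_explode, "knee"), 0.6)
  linear <- mk_sweep(seq(2, 10, length.out = 9))
  expect_equal(select_cutoff(linear, "knee"), 0.1)  # tie-break to smallest
  expect_equal(select_cutoff(linear, "fixed", cutoff = 0.6), 0.6)
  expect_warning(out <- select_cutoff(linear, "fixed", cutoff = 0.55),
                 "grid")
  expect_equal(out, 0.55)
  # knee oracle: exhaustive chord-distance enumeration
  y <- flat_then_explode$mean_gcf_size
  x <- flat_then_explode$cutoff
  chord <- function(i) {
    x0 <- x[1]; y0 <- y[1]; x1 <- x[9]; y1 <- y[9]
    abs((y1 - y0) * x[i] - (x1 - x0) * y[i] + x1 * y0 - y1 * x0) /
      sqrt((y1 - y0)^2 + (x1 - x0)^2)
  }
  expect_equal(x[which.max(vapply(1:9, chord, numeric(1)))], 0.6)
})

test_that("family size tables honour the MiBIG filter", {
  membership <- c(A = "NRPS_1", B = "NRPS_1", C = "NRPS_1",
                  D = "NRPS_2", E = "NRPS_3")
  asg <- structure(list(cutoff = 0.6, membership = membership,
                        sizes = data.frame(gcf_id = c("NRPS_1", "NRPS_2", "NRPS_3"),
                                           bgc_class = "NRPS",
                                           size = c(3L, 1L, 1L))),
                   class = "gcf_assignment")
  rec <- bgc_table(bgc_id = c("A", "B", "C", "D", "E"),
                   genome_id = "g", genus = "Beauveria", bgc_class = "NRPS",
                   domains = rep(list(domain_copies("KS")), 5),
                   has_mibig_hit = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sort(gcf_size_table(asg)$NRPS, decreasing = TRUE), c(3L, 1L, 1L))
  expect_equal(sum(unlist(gcf_size_table(asg))), 5)
  expect_equal(gcf_size_table(asg, rec, mibig_only = TRUE)$NRPS, 3L)
  rec$has_mibig_hit[] <- FALSE
  expect_length(unlist(gcf_size_table(asg, rec, mibig_only = TRUE)), 0)
})

test_that("clustering recovers planted families at the knee cutoff", {
  skip_if_not_installed("mclust")
  sim <- simulate_dataset(sim_config(mutation_rate = 0.03, seed = 7))
  edges <- pairwise_distances(sim$records)
  sw <- sweep_cutoffs(edges, sim$records)
  cut <- select_cutoff(sw, "knee")
  asg <- attr(sw, "assignments")[[as.character(cut)]]
  ari <- mclust::adjustedRandIndex(asg$membership[names(sim$truth$family)],
                                   sim$truth$family)
  expect_gte(ari, 0.9)
})
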