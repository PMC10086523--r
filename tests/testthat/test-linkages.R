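sim_small <- function(seed = 71, n_cells = 200, noise = "sampling")
  simulate_multiome(multiome_sim_params(n_cells = n_cells, seed = seed,
                                        noise = noise))

test_that("aggregates are condition-pure and honor the overlap constraints", {
  sim <- sim_small(n_cells = 500)
  for (cond in c("young", "aged")) {
    agg <- make_aggregates(sim$cells, cond, aggregate_config(k = 40),
                           seed = 72)
    conds <- sim$cells$cells$condition[match(unlist(agg$members),
                                             sim$cells$cells$cell)]
    expect_true(all(conds == cond))
    expect_true(all(lengths(agg$members) == 40))
    # exhaustive pairwise intersection check of both constraints
    shared <- utils::combn(length(agg$members), 2, function(p)
      length(intersect(agg$members[[p[1]]], agg$members[[p[2]]])))
    expect_lte(stats::median(shared), 0)
    expect_lte(mean(shared / 40), 0.10)
  }
})

test_that("k = 1 aggregates are disjoint single cells", {
  sim <- sim_small(seed = 73, n_cells = 60)
  agg <- make_aggregates(sim$cells, "young",
                         aggregate_config(k = 1, n_aggregates = 30),
                         seed = 74)
  expect_true(all(lengths(agg$members) == 1))
  expect_equal(anyDuplicated(unlist(agg$members)), 0L)
})

test_that("duplicate cells cap the number of acceptable aggregates", {
  n <- 10
  acc <- Matrix::Matrix(matrix(rep(c(1, 0, 1, 1, 0), n), n, 5,
                               byrow = TRUE), sparse = TRUE)
  ex <- Matrix::Matrix(matrix(1, n, 2), sparse = TRUE)
  peaks <- data.frame(chrom = "chrS", start = (0:4) * 1e4,
                      end = (0:4) * 1e4 + 200, name = paste0("p", 1:5))
  genes <- data.frame(name = c("g1", "g2"), chrom = "chrS",
                      tss = c(1e4, 2e4), strand = "+")
  cells <- data.frame(cell = paste0("c", 1:n),
                      condition = rep(c("young", "aged"), each = n / 2))
  cm <- cell_matrices(acc, ex, peaks, genes, cells)
  expect_error(make_aggregates(cm, "young", aggregate_config(k = 3),
                               seed = 1),
               "two aggregates")
})

test_that("aggregation requires at least k cells", {
  sim <- sim_small(seed = 75, n_cells = 45)
  expect_error(make_aggregates(sim$cells, "young",
                               aggregate_config(k = 100)),
               "fewer than k")
})

test_that("co-accessibility scores behave at limits", {
  sim <- sim_small(seed = 76)
  agg <- make_aggregates(sim$cells, "young", aggregate_config(k = 20),
                         seed = 77)
  # duplicated peak: correlation 1
  agg2 <- agg
  agg2$access <- cbind(agg$access[, 1:10], dup = agg$access[, 5])
  peaks <- sim$cells$peaks[1:11, ]
  peaks$start[11] <- peaks$start[5] + 1000
  peaks$end[11] <- peaks$end[5] + 1000
  peaks$name[11] <- "dup"
  sp <- coaccessibility_scores(agg2, peaks, max_dist = 5e5)
  dup_row <- sp[sp$peak1 == "peak_005" & sp$peak2 == "dup", ]
  expect_equal(dup_row$score, 1)
  # distance cap: peaks 600 kb apart are never scored
  far_peaks <- data.frame(chrom = "chrS", start = c(0, 6e5),
                          end = c(200, 6e5 + 200), name = c("a", "b"))
  agg3 <- agg
  agg3$access <- agg$access[, 1:2]
  expect_equal(nrow(coaccessibility_scores(agg3, far_peaks,
                                           max_dist = 5e5)), 0)
  expect_error(coaccessibility_scores(
    structure(list(condition = "young",
                   access = agg$access[1:5, ], expr = agg$expr[1:5, ],
                   members = agg$members[1:5], k = agg$k,
                   cfg = agg$cfg), class = "aggregates"),
    peaks), "at least 10")
})

test_that("null correlations stay small across aggregate pairs", {
  set.seed(78)
  n_agg <- 100
  acc <- matrix(stats::rpois(n_agg * 20, 10), n_agg, 20)
  colnames(acc) <- paste0("p", 1:20)
  agg <- structure(list(condition = "young", access = acc,
                        expr = acc, members = as.list(1:n_agg), k = 1,
                        cfg = aggregate_config(k = 1)),
                   class = "aggregates")
  peaks <- data.frame(chrom = "chrS", start = (0:19) * 1e4,
                      end = (0:19) * 1e4 + 200, name = paste0("p", 1:20))
  sp <- coaccessibility_scores(agg, peaks, max_dist = 5e5)
  # positive-score halves of a null distribution: mostly below 0.3
  expect_gte(mean(sp$score < 0.3), 0.9)
})

test_that("planted linkages are recovered; nulls and far pairs are not", {
  sim <- simulate_multiome(multiome_sim_params(n_cells = 500, seed = 79))
  a1 <- make_aggregates(sim$cells, "young", seed = 80)
  a2 <- make_aggregates(sim$cells, "aged", seed = 81)
  p2g <- peak_to_gene(a1, a2, sim$cells$peaks, sim$cells$genes)
  lt <- sim$truth$links
  ret <- p2g$linkages[p2g$linkages$retained, ]
  keys <- function(d, pk, gn) paste(d[[pk]], d[[gn]])
  shared <- lt[lt$condition == "both" & lt$rho > 0 & !lt$far, ]
  expect_gte(mean(keys(shared, "peak_name", "gene_name") %in%
                    keys(ret, "peak", "gene")), 0.9)
  nulls <- lt[lt$rho == 0, ]
  expect_lte(sum(keys(nulls, "peak_name", "gene_name") %in%
                   keys(ret, "peak", "gene")), 1)
  far <- lt[lt$far, ]
  expect_false(any(keys(far, "peak_name", "gene_name") %in%
                     keys(p2g$linkages, "peak", "gene")))
  expect_true(all(p2g$linkages$distance <= 5e5))
})

test_that("aggregate-level correlation tracks the latent-factor oracle", {
  sim <- simulate_multiome(multiome_sim_params(n_cells = 500, seed = 82))
  a1 <- make_aggregates(sim$cells, "young", seed = 83)
  a2 <- make_aggregates(sim$cells, "aged", seed = 84)
  p2g <- peak_to_gene(a1, a2, sim$cells$peaks, sim$cells$genes)
  # oracle: correlation of the planted latent logits/log-rates aggregated
  # over the same member cells
  cell_idx <- stats::setNames(seq_len(nrow(sim$cells$cells)),
                              sim$cells$cells$cell)
  members <- c(a1$members, a2$members)
  lt <- sim$truth$links
  shared <- lt[lt$condition == "both" & lt$rho > 0 & !lt$far, ][1:5, ]
  for (r in seq_len(nrow(shared))) {
    u <- sim$truth$latent_u[, shared$peak[r]]
    v <- sim$truth$latent_v[, shared$gene[r]]
    agg_u <- vapply(members, function(m) mean(u[cell_idx[m]]), numeric(1))
    agg_v <- vapply(members, function(m) mean(v[cell_idx[m]]), numeric(1))
    oracle <- stats::cor(agg_u, agg_v)
    got <- p2g$linkages$correlation[p2g$linkages$peak ==
                                      shared$peak_name[r] &
                                      p2g$linkages$gene ==
                                      shared$gene_name[r]]
    expect_lt(abs(got - oracle), 0.1)
  }
})

test_that("linkage inference is invariant to scaling and aggregate order", {
  sim <- sim_small(seed = 85)
  a1 <- make_aggregates(sim$cells, "young", aggregate_config(k = 20),
                        seed = 86)
  a2 <- make_aggregates(sim$cells, "aged", aggregate_config(k = 20),
                        seed = 87)
  base <- peak_to_gene(a1, a2, sim$cells$peaks, sim$cells$genes)

  a1s <- a1; a1s$access <- a1$access * 7
  a2s <- a2; a2s$access <- a2$access * 7
  scaled <- peak_to_gene(a1s, a2s, sim$cells$peaks, sim$cells$genes)
  expect_equal(scaled$linkages$correlation, base$linkages$correlation,
               tolerance = 1e-12)
  expect_identical(scaled$linkages$retained, base$linkages$retained)

  perm <- sample(nrow(a1$access))
  a1p <- a1
  a1p$access <- a1$access[perm, ]; a1p$expr <- a1$expr[perm, ]
  a1p$members <- a1$members[perm]
  permuted <- peak_to_gene(a1p, a2, sim$cells$peaks, sim$cells$genes)
  expect_equal(permuted$linkages$correlation, base$linkages$correlation,
               tolerance = 1e-12)
})

test_that("linkage clustering is seeded, co-clusters duplicates, recovers planting", {
  # construct five orthogonal aggregate profiles directly
  n_agg <- 40
  set.seed(88)
  centers <- diag(5)[rep(1:5, each = 8), ]
  prof <- centers[, rep(1:5, length.out = n_agg)] * 4 +
    matrix(stats::rnorm(40 * n_agg, 0, 0.1), 40, n_agg)
  linkages <- data.frame(peak = paste0("p", 1:40),
                         gene = paste0("g", 1:40),
                         chrom = "chrS", peak_start = 1:40 * 1e3,
                         peak_end = 1:40 * 1e3 + 200, tss = 1:40 * 1e3,
                         distance = 0, correlation = 0.9, pvalue = 0,
                         fdr = 0, retained = TRUE)
  p2g <- structure(list(linkages = linkages,
                        profiles = list(access = prof, expr = prof,
                                        condition = rep("young", n_agg)),
                        conditions = c("young", "aged"),
                        cfg = linkage_config()),
                   class = "peak_to_gene")
  cl <- cluster_linkages(p2g, n_clusters = 5, seed = 89)
  expect_gte(adjusted_rand(cl$cluster, rep(1:5, each = 8)), 0.9)
  cl2 <- cluster_linkages(p2g, n_clusters = 5, seed = 89)
  expect_identical(cl$cluster, cl2$cluster)
  # duplicate rows co-cluster
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_error(cluster_linkages(p2g, n_clusters = 50), "fewer retained")
})

test_that("per-gene co-accessible fractions average as specified", {
  linkages <- data.frame(
    peak = c("p1", "p2", "p3", "q1", "q2"),
    gene = c("g1", "g1", "g1", "g2", "g2"),
    chrom = "chrS",
    peak_start = c(1e3, 2e3, 3e3, 10e3, 11e3),
    peak_end = c(1e3, 2e3, 3e3, 10e3, 11e3) + 200,
    retained = TRUE)
  mkpair <- function(s1, s2) data.frame(chrom = "chrS", start1 = s1,
                                        end1 = s1 + 200, start2 = s2,
                                        end2 = s2 + 200, score = 0.5)
  # all 3 pairs of g1 peaks co-accessible; 0 of 1 pair for g2 -> mean 0.5
  pairs3 <- rbind(mkpair(1e3, 2e3), mkpair(1e3, 3e3), mkpair(2e3, 3e3))
  expect_equal(linkage_coaccess_fraction(linkages[1:3, ],
                                         pairs3)$mean_fraction, 1.0)
  none <- mkpair(5e4, 6e4)
  expect_equal(linkage_coaccess_fraction(linkages[4:5, ],
                                         none)$mean_fraction, 0.0)
  res <- linkage_coaccess_fraction(linkages, pairs3)
  expect_equal(res$mean_fraction, 0.5)
  solo <- linkages[1, ]
  expect_message(r0 <- linkage_coaccess_fraction(solo, pairs3),
                 "no gene")
  expect_true(is.na(r0$mean_fraction))
})
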