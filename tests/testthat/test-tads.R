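unit_balanced <- function(m, resolution = 40000) {
  map <- map_from_dense(m, resolution = resolution)
  map$weights <- list(chrT = rep(1, nrow(m)))
  map$normalized <- TRUE
  map
}

test_that("separation score matches a brute-force diamond-mean oracle", {
  set.seed(31)
  n <- 40
  a <- matrix(stats::runif(n * n, 1, 4), n, n)
  a <- (a + t(a)) / 2
  map <- unit_balanced(a)
  tr <- tad_separation_score(map, window_sizes = c(3, 5))
  oracle <- naive_separation_score(a, c(3, 5))
  expect_equal(tr$score$chrT, oracle, tolerance = 1e-10)
})

test_that("uniform matrices have flat scores and produce no boundaries", {
  m <- matrix(2, 30, 30)
  tr <- tad_separation_score(unit_balanced(m), window_sizes = c(3, 5))
  sc <- tr$score$chrT
  expect_true(all(is.na(sc) | abs(sc) < 1e-12))
  expect_message(b <- find_boundaries(tr), "no boundar")
  expect_equal(nrow(b), 0)
  expect_error(tad_separation_score(unit_balanced(m),
                                    window_sizes = 20),
               "exceeds")
})

test_that("a two-block matrix yields its shared border as the single boundary", {
  n <- 40; k <- 20
  m <- matrix(0.2, n, n)
  m[1:k, 1:k] <- 2
  m[(k + 1):n, (k + 1):n] <- 2
  map <- unit_balanced(m)
  tr <- tad_separation_score(map, window_sizes = c(3, 5))
  expect_equal(which.min(tr$score$chrT) - 1L, k)
  b <- find_boundaries(tr, fdr = 0.05)
  expect_equal(b$bin, k)
  dom <- assemble_domains(b, map$grid)
  expect_equal(nrow(dom), 2)
  expect_equal(dom$start_bin, c(0L, k))
  expect_equal(dom$end_bin, c(k, n))
})

test_that("planted boundaries are recovered and the FDR cut is monotone", {
  sim <- simulate_contact_map(hic_sim_params(c_comp = 1, c_loop = 1,
                                             c_tad = 3, depth = 1e6,
                                             seed = 33))
  map <- kr_balance(sim$map)
  tr <- tad_separation_score(map)
  b <- find_boundaries(tr, fdr = 0.01)
  rec <- boundary_recovery(b$bin, sim$truth$boundaries)
  expect_gte(rec$recall, 0.9)
  expect_gte(rec$precision, 0.9)
  counts <- vapply(c(1e-8, 1e-4, 0.01, 0.1), function(f)
    nrow(suppressMessages(find_boundaries(tr, fdr = f))), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("boundary matching labels stable/lost/gained with a leftmost tie rule", {
  mk <- function(bins) data.frame(chrom = "chrT",
                                  start = bins * 4e4,
                                  end = (bins + 1) * 4e4, bin = bins)
  same <- match_boundaries(mk(c(10, 20, 30)), mk(c(10, 20, 30)), 1)
  expect_true(all(same$b1$stability == "stable"))
  expect_true(all(same$b2$stability == "stable"))

  far <- match_boundaries(mk(c(10, 20)), mk(c(50, 60)), 1)
  expect_true(all(far$b1$stability == "lost"))
  expect_true(all(far$b2$stability == "gained"))

  # two condition-1 boundaries equidistant from one aged boundary
  tie <- match_boundaries(mk(c(9, 11)), mk(10), 1)
  expect_equal(tie$b1$stability, c("stable", "lost"))
  expect_equal(tie$b2$stability, "stable")
})

test_that("rearrangement classes follow the component taxonomy", {
  mk <- function(s, e) data.frame(chrom = "chrT", start = s, end = e)
  a <- mk(c(0, 100, 200) * 1e3, c(100, 200, 300) * 1e3)
  self <- classify_rearrangements(a, a, resolution = 4e4)
  expect_true(all(self$tads1$class == "stable"))

  young <- mk(0, 100e3)
  aged <- mk(c(0, 60e3), c(60e3, 100e3))
  expect_equal(classify_rearrangements(young, aged,
                                       resolution = 4e4)$tads1$class,
               "split")
  rev <- classify_rearrangements(aged, young, resolution = 4e4)
  expect_true(all(rev$tads1$class == "merge"))

  # 2 <-> 2 entangled component (one young TAD bridges both aged TADs)
  y3 <- mk(c(0, 50e3), c(50e3, 100e3))
  a3 <- mk(c(0, 30e3), c(30e3, 100e3))
  cls <- classify_rearrangements(y3, a3, resolution = 4e4)
  expect_true(all(cls$tads1$class == "indeterminate"))
  expect_true(all(cls$tads2$class == "indeterminate"))

  shift <- classify_rearrangements(mk(0, 100e3), mk(80e3, 180e3),
                                   tol_bins = 1, resolution = 4e4)
  expect_equal(shift$tads1$class, "shift")

  overl <- mk(c(0, 50e3), c(80e3, 120e3))
  expect_error(classify_rearrangements(overl, a, resolution = 4e4),
               "overlapping")
})

test_that("rearrangement classification is symmetric up to label exchange", {
  set.seed(35)
  mkrand <- function(edges) data.frame(chrom = "chrT",
                                       start = head(edges, -1),
                                       end = edges[-1])
  e1 <- cumsum(c(0, sample(3:8, 10, TRUE))) * 4e4
  e2 <- cumsum(c(0, sample(3:8, 9, TRUE))) * 4e4
  f <- classify_rearrangements(mkrand(e1), mkrand(e2), resolution = 4e4)
  r <- classify_rearrangements(mkrand(e2), mkrand(e1), resolution = 4e4)
  # count components via their single-TAD side: splits of (1 -> 2) are
  # merges of (2 -> 1) and vice versa
  expect_equal(sum(f$tads1$class == "split"),
               sum(r$tads2$class == "merge"))
  expect_equal(sum(f$tads2$class == "merge"),
               sum(r$tads1$class == "split"))
  expect_equal(sum(f$tads1$class == "stable"),
               sum(r$tads1$class == "stable"))
})

test_that("intra-TAD connectivity equals the hand-counted toy and scales correctly", {
  n <- 6
  m <- matrix(1, n, n)
  m[1:3, 1:3] <- 4
  m[4:6, 4:6] <- 4
  map <- map_from_dense(m)
  tads <- data.frame(chrom = "chrT", start = c(0, 3) * 4e4,
                     end = c(3, 6) * 4e4)
  cr <- intra_tad_connectivity(map, tads)
  # 6 intra pixels of 4 -> mean 4; 9 inter pixels of 1 -> sum 9
  expect_equal(cr$connectivity, c(4 / 9, 4 / 9))

  cr10 <- intra_tad_connectivity(map_from_dense(10 * m), tads)
  expect_equal(cr10$connectivity, cr$connectivity)

  # raising intra counts with flanks fixed strictly increases connectivity
  m2 <- m; m2[1:3, 1:3] <- 8
  cr2 <- intra_tad_connectivity(map_from_dense(m2), tads)
  expect_gt(cr2$connectivity[1], cr$connectivity[1])

  m0 <- m; m0[1:3, 4:6] <- 0; m0[4:6, 1:3] <- 0
  cr0 <- intra_tad_connectivity(map_from_dense(m0), tads)
  expect_true(all(is.na(cr0$connectivity)))

  cm <- intra_tad_connectivity(map, tads, inter_mode = "mean")
  expect_equal(cm$connectivity, c(4, 4))
})

test_that("degree of disorder matches brute-force nearest-neighbor means", {
  # one 2x2 cluster of spiked pixels inside a 6-bin TAD
  n <- 30
  m <- matrix(5, n, n)
  hot <- rbind(c(2, 4), c(2, 5), c(3, 4), c(3, 5))
  for (r in seq_len(nrow(hot))) {
    m[hot[r, 1], hot[r, 2]] <- 500
    m[hot[r, 2], hot[r, 1]] <- 500
  }
  map <- unit_balanced(m, resolution = 10000)
  tad <- data.frame(chrom = "chrT", start = 0, end = 6 * 1e4)
  res <- degree_of_disorder(map, tad, dod_config(k = 3, top = 0.85))
  expect_equal(res$n_significant, 4)
  expect_equal(res$dod, (1 + 1 + sqrt(2)) / 3, tolerance = 1e-10)

  # same pixels split into two clusters far apart -> strictly larger DoD
  n2 <- 40
  m2 <- matrix(5, n2, n2)
  hot2 <- rbind(c(2, 4), c(2, 5), c(30, 32), c(30, 33))
  for (r in seq_len(nrow(hot2))) {
    m2[hot2[r, 1], hot2[r, 2]] <- 500
    m2[hot2[r, 2], hot2[r, 1]] <- 500
  }
  map2 <- unit_balanced(m2, resolution = 10000)
  tad2 <- data.frame(chrom = "chrT", start = 0, end = 40 * 1e4)
  res2 <- degree_of_disorder(map2, tad2, dod_config(k = 3, top = 0.996))
  expect_equal(res2$n_significant, 4)
  expect_gt(res2$dod, res$dod)

  # brute-force oracle on a random map
  set.seed(37)
  a <- matrix(stats::runif(900, 1, 10), 30, 30)
  a <- (a + t(a)) / 2
  mapr <- unit_balanced(a, resolution = 10000)
  tadr <- data.frame(chrom = "chrT", start = 0, end = 30 * 1e4)
  got <- degree_of_disorder(mapr, tadr, dod_config(k = 3, top = 0.7))
  prof <- expected_by_distance(mapr)
  oe <- observed_over_expected(mapr, prof)$chrT
  ut <- which(upper.tri(oe, diag = TRUE) & !is.na(oe), arr.ind = TRUE)
  vals <- oe[ut]
  sig <- ut[vals >= stats::quantile(vals, 0.7), , drop = FALSE]
  knn <- vapply(seq_len(nrow(sig)), function(i) {
    d <- sqrt(rowSums((sig - matrix(sig[i, ], nrow(sig), 2,
                                    byrow = TRUE))^2))
    mean(sort(d[-i])[1:3])
  }, numeric(1))
  expect_equal(got$dod, mean(knn), tolerance = 1e-10)
})

test_that("too few significant pixels yields NA disorder", {
  m <- matrix(5, 10, 10)
  m[2, 3] <- m[3, 2] <- 500
  map <- unit_balanced(m, resolution = 10000)
  tad <- data.frame(chrom = "chrT", start = 0, end = 4e4)
  res <- degree_of_disorder(map, tad, dod_config(k = 3, top = 0.95))
  expect_true(is.na(res$dod))
})
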