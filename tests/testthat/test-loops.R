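single_res_cfg <- function(res = 40000, fdr = 0.1, p = 2, w = 5,
                           min_dist = 80000, merge = 40000)
  loop_config(resolutions = res, loop_fdr = fdr, peak_widths = p,
              windows = w, min_dists = min_dist, merge_dists = merge)

test_that("no loops are called on a pure-decay null", {
  false_calls <- 0
  for (r in 1:5) {
    sim <- simulate_contact_map(
      hic_sim_params(n_bins = 200, c_comp = 1, c_tad = 1, c_loop = 1,
                     comp_blocks = c(100, 100), tad_boundaries = 100,
                     depth = 4e5, seed = 40 + r))
    lc <- call_loops(kr_balance(sim$map), single_res_cfg())
    false_calls <- false_calls + nrow(lc$loops)
  }
  expect_lte(false_calls / 5, 0.1 * 1)   # far below the BH-allowed budget
})

test_that("a planted focal peak is recovered at exactly its pixel", {
  sim <- simulate_contact_map(
    hic_sim_params(n_bins = 150, c_comp = 1, c_tad = 1, c_loop = 10,
                   comp_blocks = 150, tad_boundaries = integer(),
                   loops = data.frame(bin1 = 40L, bin2 = 80L),
                   depth = 8e5, seed = 47))
  lc <- call_loops(kr_balance(sim$map), single_res_cfg())
  expect_equal(nrow(lc$loops), 1)
  expect_lte(abs(lc$loops$bin1 - 40), 1)
  expect_lte(abs(lc$loops$bin2 - 80), 1)
  expect_true(lc$loops$qvalue < 0.1)
})

test_that("pixels inside the minimum diagonal distance are never tested", {
  sim <- simulate_contact_map(
    hic_sim_params(n_bins = 150, c_comp = 1, c_tad = 1, c_loop = 10,
                   comp_blocks = 150, tad_boundaries = integer(),
                   loops = data.frame(bin1 = 60L, bin2 = 61L),
                   depth = 8e5, seed = 48))
  lc <- call_loops(kr_balance(sim$map),
                   single_res_cfg(min_dist = 200000))
  expect_false(any(abs(lc$loops$bin1 - 60) <= 1 &
                     abs(lc$loops$bin2 - 61) <= 1))
})

test_that("calling requires a map at each configured resolution", {
  sim <- simulate_contact_map(hic_sim_params(n_bins = 100, depth = 2e5,
                                             seed = 49))
  expect_error(call_loops(kr_balance(sim$map),
                          single_res_cfg(res = 10000)),
               "resolution 10000")
})

test_that("cross-resolution merge prefers the finest call", {
  # the same genomic loop at 20 kb and 40 kb: merged list keeps the 20 kb
  # call and drops the coarse duplicate; a second coarse-only loop stays
  spike <- function(n, res, pixels) {
    m <- matrix(0, n, n)
    d <- abs(row(m) - col(m))
    m[] <- rpois(n * n, 20 / (1 + d))
    m <- (m + t(m))
    for (r in seq_len(nrow(pixels))) {
      m[pixels[r, 1], pixels[r, 2]] <- m[pixels[r, 1], pixels[r, 2]] + 200
      m[pixels[r, 2], pixels[r, 1]] <- m[pixels[r, 1], pixels[r, 2]]
    }
    map_from_dense(m, resolution = res, chrom = "chrT")
  }
  set.seed(50)
  fine <- kr_balance(spike(200, 20000, rbind(c(50, 150))),
                     min_nnz_frac = 0)
  coarse <- kr_balance(spike(100, 40000, rbind(c(25, 75), c(10, 60))),
                       min_nnz_frac = 0)
  cfg <- loop_config(resolutions = c(20000, 40000),
                     loop_fdr = c(0.1, 0.1), peak_widths = c(2, 2),
                     windows = c(5, 5), min_dists = c(80000, 80000),
                     merge_dists = c(40000, 40000))
  lc <- call_loops(list(fine, coarse), cfg)
  mid1 <- (lc$loops$start1 + lc$loops$end1) / 2
  at_dup <- abs(mid1 - 49 * 20000) <= 60000
  expect_true(any(at_dup & lc$loops$resolution == 20000))
  expect_false(any(at_dup & lc$loops$resolution == 40000))
  expect_true(any(lc$loops$resolution == 40000))   # coarse-only loop kept
})

test_that("APA scores flat maps at 1 and planted loops above 1", {
  flat <- matrix(50, 80, 80)
  mapf <- map_from_dense(flat)
  mapf$weights <- list(chrT = rep(1, 80))
  mapf$normalized <- TRUE
  loops <- data.frame(chrom = "chrT", start1 = 10 * 4e4, end1 = 11 * 4e4,
                      start2 = 60 * 4e4, end2 = 61 * 4e4)
  res <- apa(mapf, loops, W = 5)
  expect_equal(res$score, 1, tolerance = 1e-12)
  expect_equal(mean(res$matrix), 1, tolerance = 1e-12)

  sim <- simulate_contact_map(hic_sim_params(c_comp = 1, c_loop = 6,
                                             depth = 1e6, seed = 52))
  map <- kr_balance(sim$map)
  tl <- sim$truth$loops
  planted <- data.frame(chrom = "chrS", start1 = tl$bin1 * 4e4,
                        end1 = (tl$bin1 + 1) * 4e4,
                        start2 = tl$bin2 * 4e4,
                        end2 = (tl$bin2 + 1) * 4e4)
  expect_gt(apa(map, planted, W = 10)$score, 1)
  expect_error(apa(mapf, loops[0, ], W = 5), "no loops eligible")
})

test_that("loop/TAD classification covers the three classes and fractions", {
  tads <- data.frame(chrom = "chrT", start = c(0, 4e5, 8e5),
                     end = c(4e5, 8e5, 12e5))
  mk <- function(s1, s2) data.frame(chrom = "chrT", start1 = s1,
                                    end1 = s1 + 4e4, start2 = s2,
                                    end2 = s2 + 4e4)
  within <- classify_loops_vs_tads(mk(4e4, 2e5), tads)
  expect_equal(within$class, "within-TAD")
  cross <- classify_loops_vs_tads(mk(1e5, 6e5), tads)
  expect_equal(cross$class, "cross-TAD")
  banch <- classify_loops_vs_tads(mk(3.8e5, 8.2e5), tads)
  expect_equal(banch$class, "boundary-anchored")

  toy <- do.call(rbind, c(replicate(9, mk(4e4, 2e5), simplify = FALSE),
                          list(mk(1e5, 6e5))))
  fr <- attr(classify_loops_vs_tads(toy, tads), "fractions")
  expect_equal(unname(fr["within-TAD"]), 0.9)
})

test_that("loop matching is one-to-one with stable/lost/gained labels", {
  mk <- function(s1, s2) data.frame(chrom = "chrT", start1 = s1,
                                    end1 = s1 + 4e4, start2 = s2,
                                    end2 = s2 + 4e4)
  a <- rbind(mk(1e5, 5e5), mk(2e5, 9e5))
  same <- match_loops(a, a, tol = 4e4)
  expect_true(all(same$l1$stability == "stable"))
  expect_equal(nrow(same$matches), 2)

  far <- match_loops(a, rbind(mk(3e6, 40e5)), tol = 4e4)
  expect_true(all(far$l1$stability == "lost"))
  expect_true(all(far$l2$stability == "gained"))

  # one anchor matches, the other is off by more than tol -> no match
  off <- match_loops(mk(1e5, 5e5), mk(1e5, 7e5), tol = 4e4)
  expect_equal(off$l1$stability, "lost")
})
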