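#' Parameters for the synthetic Hi-C generator
#'
#' The generative model is multiplicative over structural features: the
#' expected count at pixel `(i, j)` is
#' `Z * (1 + |i - j|)^-alpha * c_comp^[same compartment] *
#'  c_tad^[same TAD] * c_loop^[within a loop peak]`,
#' with `Z` set so the expected total over the upper triangle equals
#' `depth`, and observed counts drawn Poisson. Defaults describe a single
#' 20 Mb synthetic chromosome at 40 kb (500 bins) with 10 alternating
#' compartment blocks, 10 TADs whose interior boundaries deliberately do not
#' coincide with compartment block edges, and 20 single-pixel loops placed
#' inside TADs.
#'
#' @param n_bins number of bins on the synthetic chromosome.
#' @param resolution bin size (bp).
#' @param chrom chromosome name.
#' @param alpha power-law distance-decay exponent (contact probability
#'   proportional to `(1 + d)^-alpha`, `d` in bins).
#' @param comp_blocks integer vector of compartment block lengths in bins,
#'   alternating A, B, A, ... and summing to `n_bins`.
#' @param c_comp multiplicative enrichment for same-compartment pairs (>= 1).
#' @param c_tad multiplicative enrichment for same-TAD pairs (>= 1).
#' @param c_loop focal amplification at loop pixels (>= 1).
#' @param tad_boundaries interior TAD boundary bin indices (0-based); TADs
#'   tile the chromosome between consecutive boundaries.
#' @param loops data.frame with 0-based pixel columns `bin1 < bin2`, or
#'   `NULL` for the default placement of 2 loops per TAD.
#' @param w_peak odd loop-peak width in pixels (amplified square is
#'   `w_peak x w_peak` centered on each loop pixel).
#' @param depth expected total read count over the upper triangle.
#' @param seed RNG seed.
#' @return A list of class `hic_sim_params`.
#' @export
hic_sim_params <- function(n_bins = 500, resolution = 40000, chrom = "chrS",
                           alpha = 1, comp_blocks = NULL,
                           c_comp = 1.5, c_tad = 3, c_loop = 6,
                           tad_boundaries = NULL,
                           loops = NULL, w_peak = 1, depth = 1e6,
                           seed = 1L) {
  if (is.null(comp_blocks)) {
    # 10 alternating blocks spanning the chromosome
    comp_blocks <- diff(round(seq(0, n_bins, length.out = 11)))
  }
  if (is.null(tad_boundaries)) {
    # 10 TADs; interior boundaries deliberately off the compartment edges
    tad_boundaries <- round(n_bins *
                              c(45, 85, 140, 190, 250, 290, 340, 395,
                                440) / 500)
    tad_boundaries <- tad_boundaries[tad_boundaries > 0 &
                                       tad_boundaries < n_bins]
  }
  stopifnot(sum(comp_blocks) == n_bins,
            c_comp >= 1, c_tad >= 1, c_loop >= 1,
            w_peak >= 1, w_peak %% 2 == 1)
  tad_boundaries <- sort(unique(as.integer(tad_boundaries)))
  if (length(tad_boundaries) &&
      (min(tad_boundaries) <= 0 || max(tad_boundaries) >= n_bins))
    stop("tad_boundaries must be interior bins")
  edges <- c(0L, tad_boundaries, n_bins)
  tads <- data.frame(start_bin = edges[-length(edges)],
                     end_bin = edges[-1])
  if (is.null(loops)) {
    loops <- do.call(rbind, lapply(seq_len(nrow(tads)), function(t) {
      a <- tads$start_bin[t]; s <- tads$end_bin[t] - a
      data.frame(bin1 = c(a + floor(s / 5), a + 2L),
                 bin2 = c(a + floor(4 * s / 5), a + 2L + floor(s / 2)))
    }))
  }
  if (any(loops$bin1 >= loops$bin2) || any(loops$bin1 < 0) ||
      any(loops$bin2 >= n_bins))
    stop("loop pixels must satisfy 0 <= bin1 < bin2 < n_bins")
  structure(list(n_bins = as.integer(n_bins), resolution = resolution,
                 chrom = chrom, alpha = alpha, comp_blocks = comp_blocks,
                 c_comp = c_comp, c_tad = c_tad, c_loop = c_loop,
                 tads = tads, loops = loops, w_peak = as.integer(w_peak),
                 depth = depth, seed = as.integer(seed)),
            class = "hic_sim_params")
}

# per-bin compartment labels "A"/"B" from alternating block lengths
comp_labels <- function(comp_blocks) {
  rep(rep(c("A", "B"), length.out = length(comp_blocks)), comp_blocks)
}

# expected count matrix (upper-triangle semantics but returned dense
# symmetric), before Poisson sampling; Z scales total to depth
hic_lambda <- function(params) {
  n <- params$n_bins
  d <- abs(row(diag(n)) - col(diag(n)))
  lam <- (1 + d)^(-params$alpha)
  lab <- comp_labels(params$comp_blocks)
  same_comp <- outer(lab, lab, "==")
  lam <- lam * ifelse(same_comp, params$c_comp, 1)
  tad_id <- rep(NA_integer_, n)
  for (t in seq_len(nrow(params$tads)))
    tad_id[(params$tads$start_bin[t] + 1):params$tads$end_bin[t]] <- t
  same_tad <- outer(tad_id, tad_id, "==")
  same_tad[is.na(same_tad)] <- FALSE
  lam <- lam * ifelse(same_tad, params$c_tad, 1)
  if (nrow(params$loops) && params$c_loop > 1) {
    h <- (params$w_peak - 1L) %/% 2L
    loop_mask <- matrix(FALSE, n, n)
    for (l in seq_len(nrow(params$loops))) {
      ri <- pmax(1L, params$loops$bin1[l] + 1L - h):
        pmin(n, params$loops$bin1[l] + 1L + h)
      cj <- pmax(1L, params$loops$bin2[l] + 1L - h):
        pmin(n, params$loops$bin2[l] + 1L + h)
      loop_mask[ri, cj] <- TRUE
      loop_mask[cj, ri] <- TRUE
    }
    lam <- lam * ifelse(loop_mask, params$c_loop, 1)
  }
  ut_total <- sum(lam[upper.tri(lam, diag = TRUE)])
  lam * params$depth / ut_total
}

#' Simulate a two-level structured Hi-C contact map with planted truth
#'
#' Draws Poisson counts around a power-law distance decay modulated by
#' planted compartment blocks, TADs, and focal loop pixels (see
#' [hic_sim_params()]), and emits the planted ground truth alongside a
#' GC-content track in which A bins have higher GC than B bins (so
#' compartment-sign orientation is testable).
#'
#' @param params a [hic_sim_params()].
#' @return A list with elements `map` (raw [contact_map()]), `truth`
#'   (planted labels, TAD/boundary/loop positions, expected-count matrix
#'   scale), `gc` (a [signal_track()]), and `params`.
#' @export
simulate_contact_map <- function(params) {
  stopifnot(inherits(params, "hic_sim_params"))
  n <- params$n_bins
  lam <- hic_lambda(params)
  if (mean(lam[cbind(seq_len(n - 1), seq_len(n - 1) + 1)]) < 1)
    warning("depth too low to expect one count per first-diagonal pixel")
  asm <- genome_assembly(params$chrom, n * params$resolution)
  grid <- bin_grid(asm, params$resolution)
  lab <- comp_labels(params$comp_blocks)
  res <- withr::with_seed(params$seed, {
    ut <- which(upper.tri(lam, diag = TRUE), arr.ind = TRUE)
    counts <- stats::rpois(nrow(ut), lam[ut])
    gc <- 0.40 + 0.06 * (lab == "A") + stats::rnorm(n, 0, 0.005)
    list(ut = ut, counts = counts, gc = gc)
  })
  keep <- res$counts > 0
  m <- Matrix::sparseMatrix(i = res$ut[keep, 1], j = res$ut[keep, 2],
                            x = res$counts[keep], dims = c(n, n))
  map <- contact_map(grid, stats::setNames(list(m), params$chrom))
  tads_bp <- data.frame(chrom = params$chrom,
                        start = params$tads$start_bin * params$resolution,
                        end = params$tads$end_bin * params$resolution,
                        start_bin = params$tads$start_bin,
                        end_bin = params$tads$end_bin)
  bnd <- setdiff(unique(c(params$tads$start_bin, params$tads$end_bin)),
                 c(0L, n))
  truth <- list(compartments = lab, tads = tads_bp,
                boundaries = sort(bnd), loops = params$loops,
                lambda_scale = lam[1, 1])
  gc_track <- signal_track(grid,
                           stats::setNames(list(res$gc), params$chrom))
  list(map = map, truth = truth, gc = gc_track, params = params)
}

#' Simulate scored site pairs with controlled TAD placement
#'
#' Generates `n_within` pairs with both sites inside a single TAD and
#' `n_between` pairs straddling different TADs; pair distances are drawn
#' uniformly so the downstream 25 kb distance bins are populated. Sites are
#' 200 bp intervals. TADs shorter than `min_dist` are skipped for
#' within-TAD placement (with a message).
#'
#' @param tads data.frame with columns chrom, start, end (non-overlapping).
#' @param n_within,n_between number of pairs of each placement class.
#' @param score_fun function(n) drawing co-accessibility scores.
#' @param min_dist minimum intra-pair distance (bp).
#' @param condition condition label attached to the pairs.
#' @param seed RNG seed.
#' @return data.frame of site pairs (chrom, start1, end1, start2, end2,
#'   score, condition, planted) where `planted` is `"within"`/`"between"`.
#' @export
simulate_site_pairs <- function(tads, n_within, n_between,
                                score_fun = function(n)
                                  stats::runif(n, 0.1, 0.9),
                                min_dist = 1000, condition = "young",
                                seed = 1L) {
  validate_intervals(tads, "TAD")
  usable <- tads[tads$end - tads$start > min_dist + 400, , drop = FALSE]
  if (nrow(usable) < nrow(tads))
    message(nrow(tads) - nrow(usable),
            " TAD(s) shorter than the minimum pair distance were skipped")
  if (n_within > 0 && nrow(usable) == 0)
    stop("no TAD is long enough for within-TAD pairs")
  withr::with_seed(seed, {
    rows <- list()
    if (n_within > 0) {
      t_idx <- sample(nrow(usable), n_within, replace = TRUE,
                      prob = usable$end - usable$start)
      s1 <- numeric(n_within); s2 <- numeric(n_within)
      for (p in seq_len(n_within)) {
        a <- usable$start[t_idx[p]]; b <- usable$end[t_idx[p]]
        x <- stats::runif(1, a, b - min_dist - 400)
        y <- stats::runif(1, x + min_dist, b - 400)
        s1[p] <- floor(x); s2[p] <- floor(y)
      }
      rows$within <- data.frame(chrom = usable$chrom[t_idx], start1 = s1,
                                end1 = s1 + 200, start2 = s2,
                                end2 = s2 + 200, planted = "within")
    }
    if (n_between > 0) {
      if (nrow(tads) < 2) stop("need >= 2 TADs for between-TAD pairs")
      s1 <- numeric(n_between); s2 <- numeric(n_between)
      chv <- character(n_between)
      for (p in seq_len(n_between)) {
        ts <- sort(sample(nrow(tads), 2))
        x <- stats::runif(1, tads$start[ts[1]], tads$end[ts[1]] - 400)
        y <- stats::runif(1, tads$start[ts[2]], tads$end[ts[2]] - 400)
        s1[p] <- floor(x); s2[p] <- floor(y)
        chv[p] <- tads$chrom[ts[1]]
      }
      rows$between <- data.frame(chrom = chv, start1 = s1, end1 = s1 + 200,
                                 start2 = s2, end2 = s2 + 200,
                                 planted = "between")
    }
    out <- do.call(rbind, rows)
    swap <- out$start1 > out$start2
    if (any(swap)) {
      tmp <- out[swap, c("start1", "end1")]
      out[swap, c("start1", "end1")] <- out[swap, c("start2", "end2")]
      out[swap, c("start2", "end2")] <- tmp
    }
    out$score <- score_fun(nrow(out))
    out$condition <- condition
    rownames(out) <- NULL
    out
  })
}

#' Simulate TAD-indifferent scored site pairs
#'
#' Places pairs uniformly on a chromosome span with uniformly drawn
#' distances, ignoring any domain structure; the null reference case for
#' the within-TAD enrichment statistic.
#'
#' @param chrom chromosome name.
#' @param span_end chromosome span (bp) to place sites in.
#' @param n_pairs number of pairs.
#' @param max_dist,min_dist distance range (bp).
#' @inheritParams simulate_site_pairs
#' @return data.frame of site pairs as in [simulate_site_pairs()].
#' @export
simulate_random_pairs <- function(chrom, span_end, n_pairs,
                                  min_dist = 1000, max_dist = 1e6,
                                  score_fun = function(n)
                                    stats::runif(n, 0.1, 0.9),
                                  condition = "young", seed = 1L) {
  withr::with_seed(seed, {
    d <- stats::runif(n_pairs, min_dist, max_dist)
    s1 <- floor(stats::runif(n_pairs, 0, span_end - d - 400))
    s2 <- floor(s1 + d)
    data.frame(chrom = chrom, start1 = s1, end1 = s1 + 200,
               start2 = s2, end2 = s2 + 200, planted = "random",
               score = score_fun(n_pairs), condition = condition)
  })
}
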