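# integral-image rectangle sums: S[a2+1, b2+1] - ... with clipping
make_integral <- function(m) {
  n <- nrow(m)
  s <- matrix(0, n + 1, n + 1)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  s
}

rect_sum <- function(S, a1, a2, b1, b2) {
  n <- nrow(S) - 1L
  a1 <- pmax(a1, 1L); b1 <- pmax(b1, 1L)
  a2 <- pmin(a2, n); b2 <- pmin(b2, n)
  bad <- a1 > a2 | b1 > b2
  a1 <- pmin(a1, n); b1 <- pmin(b1, n)
  a2 <- pmax(a2, 1L); b2 <- pmax(b2, 1L)
  v <- S[cbind(a2 + 1L, b2 + 1L)] - S[cbind(a1, b2 + 1L)] -
    S[cbind(a2 + 1L, b1)] + S[cbind(a1, b1)]
  v[bad] <- 0
  v
}

# donut / horizontal / vertical / lower-left neighborhood sums for pixel
# vectors (i, j) (1-based) given integral image S, peak p, window w
nbhd_sums <- function(S, i, j, p, w) {
  box_w <- rect_sum(S, i - w, i + w, j - w, j + w)
  box_p <- rect_sum(S, i - p, i + p, j - p, j + p)
  row_l <- rect_sum(S, i, i, j - w, j - p - 1L)
  row_r <- rect_sum(S, i, i, j + p + 1L, j + w)
  col_u <- rect_sum(S, i - w, i - p - 1L, j, j)
  col_d <- rect_sum(S, i + p + 1L, i + w, j, j)
  donut <- box_w - box_p - row_l - row_r - col_u - col_d
  horiz <- rect_sum(S, i - 1L, i + 1L, j - w, j - p - 1L) +
    rect_sum(S, i - 1L, i + 1L, j + p + 1L, j + w)
  vert <- rect_sum(S, i - w, i - p - 1L, j - 1L, j + 1L) +
    rect_sum(S, i + p + 1L, i + w, j - 1L, j + 1L)
  ll <- rect_sum(S, i + 1L, i + w, j - w, j - 1L) -
    rect_sum(S, i + 1L, i + p, j - p, j - 1L)
  list(donut = donut, horiz = horiz, vert = vert, ll = ll)
}

# donut-filter pixel tests + clustering at one resolution
call_loops_at <- function(map, fdr, p, w, min_dist_bp, thresholds) {
  profile <- expected_by_distance(map)
  res <- map$grid$resolution
  out <- list()
  for (ch in cm_chroms(map)) {
    C <- cm_dense(map, ch)
    n <- nrow(C)
    wt <- map$weights[[ch]]
    d <- abs(row(C) - col(C))
    pr <- profile$profile[[ch]][d + 1]
    E <- matrix(pr, n, n) / outer(wt, wt)
    valid <- is.finite(E) & E > 0
    C0 <- C; C0[!valid] <- 0
    E0 <- E; E0[!valid] <- 0
    SC <- make_integral(C0)
    SE <- make_integral(E0)
    min_db <- floor(min_dist_bp / res)
    cand <- which(valid & d > min_db & col(C) > row(C) & C > E,
                  arr.ind = TRUE)
    if (!nrow(cand)) next
    i <- cand[, 1]; j <- cand[, 2]
    nC <- nbhd_sums(SC, i, j, p, w)
    nE <- nbhd_sums(SE, i, j, p, w)
    eij <- E[cand]
    est <- function(nc, ne) ifelse(ne > 0, eij * nc / ne, NA_real_)
    exp4 <- cbind(donut = est(nC$donut, nE$donut),
                  horiz = est(nC$horiz, nE$horiz),
                  vert = est(nC$vert, nE$vert),
                  ll = est(nC$ll, nE$ll))
    expected <- apply(exp4, 1, max, na.rm = TRUE)
    ok <- is.finite(expected) & expected > 0
    pv <- rep(NA_real_, length(expected))
    pv[ok] <- stats::ppois(C[cand][ok] - 1, expected[ok],
                           lower.tail = FALSE)
    keep <- !is.na(pv)
    out[[ch]] <- data.frame(chrom = ch, i = i[keep], j = j[keep],
                            obs = C[cand][keep],
                            exp_donut = exp4[keep, "donut"],
                            exp_horiz = exp4[keep, "horiz"],
                            exp_vert = exp4[keep, "vert"],
                            exp_ll = exp4[keep, "ll"],
                            expected = expected[keep], pvalue = pv[keep])
  }
  tests <- do.call(rbind, out)
  empty <- data.frame(chrom = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(),
                      end2 = numeric(), bin1 = integer(), bin2 = integer(),
                      obs = numeric(), expected = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      cluster_size = integer(), resolution = numeric())
  if (is.null(tests) || !nrow(tests))
    return(list(loops = empty, n_tested = 0L))
  tests$qvalue <- stats::p.adjust(tests$pvalue, "BH")
  sig <- tests[tests$qvalue < fdr, , drop = FALSE]
  if (!nrow(sig)) return(list(loops = empty, n_tested = nrow(tests)))
  loops <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    # 8-connectivity clusters of significant pixels
    adj <- which(outer(s$i, s$i, function(a, b) abs(a - b) <= 1) &
                   outer(s$j, s$j, function(a, b) abs(a - b) <= 1),
                 arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(cbind(adj[, 1], adj[, 2]),
                                     directed = FALSE)
    memb <- igraph::components(g)$membership[seq_len(nrow(s))]
    for (cl in unique(memb)) {
      rows <- s[memb == cl, , drop = FALSE]
      best <- rows[which.max(rows$obs), ]
      ci <- as.integer(round(mean(rows$i)))
      cj <- as.integer(round(mean(rows$j)))
      loops[[length(loops) + 1L]] <- data.frame(
        chrom = ch, bin1 = ci - 1L, bin2 = cj - 1L,
        obs = best$obs, exp_donut = best$exp_donut,
        exp_horiz = best$exp_horiz, exp_vert = best$exp_vert,
        exp_ll = best$exp_ll, expected = best$expected,
        pvalue = best$pvalue, qvalue = best$qvalue,
        cluster_size = nrow(rows))
    }
  }
  loops <- do.call(rbind, loops)
  # post-hoc enrichment-ratio filters (q cap; stripe, donut, lower-left)
  rat <- function(e) ifelse(is.na(e) | e <= 0, Inf, loops$obs / e)
  pass <- loops$qvalue <= thresholds[1] &
    rat(loops$exp_horiz) >= thresholds[2] &
    rat(loops$exp_vert) >= thresholds[2] &
    rat(loops$exp_donut) >= thresholds[3] &
    rat(loops$exp_ll) >= thresholds[4]
  loops <- loops[pass, , drop = FALSE]
  if (!nrow(loops)) return(list(loops = empty, n_tested = nrow(tests)))
  loops$start1 <- loops$bin1 * res
  loops$end1 <- (loops$bin1 + 1) * res
  loops$start2 <- loops$bin2 * res
  loops$end2 <- (loops$bin2 + 1) * res
  loops$resolution <- res
  loops <- loops[order(loops$chrom, loops$bin1, loops$bin2), ]
  rownames(loops) <- NULL
  list(loops = loops, n_tested = nrow(tests))
}

#' Call focal chromatin loops with donut-filter local expectations
#'
#' For each resolution, every candidate pixel (upper triangle, beyond the
#' minimum diagonal distance, observed above its distance-decay
#' expectation) is tested against the maximum of four local background
#' estimators — donut annulus, horizontal and vertical stripes, and the
#' lower-left quadrant — each formed by scaling the pixel's distance-decay
#' expectation by the neighborhood observed/expected ratio. P-values are
#' Poisson upper tails, adjusted by Benjamini-Hochberg over all tested
#' pixels; significant pixels are clustered by 8-connectivity and each
#' cluster reports its centroid pixel. Post-hoc enrichment filters
#' (`cfg$thresholds`) and a cross-resolution merge preferring the finest
#' resolution produce the final list.
#'
#' @param maps a balanced [contact_map()] or list of balanced maps covering
#'   `cfg$resolutions` (matched by grid resolution).
#' @param cfg a [loop_config()].
#' @return A list of class `loop_call`: `loops` (merged data.frame with
#'   anchors, observed/expected statistics and q-values), `per_resolution`
#'   (named list of per-resolution calls), and `n_tested` per resolution.
#' @export
call_loops <- function(maps, cfg = loop_config()) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  res_avail <- vapply(maps, function(m) m$grid$resolution, numeric(1))
  per_res <- list()
  n_tested <- stats::setNames(integer(length(cfg$resolutions)),
                              as.character(cfg$resolutions))
  for (ri in seq_along(cfg$resolutions)) {
    r <- cfg$resolutions[ri]
    mi <- which(res_avail == r)
    if (!length(mi))
      stop("no contact map supplied at resolution ", r)
    m <- maps[[mi[1]]]
    if (!m$normalized) stop("maps must be balanced first (kr_balance)")
    cl <- call_loops_at(m, fdr = cfg$loop_fdr[ri],
                        p = cfg$peak_widths[ri], w = cfg$windows[ri],
                        min_dist_bp = cfg$min_dists[ri],
                        thresholds = cfg$thresholds)
    per_res[[as.character(r)]] <- cl$loops
    n_tested[ri] <- cl$n_tested
  }
  # merge finest -> coarsest; a coarser loop is dropped when a kept loop
  # has both anchor midpoints within the coarser resolution's merge radius
  ord <- order(cfg$resolutions)
  merged <- NULL
  for (ri in ord) {
    r <- cfg$resolutions[ri]
    cand <- per_res[[as.character(r)]]
    if (!nrow(cand)) next
    if (is.null(merged)) {
      merged <- cand
      next
    }
    md <- cfg$merge_dists[ri]
    keep <- vapply(seq_len(nrow(cand)), function(k) {
      same <- merged$chrom == cand$chrom[k]
      if (!any(same)) return(TRUE)
      m1 <- (merged$start1[same] + merged$end1[same]) / 2
      m2 <- (merged$start2[same] + merged$end2[same]) / 2
      c1 <- (cand$start1[k] + cand$end1[k]) / 2
      c2 <- (cand$start2[k] + cand$end2[k]) / 2
      !any(abs(m1 - c1) <= md & abs(m2 - c2) <= md)
    }, logical(1))
    merged <- rbind(merged, cand[keep, , drop = FALSE])
  }
  if (is.null(merged)) merged <- per_res[[1]][0, ]
  merged <- merged[order(merged$chrom, merged$start1, merged$start2), ]
  rownames(merged) <- NULL
  structure(list(loops = merged, per_resolution = per_res,
                 n_tested = n_tested),
            class = "loop_call")
}

#' @export
print.loop_call <- function(x, ...) {
  cat("<loop_call> ", nrow(x$loops), " merged loops (",
      paste(sprintf("%s bp: %d", names(x$per_resolution),
                    vapply(x$per_resolution, nrow, integer(1))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Aggregate peak analysis
#'
#' Extracts the `(2W+1) x (2W+1)` observed/expected submatrix centered on
#' each loop pixel, normalizes each submatrix to mean 1, averages them
#' element-wise, and scores the aggregate as the central pixel over the
#' mean of the 6x6 lower-left corner block.
#'
#' @param map a balanced [contact_map()].
#' @param loops data.frame with columns chrom, start1, end1, start2, end2.
#' @param W window half-width in bins (21 x 21 window by default).
#' @return A list of class `apa_result` with the aggregate `matrix`,
#'   `score`, and `n_loops` used.
#' @export
apa <- function(map, loops, W = 10) {
  profile <- expected_by_distance(map)
  oe <- observed_over_expected(map, profile)
  res <- map$grid$resolution
  agg <- matrix(0, 2 * W + 1, 2 * W + 1)
  used <- 0L
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom[k]
    if (!ch %in% cm_chroms(map)) next
    n <- map$grid$n_bins[[ch]]
    i <- floor((loops$start1[k] + loops$end1[k]) / 2 / res) + 1L
    j <- floor((loops$start2[k] + loops$end2[k]) / 2 / res) + 1L
    if (j - i <= 2 * W + 1) next                   # too close to diagonal
    if (i - W < 1 || j + W > n || i + W >= j - W) next
    sub <- oe[[ch]][(i - W):(i + W), (j - W):(j + W)]
    mu <- mean(sub, na.rm = TRUE)
    if (!is.finite(mu) || mu <= 0) next
    sub <- sub / mu
    sub[is.na(sub)] <- 1
    agg <- agg + sub
    used <- used + 1L
  }
  if (used == 0L) stop("no loops eligible for APA at this window size")
  agg <- agg / used
  side <- 2 * W + 1
  corner <- agg[(side - 5):side, 1:6]
  structure(list(matrix = agg, score = agg[W + 1, W + 1] / mean(corner),
                 n_loops = used, W = W),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat("<apa_result> ", x$n_loops, " loops, APA score ",
      round(x$score, 3), "\n", sep = "")
  invisible(x)
}

#' Classify loops against TADs and boundaries
#'
#' A loop is within-TAD when both anchor midpoints fall in one TAD;
#' otherwise boundary-anchored when an anchor midpoint lies within
#' `tol_bins` of a boundary bin; otherwise cross-TAD.
#'
#' @param loops loop data.frame (chrom, start1, end1, start2, end2).
#' @param tads non-overlapping domains (chrom, start, end).
#' @param boundaries optional boundary set (chrom, start, end); defaults to
#'   the interior TAD edges.
#' @param tol_bins boundary tolerance in bins.
#' @param resolution bin size (bp).
#' @return The loops with a `class` column plus a `fractions` attribute
#'   (named per-class fractions).
#' @export
classify_loops_vs_tads <- function(loops, tads, boundaries = NULL,
                                   tol_bins = 1, resolution = 40000) {
  if (is.null(boundaries)) {
    b <- list()
    for (ch in unique(tads$chrom)) {
      d <- tads[tads$chrom == ch, ]
      edges <- sort(intersect(d$start, d$end))
      if (length(edges))
        b[[ch]] <- data.frame(chrom = ch, start = edges,
                              end = edges + resolution)
    }
    boundaries <- do.call(rbind, b)
  }
  tol <- tol_bins * resolution
  cls <- character(nrow(loops))
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom[k]
    m1 <- (loops$start1[k] + loops$end1[k]) / 2
    m2 <- (loops$start2[k] + loops$end2[k]) / 2
    td <- tads[tads$chrom == ch, ]
    t1 <- which(td$start <= m1 & m1 < td$end)
    t2 <- which(td$start <= m2 & m2 < td$end)
    if (length(t1) == 1 && length(t2) == 1 && t1 == t2) {
      cls[k] <- "within-TAD"
      next
    }
    bn <- boundaries[!is.null(boundaries) & boundaries$chrom == ch, ]
    near <- nrow(bn) && (any(abs(bn$start - m1) <= tol + resolution / 2) ||
                           any(abs(bn$start - m2) <= tol + resolution / 2))
    cls[k] <- if (isTRUE(near)) "boundary-anchored" else "cross-TAD"
  }
  loops$class <- cls
  lv <- c("within-TAD", "cross-TAD", "boundary-anchored")
  attr(loops, "fractions") <-
    table(factor(cls, lv)) / max(1L, length(cls))
  loops
}

#' Match loops across conditions into stable / lost / gained
#'
#' Loops match when both anchor midpoints agree within `tol` bp; matching
#' is greedy mutual-nearest (increasing total anchor offset) and
#' one-to-one.
#'
#' @param l1,l2 loop data.frames for the two conditions.
#' @param tol anchor tolerance in bp.
#' @return A list with `l1`, `l2` (inputs plus `stability`) and `matches`.
#' @export
match_loops <- function(l1, l2, tol = 40000) {
  s1 <- rep("lost", nrow(l1)); s2 <- rep("gained", nrow(l2))
  matches <- data.frame(i1 = integer(), i2 = integer(), dist = numeric())
  mid <- function(l, a) (l[[paste0("start", a)]] + l[[paste0("end", a)]]) / 2
  for (ch in union(unique(l1$chrom), unique(l2$chrom))) {
    i1 <- which(l1$chrom == ch); i2 <- which(l2$chrom == ch)
    if (!length(i1) || !length(i2)) next
    d1 <- abs(outer(mid(l1, 1)[i1], mid(l2, 1)[i2], "-"))
    d2 <- abs(outer(mid(l1, 2)[i1], mid(l2, 2)[i2], "-"))
    tot <- d1 + d2
    cand <- which(d1 <= tol & d2 <= tol, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(tot[cand], cand[, 1], cand[, 2])
    used1 <- logical(length(i1)); used2 <- logical(length(i2))
    for (r in ord) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (used1[a] || used2[b]) next
      used1[a] <- used2[b] <- TRUE
      s1[i1[a]] <- "stable"; s2[i2[b]] <- "stable"
      matches <- rbind(matches, data.frame(i1 = i1[a], i2 = i2[b],
                                           dist = tot[a, b]))
    }
  }
  l1$stability <- s1; l2$stability <- s2
  list(l1 = l1, l2 = l2, matches = matches)
}
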