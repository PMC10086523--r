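#' TAD separation score and boundary significance
#'
#' For each window size `w` and bin `i`, the diamond mean is the mean
#' balanced value over pixels `{(a, b): i - w <= a < i <= b < i + w}`; the
#' per-window means are z-scored along each chromosome and averaged across
#' window sizes into the separation score. Each bin also gets a one-sided
#' rank-sum p-value comparing its pooled diamond pixels against the pooled
#' diamond pixels at `i - w` and `i + w` (low contacts across `i` relative
#' to its flanks mark a boundary).
#'
#' @param map a balanced [contact_map()] (conventionally at 40 kb).
#' @param window_sizes window sizes in bins.
#' @return An object of class `separation_track` with per-chromosome
#'   `score` and `pvalue` vectors (NA where undefined).
#' @export
tad_separation_score <- function(map, window_sizes = c(4, 6, 8, 10)) {
  if (!map$normalized) stop("map must be balanced first (kr_balance)")
  score <- list(); pvalue <- list()
  for (ch in cm_chroms(map)) {
    b <- balanced_dense(map, ch)
    n <- nrow(b)
    if (max(window_sizes) * 2 > n)
      stop("window size exceeds chromosome ", ch)
    zmat <- matrix(NA_real_, n, length(window_sizes))
    diamonds <- vector("list", n)  # pooled pixel values across windows
    for (wi in seq_along(window_sizes)) {
      w <- window_sizes[wi]
      dm <- rep(NA_real_, n)
      for (i in w:(n - w)) {      # 0-based bin i; 1-based row/col below
        px <- b[(i - w + 1):i, (i + 1):(i + w)]
        px <- px[!is.na(px)]
        if (length(px)) {
          dm[i + 1] <- mean(px)
          diamonds[[i + 1]] <- c(diamonds[[i + 1]], px)
        }
      }
      mu <- mean(dm, na.rm = TRUE); sg <- stats::sd(dm, na.rm = TRUE)
      if (is.finite(sg) && sg > 0) zmat[, wi] <- (dm - mu) / sg
    }
    sc <- rowMeans(zmat, na.rm = TRUE)
    sc[is.nan(sc)] <- NA_real_
    pv <- rep(NA_real_, n)
    for (i in which(!is.na(sc))) {
      x <- diamonds[[i]]
      y <- unlist(lapply(window_sizes, function(w) {
        c(if (i - w >= 1) diamonds[[i - w]],
          if (i + w <= n) diamonds[[i + w]])
      }))
      if (length(x) >= 3 && length(y) >= 3) {
        pv[i] <- suppressWarnings(
          stats::wilcox.test(x, y, alternative = "less",
                             exact = FALSE)$p.value)
      }
    }
    score[[ch]] <- sc
    pvalue[[ch]] <- pv
  }
  structure(list(grid = map$grid, score = score, pvalue = pvalue,
                 window_sizes = window_sizes),
            class = "separation_track")
}

#' Boundaries from a separation track
#'
#' Boundaries are local minima of the separation score whose BH-adjusted
#' rank-sum p-value (adjusted over all candidate minima genome-wide) is
#' below `fdr` and whose score sits at least `delta` below both flanking
#' maxima (the score maxima between this minimum and the neighboring
#' minima or chromosome ends).
#'
#' @param track a [tad_separation_score()] result.
#' @param fdr BH-adjusted p-value threshold.
#' @param delta minimum score drop versus both flanking maxima.
#' @return data.frame (chrom, start, end, bin, score, pvalue, qvalue),
#'   class `boundary_set`; zero rows when nothing passes.
#' @export
find_boundaries <- function(track, fdr = 0.01, delta = 0.01) {
  cand <- list()
  for (ch in names(track$score)) {
    s <- track$score[[ch]]
    n <- length(s)
    left <- c(NA, s[-n]); right <- c(s[-1], NA)
    mins <- which(!is.na(s) & !is.na(left) & !is.na(right) &
                    s < left & s <= right)
    mins <- mins[!is.na(track$pvalue[[ch]][mins])]
    if (!length(mins)) next
    drops <- vapply(mins, function(i) {
      others <- setdiff(mins, i)
      lo <- max(c(1, others[others < i]))
      hi <- min(c(n, others[others > i]))
      lmax <- suppressWarnings(max(s[lo:i], na.rm = TRUE))
      rmax <- suppressWarnings(max(s[i:hi], na.rm = TRUE))
      min(lmax, rmax) - s[i]
    }, numeric(1))
    cand[[ch]] <- data.frame(chrom = ch, bin = mins - 1L,
                             score = s[mins],
                             pvalue = track$pvalue[[ch]][mins],
                             drop = drops)
  }
  cand <- do.call(rbind, cand)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), bin = integer(), score = numeric(),
                      pvalue = numeric(), qvalue = numeric())
  class(empty) <- c("boundary_set", "data.frame")
  if (is.null(cand) || !nrow(cand)) {
    message("no boundary candidates found")
    return(empty)
  }
  cand$qvalue <- stats::p.adjust(cand$pvalue, "BH")
  keep <- cand$qvalue < fdr & cand$drop >= delta
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) {
    message("no boundaries pass fdr ", fdr)
    return(empty)
  }
  iv <- do.call(rbind, lapply(seq_len(nrow(cand)), function(r)
    bin_interval(track$grid, cand$chrom[r], cand$bin[r])))
  out <- data.frame(chrom = cand$chrom, start = iv$start, end = iv$end,
                    bin = cand$bin, score = cand$score,
                    pvalue = cand$pvalue, qvalue = cand$qvalue)
  out <- out[order(out$chrom, out$bin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("boundary_set", "data.frame")
  out
}

#' Assemble domains by tiling between consecutive boundaries
#'
#' Domains span chromosome start -> boundary -> ... -> chromosome end;
#' spans shorter than `min_domain_bins` are dropped.
#'
#' @param boundaries a [find_boundaries()] result.
#' @param grid the [bin_grid()] boundaries were called on.
#' @param min_domain_bins minimum domain size in bins.
#' @return data.frame (chrom, start, end, start_bin, end_bin).
#' @export
assemble_domains <- function(boundaries, grid, min_domain_bins = 3) {
  out <- list()
  for (ch in grid_chroms(grid)) {
    n <- grid$n_bins[[ch]]
    bnd <- sort(boundaries$bin[boundaries$chrom == ch])
    edges <- unique(c(0L, bnd, n))
    d <- data.frame(chrom = ch, start_bin = edges[-length(edges)],
                    end_bin = edges[-1])
    d <- d[d$end_bin - d$start_bin >= min_domain_bins, , drop = FALSE]
    if (nrow(d)) {
      d$start <- d$start_bin * grid$resolution
      d$end <- pmin(d$end_bin * grid$resolution,
                    grid$assembly$chrom_lengths[[ch]])
      out[[ch]] <- d[, c("chrom", "start", "end", "start_bin", "end_bin")]
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(),
                                      start = numeric(), end = numeric(),
                                      start_bin = integer(),
                                      end_bin = integer())
  rownames(out) <- NULL
  out
}

#' Match boundaries across conditions into stable / lost / gained
#'
#' Greedy mutual-nearest matching within `tol_bins`: pairs are taken in
#' order of increasing distance (ties broken towards the leftmost boundary
#' of condition 1, then of condition 2) and each boundary is used at most
#' once. Matched boundaries are stable; unmatched condition-1 boundaries
#' are lost, unmatched condition-2 boundaries gained.
#'
#' @param b1,b2 [find_boundaries()] results for condition 1 (young) and
#'   condition 2 (aged) on the same grid.
#' @param tol_bins matching tolerance in bins.
#' @return A list with `b1` and `b2` (inputs plus a `stability` column) and
#'   `matches` (row indices into b1/b2 with the bin distance).
#' @export
match_boundaries <- function(b1, b2, tol_bins = 1) {
  s1 <- rep("lost", nrow(b1))
  s2 <- rep("gained", nrow(b2))
  matches <- data.frame(i1 = integer(), i2 = integer(), dist = integer())
  for (ch in union(unique(b1$chrom), unique(b2$chrom))) {
    i1 <- which(b1$chrom == ch); i2 <- which(b2$chrom == ch)
    if (!length(i1) || !length(i2)) next
    dd <- abs(outer(b1$bin[i1], b2$bin[i2], "-"))
    cand <- which(dd <= tol_bins, arr.ind = TRUE)
    if (!nrow(cand)) next
    ord <- order(dd[cand], b1$bin[i1][cand[, 1]], b2$bin[i2][cand[, 2]])
    used1 <- logical(length(i1)); used2 <- logical(length(i2))
    for (r in ord) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (used1[a] || used2[b]) next
      used1[a] <- used2[b] <- TRUE
      s1[i1[a]] <- "stable"; s2[i2[b]] <- "stable"
      matches <- rbind(matches,
                       data.frame(i1 = i1[a], i2 = i2[b],
                                  dist = dd[a, b]))
    }
  }
  b1$stability <- s1
  b2$stability <- s2
  list(b1 = b1, b2 = b2, matches = matches)
}

#' Classify TAD rearrangements between conditions
#'
#' Builds the overlap graph between the two domain sets (>= 1 bp overlap)
#' and classifies each connected component: one-to-one with both boundary
#' offsets within tolerance -> stable, one-to-one beyond tolerance ->
#' shift, one-to-many -> split, many-to-one -> merge, many-to-many (or a
#' domain with no partner) -> indeterminate.
#'
#' @param tads1,tads2 non-overlapping sorted domain data.frames
#'   (chrom, start, end) for the two conditions.
#' @param tol_bins boundary-offset tolerance in bins.
#' @param resolution bin size in bp (converts `tol_bins` to bp).
#' @return A list of class `rearrangement_report`: `tads1`/`tads2` with a
#'   `class` column and a `summary` count table.
#' @export
classify_rearrangements <- function(tads1, tads2, tol_bins = 1,
                                    resolution = 40000) {
  validate_intervals(tads1, "TAD"); validate_intervals(tads2, "TAD")
  check_no_overlap <- function(t) {
    for (ch in unique(t$chrom)) {
      d <- t[t$chrom == ch, ]
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop("overlapping TADs within one condition")
    }
  }
  check_no_overlap(tads1); check_no_overlap(tads2)
  tol <- tol_bins * resolution
  c1 <- rep("indeterminate", nrow(tads1))
  c2 <- rep("indeterminate", nrow(tads2))
  edges <- list()
  for (a in seq_len(nrow(tads1))) {
    hit <- which(tads2$chrom == tads1$chrom[a] &
                   tads2$start < tads1$end[a] &
                   tads2$end > tads1$start[a])
    if (length(hit))
      edges[[length(edges) + 1L]] <- data.frame(a = a, b = hit)
  }
  edges <- do.call(rbind, edges)
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_edgelist(
      cbind(paste0("Y", edges$a), paste0("O", edges$b)), directed = FALSE)
    comp <- igraph::components(g)
    for (cp in seq_len(comp$no)) {
      vs <- names(comp$membership)[comp$membership == cp]
      ia <- as.integer(sub("Y", "", vs[startsWith(vs, "Y")]))
      ib <- as.integer(sub("O", "", vs[startsWith(vs, "O")]))
      cls <- if (length(ia) == 1 && length(ib) == 1) {
        if (abs(tads1$start[ia] - tads2$start[ib]) <= tol &&
            abs(tads1$end[ia] - tads2$end[ib]) <= tol) "stable" else "shift"
      } else if (length(ia) == 1 && length(ib) > 1) "split"
      else if (length(ia) > 1 && length(ib) == 1) "merge"
      else "indeterminate"
      c1[ia] <- cls; c2[ib] <- cls
    }
  }
  tads1$class <- c1; tads2$class <- c2
  lv <- c("stable", "shift", "split", "merge", "indeterminate")
  structure(list(tads1 = tads1, tads2 = tads2,
                 summary = rbind(cond1 = table(factor(c1, lv)),
                                 cond2 = table(factor(c2, lv)))),
            class = "rearrangement_report")
}

tad_bins <- function(tads, grid) {
  if (all(c("start_bin", "end_bin") %in% names(tads))) return(tads)
  tads$start_bin <- as.integer(tads$start / grid$resolution)
  tads$end_bin <- as.integer(ceiling(tads$end / grid$resolution))
  tads
}

#' Intra-TAD connectivity
#'
#' For each TAD, the mean raw count per intra-TAD pixel (upper-triangle
#' pixels including the diagonal) divided by the raw counts of all
#' cis-interactions with the immediately flanking TADs. With
#' `inter_mode = "sum"` (default) the denominator is the summed flanking
#' inter-TAD count; with `"mean"` it is the mean count per inter-TAD pixel.
#' First/last TADs use their single flank; a zero denominator yields `NA`.
#'
#' @param map a raw [contact_map()].
#' @param tads sorted non-overlapping domains (chrom, start, end).
#' @param inter_mode `"sum"` or `"mean"` denominator.
#' @return data.frame with per-TAD intra mean, flank sums and connectivity.
#' @export
intra_tad_connectivity <- function(map, tads,
                                   inter_mode = c("sum", "mean")) {
  inter_mode <- match.arg(inter_mode)
  tads <- tad_bins(tads, map$grid)
  out <- list()
  for (ch in unique(tads$chrom)) {
    m <- cm_dense(map, ch)
    d <- tads[tads$chrom == ch, ]
    d <- d[order(d$start_bin), ]
    nt <- nrow(d)
    for (t in seq_len(nt)) {
      rt <- (d$start_bin[t] + 1):d$end_bin[t]
      s <- length(rt)
      ut <- m[rt, rt, drop = FALSE]
      intra_sum <- (sum(ut) + sum(diag(ut))) / 2
      n_intra <- s * (s + 1) / 2
      inter_sum <- 0; n_inter <- 0
      for (fl in c(t - 1, t + 1)) {
        if (fl < 1 || fl > nt) next
        rf <- (d$start_bin[fl] + 1):d$end_bin[fl]
        inter_sum <- inter_sum + sum(m[rt, rf])
        n_inter <- n_inter + s * length(rf)
      }
      denom <- if (inter_mode == "sum") inter_sum
               else if (n_inter > 0) inter_sum / n_inter else 0
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = d$start[t], end = d$end[t],
        intra_mean = intra_sum / n_intra, inter_sum = inter_sum,
        connectivity = if (denom > 0) (intra_sum / n_intra) / denom
                       else NA_real_)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Degree of disorder within TADs
#'
#' Significant contacts are the pixels inside a TAD whose O/E value is at
#' or above the `top` empirical quantile of that TAD's pixels; the degree
#' of disorder is the mean, over significant pixels, of the mean Euclidean
#' distance (in bin units) to each pixel's `k` nearest other significant
#' pixels. Fewer than `k + 1` significant pixels yields `NA`.
#'
#' @param map a balanced [contact_map()] (conventionally at 10 kb).
#' @param tads domains (chrom, start, end).
#' @param dod a [dod_config()]; only `k` and `top` drive the statistic
#'   (ww/pw/ratio/gap are accepted for interface compatibility).
#' @return data.frame with per-TAD pixel counts and `dod`.
#' @export
degree_of_disorder <- function(map, tads, dod = dod_config()) {
  if (!map$normalized) stop("map must be balanced first (kr_balance)")
  defaults <- dod_config()
  extras <- c("ww", "pw", "ratio", "gap")
  if (!identical(dod[extras], defaults[extras]))
    message("DoD parameters ww/pw/ratio/gap are accepted but unused")
  profile <- expected_by_distance(map)
  oe <- observed_over_expected(map, profile)
  tads <- tad_bins(tads, map$grid)
  res <- lapply(seq_len(nrow(tads)), function(t) {
    ch <- tads$chrom[t]
    rt <- (tads$start_bin[t] + 1):tads$end_bin[t]
    sub <- oe[[ch]][rt, rt, drop = FALSE]
    ut <- which(upper.tri(sub, diag = TRUE) & !is.na(sub), arr.ind = TRUE)
    vals <- sub[ut]
    n_sig <- 0L; dd <- NA_real_
    if (length(vals) >= 2) {
      thr <- stats::quantile(vals, dod$top, names = FALSE)
      sig <- ut[vals >= thr, , drop = FALSE]
      n_sig <- nrow(sig)
      if (n_sig >= dod$k + 1) {
        dm <- as.matrix(stats::dist(sig))
        diag(dm) <- Inf
        knn_mean <- apply(dm, 1, function(r)
          mean(sort(r)[seq_len(dod$k)]))
        dd <- mean(knn_mean)
      }
    }
    data.frame(chrom = ch, start = tads$start[t], end = tads$end[t],
               n_pixels = length(vals), n_significant = n_sig, dod = dd)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
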