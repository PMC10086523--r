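site_names <- function(pairs) {
  list(s1 = paste0(pairs$chrom, ":", pairs$start1, "-", pairs$end1),
       s2 = paste0(pairs$chrom, ":", pairs$start2, "-", pairs$end2))
}

#' Detect cis-co-accessibility networks (CCANs)
#'
#' Builds a graph over sites with an edge wherever the co-accessibility
#' score is at or above `cutoff`, runs Louvain community detection under a
#' fixed seed (vertices are sorted by name first, so the result is
#' invariant to input pair order), and keeps communities with at least
#' `min_size` member sites.
#'
#' @param pairs site-pair data.frame (chrom, start1, end1, start2, end2,
#'   score) from one condition.
#' @param cutoff minimum score defining an edge.
#' @param min_size minimum sites per CCAN.
#' @param seed RNG seed for the community detection.
#' @return data.frame (ccan, site, chrom, start, end), class `ccan_set`;
#'   zero rows when the graph is empty.
#' @export
detect_ccans <- function(pairs, cutoff = 0.1, min_size = 3, seed = 1L) {
  empty <- data.frame(ccan = integer(), site = character(),
                      chrom = character(), start = numeric(),
                      end = numeric())
  class(empty) <- c("ccan_set", "data.frame")
  keep <- pairs$score >= cutoff
  if (!any(keep)) return(empty)
  p <- pairs[keep, , drop = FALSE]
  nm <- site_names(p)
  verts <- sort(unique(c(nm$s1, nm$s2)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = nm$s1, to = nm$s2, weight = pmax(p$score, 1e-9)),
    directed = FALSE, vertices = verts)
  g <- igraph::simplify(g, edge.attr.comb = "max")
  memb <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = 1)$membership)
  df <- data.frame(site = verts, comm = memb)
  sizes <- table(df$comm)
  df <- df[df$comm %in% names(sizes)[sizes >= min_size], , drop = FALSE]
  if (!nrow(df)) return(empty)
  # renumber CCANs deterministically by leftmost member site
  parts <- do.call(rbind, strsplit(sub("-", ":", df$site), ":"))
  df$chrom <- parts[, 1]
  df$start <- as.numeric(parts[, 2])
  df$end <- as.numeric(parts[, 3])
  first <- stats::aggregate(start ~ comm, df, min)
  ord <- order(first$start, first$comm)
  remap <- stats::setNames(seq_along(ord), first$comm[ord])
  df$ccan <- as.integer(remap[as.character(df$comm)])
  out <- df[order(df$ccan, df$start), c("ccan", "site", "chrom", "start",
                                        "end")]
  rownames(out) <- NULL
  class(out) <- c("ccan_set", "data.frame")
  out
}

#' Select the co-accessibility cutoff maximizing the joint CCAN count
#'
#' Returns the candidate cutoff maximizing (number of CCANs in condition 1)
#' + (number in condition 2); ties go to the smallest cutoff.
#'
#' @param pairs1,pairs2 site pairs per condition.
#' @param candidate_cutoffs cutoffs to evaluate.
#' @param min_size minimum CCAN size.
#' @param seed seed passed to [detect_ccans()].
#' @return The selected cutoff (scalar).
#' @export
select_ccan_cutoff <- function(pairs1, pairs2,
                               candidate_cutoffs = seq(0.05, 0.5, 0.05),
                               min_size = 3, seed = 1L) {
  candidate_cutoffs <- sort(candidate_cutoffs)
  counts <- vapply(candidate_cutoffs, function(ct) {
    n1 <- length(unique(detect_ccans(pairs1, ct, min_size, seed)$ccan))
    n2 <- length(unique(detect_ccans(pairs2, ct, min_size, seed)$ccan))
    n1 + n2
  }, numeric(1))
  candidate_cutoffs[which.max(counts)]   # ties -> first = smallest
}

#' Match CCANs across conditions by maximum-weight bipartite matching
#'
#' Edge weight between a condition-1 and a condition-2 CCAN is the number
#' of shared member sites; zero-weight edges are excluded and the matching
#' maximizes total shared sites, one-to-one. Shared fraction per match is
#' Jaccard (`|intersection| / |union|`); set `shared_mode = "mean"` for the
#' per-side mean fraction instead.
#'
#' @param ccans1,ccans2 [detect_ccans()] results over a comparable site
#'   universe.
#' @param shared_mode `"jaccard"` (default) or `"mean"`.
#' @return data.frame (ccan1, ccan2, shared, fraction) with attribute
#'   `total_weight`.
#' @export
match_ccans <- function(ccans1, ccans2,
                        shared_mode = c("jaccard", "mean")) {
  shared_mode <- match.arg(shared_mode)
  m1 <- split(ccans1$site, ccans1$ccan)
  m2 <- split(ccans2$site, ccans2$ccan)
  empty <- data.frame(ccan1 = integer(), ccan2 = integer(),
                      shared = integer(), fraction = numeric())
  attr(empty, "total_weight") <- 0
  if (!length(m1) || !length(m2)) return(empty)
  W <- outer(seq_along(m1), seq_along(m2),
             Vectorize(function(a, b) length(intersect(m1[[a]], m2[[b]]))))
  edges <- which(W > 0, arr.ind = TRUE)
  if (!nrow(edges)) return(empty)
  n1 <- length(m1); n2 <- length(m2)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, n1), rep(TRUE, n2)),
                                    as.vector(t(cbind(edges[, 1],
                                                      n1 + edges[, 2]))))
  res <- igraph::max_bipartite_match(g, weights = W[edges])
  mt <- res$matching[seq_len(n1)]
  out <- list()
  for (a in which(!is.na(mt))) {
    b <- mt[a] - n1
    shared <- W[a, b]
    frac <- if (shared_mode == "jaccard")
      shared / length(union(m1[[a]], m2[[b]]))
    else mean(c(shared / length(m1[[a]]), shared / length(m2[[b]])))
    out[[length(out) + 1L]] <- data.frame(
      ccan1 = as.integer(names(m1)[a]), ccan2 = as.integer(names(m2)[b]),
      shared = shared, fraction = frac)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$ccan1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_weight") <- res$matching_weight
  out
}

#' Fraction of CCANs fully contained in single domains
#'
#' A CCAN is contained when every member-site midpoint lies within one
#' domain interval (TAD, or loop span from anchor1 start to anchor2 end).
#'
#' @param ccans a [detect_ccans()] result.
#' @param domains data.frame (chrom, start, end).
#' @return A list with the contained `fraction`, per-CCAN logical
#'   `contained`, and `n_ccans`.
#' @export
ccan_containment <- function(ccans, domains) {
  ids <- unique(ccans$ccan)
  if (!length(ids))
    return(list(fraction = NA_real_, contained = logical(), n_ccans = 0L))
  contained <- vapply(ids, function(cc) {
    mem <- ccans[ccans$ccan == cc, ]
    mid <- (mem$start + mem$end) / 2
    dom <- domains[domains$chrom == mem$chrom[1], , drop = FALSE]
    if (length(unique(mem$chrom)) > 1 || !nrow(dom)) return(FALSE)
    any(vapply(seq_len(nrow(dom)), function(r)
      all(mid >= dom$start[r] & mid < dom$end[r]), logical(1)))
  }, logical(1))
  list(fraction = mean(contained),
       contained = stats::setNames(contained, ids),
       n_ccans = length(ids))
}

#' Within-TAD enrichment of co-accessible pairs by distance bin
#'
#' Pairs are grouped by inter-site distance into `bin_kb` bins; per bin the
#' observed fold enrichment is (# pairs with both sites in one TAD) /
#' (# pairs spanning different TADs). The null randomly re-assigns links
#' among the bin's sites within each (distance bin, chromosome) stratum:
#' the pair offsets (signed site-to-site distances) are permuted across
#' the stratum's upstream anchors, so every null link starts at a real
#' site and the bin's distance distribution is retained exactly. The fold
#' enrichment is recomputed over `n_shuffles` permutations.
#'
#' @param pairs site-pair data.frame.
#' @param tads non-overlapping domains (chrom, start, end).
#' @param bin_kb distance bin width in kb.
#' @param n_shuffles number of null permutations.
#' @param seed RNG seed.
#' @param min_pairs bins with fewer pairs are flagged `low_n`.
#' @return data.frame per distance bin: pair counts, `fe_obs` (Inf when no
#'   cross-TAD pairs), null mean/quantiles, the empirical `percentile` of
#'   the observed value, and flags.
#' @export
tad_enrichment_by_distance <- function(pairs, tads, bin_kb = 25,
                                       n_shuffles = 500, seed = 1L,
                                       min_pairs = 5) {
  validate_loops(pairs)
  mid1 <- (pairs$start1 + pairs$end1) / 2
  mid2 <- (pairs$start2 + pairs$end2) / 2
  dist <- abs(mid2 - mid1)
  bin <- floor(dist / (bin_kb * 1000))
  tad_of <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      d <- tads[tads$chrom == ch, , drop = FALSE]
      if (!nrow(d)) next
      d <- d[order(d$start), ]
      sel <- chrom == ch
      idx <- findInterval(pos[sel], d$start)
      ok <- idx >= 1 & pos[sel] < d$end[pmax(idx, 1)]
      out[sel][ok] <- idx[ok]
    }
    out
  }
  fe_of <- function(t1, t2) {
    within <- sum(!is.na(t1) & !is.na(t2) & t1 == t2)
    cross <- sum(!is.na(t1) & !is.na(t2) & t1 != t2)
    c(within = within, cross = cross,
      fe = if (cross > 0) within / cross else Inf)
  }
  t1 <- tad_of(pairs$chrom, mid1)
  t2 <- tad_of(pairs$chrom, mid2)
  bins <- sort(unique(bin))
  withr::with_seed(seed, {
    out <- lapply(bins, function(b) {
      sel <- which(bin == b)
      obs <- fe_of(t1[sel], t2[sel])
      null_fe <- rep(NA_real_, n_shuffles)
      offs <- mid2[sel] - mid1[sel]
      for (s in seq_len(n_shuffles)) {
        nm2 <- numeric(length(sel))
        for (ch in unique(pairs$chrom[sel])) {
          cs <- which(pairs$chrom[sel] == ch)
          nm2[cs] <- mid1[sel[cs]] + offs[cs][sample(length(cs))]
        }
        null_fe[s] <- fe_of(t1[sel],
                            tad_of(pairs$chrom[sel], nm2))[["fe"]]
      }
      fin <- null_fe[is.finite(null_fe)]
      data.frame(
        bin_start = b * bin_kb * 1000, n_pairs = length(sel),
        n_within = obs[["within"]], n_cross = obs[["cross"]],
        fe_obs = obs[["fe"]],
        null_mean = if (length(fin)) mean(fin) else NA_real_,
        null_lo = if (length(fin)) unname(stats::quantile(fin, 0.025))
                  else NA_real_,
        null_hi = if (length(fin)) unname(stats::quantile(fin, 0.975))
                  else NA_real_,
        percentile = 100 * mean(null_fe <= obs[["fe"]], na.rm = TRUE),
        low_n = length(sel) < min_pairs,
        infinite = !is.finite(obs[["fe"]]))
    })
    do.call(rbind, out)
  })
}
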