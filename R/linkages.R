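#' Build condition-pure low-overlap cell aggregates
#'
#' Cells of one condition are embedded in the top principal directions of
#' the log-scaled accessibility matrix; aggregates are the `k` nearest
#' neighbors (including self) of randomly ordered seed cells, accepted
#' greedily while the running constraints hold: the median pairwise
#' shared-cell count stays at `max_median_shared` (0 by default) and the
#' mean pairwise shared fraction stays at or below `max_overlap`.
#'
#' @param cells a [cell_matrices()].
#' @param condition which condition to aggregate.
#' @param cfg an [aggregate_config()].
#' @param seed RNG seed (seed-cell order).
#' @return An object of class `aggregates`: member lists plus summed
#'   accessibility (aggregates x peaks) and expression (aggregates x
#'   genes) matrices.
#' @export
make_aggregates <- function(cells, condition, cfg = aggregate_config(),
                            seed = 1L) {
  stopifnot(inherits(cells, "cell_matrices"))
  if (!condition %in% cells$conditions)
    stop("unknown condition: ", condition)
  idx <- which(cells$cells$condition == condition)
  n <- length(idx)
  k <- cfg$k
  if (n < k) stop("condition ", condition, " has ", n,
                  " cells, fewer than k = ", k)
  acc <- as.matrix(cells$access[idx, , drop = FALSE])
  memb <- withr::with_seed(seed, {
    if (k == 1) {
      seeds <- sample(n, min(n, cfg$n_aggregates))
      lapply(seeds, identity)
    } else {
      x <- log1p(acc)
      keep <- which(apply(x, 2, stats::sd) > 0)
      emb <- if (length(keep) == 0) matrix(0, n, 1) else
        stats::prcomp(x[, keep, drop = FALSE], center = TRUE,
                      rank. = min(cfg$n_dims, length(keep), n - 1))$x
      order_seeds <- sample(n)
      accepted <- list()
      overlaps <- numeric()   # pairwise shared counts among accepted
      for (s in order_seeds) {
        if (length(accepted) >= cfg$n_aggregates) break
        d <- colSums((t(emb) - emb[s, ])^2)
        members <- order(d, seq_len(n))[seq_len(k)]
        new_shared <- vapply(accepted, function(a)
          length(intersect(a, members)), numeric(1))
        cand_overlaps <- c(overlaps, new_shared)
        if (length(accepted) == 0 ||
            (stats::median(cand_overlaps) <= cfg$max_median_shared &&
             mean(cand_overlaps / k) <= cfg$max_overlap)) {
          accepted[[length(accepted) + 1L]] <- members
          overlaps <- cand_overlaps
        }
      }
      accepted
    }
  })
  if (length(memb) < 2)
    stop("could not assemble two aggregates within the overlap ",
         "constraints (mean shared fraction reached ",
         round(mean(vapply(memb, length, 1)) / k, 3), ")")
  agg_acc <- do.call(rbind, lapply(memb, function(m)
    Matrix::colSums(cells$access[idx[m], , drop = FALSE])))
  agg_exp <- do.call(rbind, lapply(memb, function(m)
    Matrix::colSums(cells$expr[idx[m], , drop = FALSE])))
  rownames(agg_acc) <- rownames(agg_exp) <-
    sprintf("%s_agg_%03d", condition, seq_along(memb))
  structure(list(condition = condition,
                 members = lapply(memb, function(m)
                   cells$cells$cell[idx[m]]),
                 access = agg_acc, expr = agg_exp, k = k, cfg = cfg),
            class = "aggregates")
}

#' @export
print.aggregates <- function(x, ...) {
  cat("<aggregates> ", length(x$members), " aggregates of ", x$k,
      " cells (", x$condition, ")\n", sep = "")
  invisible(x)
}

# pairwise shared-cell statistics, used by tests and validation
aggregate_overlap_stats <- function(agg) {
  m <- agg$members
  if (length(m) < 2) return(list(median_shared = 0, mean_fraction = 0))
  shared <- utils::combn(length(m), 2, function(p)
    length(intersect(m[[p[1]]], m[[p[2]]])))
  list(median_shared = stats::median(shared),
       mean_fraction = mean(shared / agg$k))
}

#' Aggregate-level co-accessibility scores for nearby peak pairs
#'
#' For every same-chromosome peak pair whose centers lie within
#' `max_dist`, the score is the Pearson correlation of the two peaks'
#' aggregate accessibility vectors; non-positive scores are dropped and
#' zero-variance peaks skipped.
#'
#' @param agg an [aggregates()][make_aggregates()] result (or a list of
#'   them; aggregates are then pooled row-wise).
#' @param peaks the peak table (chrom, start, end, name) matching the
#'   accessibility columns.
#' @param max_dist maximum center-to-center distance (bp).
#' @return Site-pair data.frame (chrom, start1, end1, start2, end2, score,
#'   condition, peak1, peak2).
#' @export
coaccessibility_scores <- function(agg, peaks, max_dist = 500000) {
  if (inherits(agg, "aggregates")) agg <- list(agg)
  acc <- do.call(rbind, lapply(agg, `[[`, "access"))
  condition <- paste(unique(vapply(agg, `[[`, "", "condition")),
                     collapse = "+")
  if (nrow(acc) < 10) stop("need at least 10 aggregates")
  ctr <- (peaks$start + peaks$end) / 2
  sds <- apply(acc, 2, stats::sd)
  out <- list()
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    if (length(pk) < 2) next
    cmb <- utils::combn(pk, 2)
    d <- abs(ctr[cmb[2, ]] - ctr[cmb[1, ]])
    cmb <- cmb[, d <= max_dist, drop = FALSE]
    if (!ncol(cmb)) next
    ok <- sds[cmb[1, ]] > 0 & sds[cmb[2, ]] > 0
    cmb <- cmb[, ok, drop = FALSE]
    if (!ncol(cmb)) next
    sc <- vapply(seq_len(ncol(cmb)), function(q)
      stats::cor(acc[, cmb[1, q]], acc[, cmb[2, q]]), numeric(1))
    keep <- sc > 0
    if (!any(keep)) next
    cmb <- cmb[, keep, drop = FALSE]
    out[[ch]] <- data.frame(
      chrom = ch,
      start1 = peaks$start[cmb[1, ]], end1 = peaks$end[cmb[1, ]],
      start2 = peaks$start[cmb[2, ]], end2 = peaks$end[cmb[2, ]],
      score = sc[keep], condition = condition,
      peak1 = peaks$name[cmb[1, ]], peak2 = peaks$name[cmb[2, ]])
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(),
                                      start1 = numeric(), end1 = numeric(),
                                      start2 = numeric(), end2 = numeric(),
                                      score = numeric(),
                                      condition = character(),
                                      peak1 = character(),
                                      peak2 = character())
  rownames(out) <- NULL
  out
}

#' Aggregate-level peak-to-gene linkage inference
#'
#' Pools the two conditions' aggregates; expression is total-count scaled
#' per aggregate and log1p-transformed, accessibility enters as raw member
#' sums. Every peak-gene pair with `|TSS - peak center| <= max_dist` on
#' one chromosome is tested by Pearson correlation across the pooled
#' aggregates (p-value from the correlation t statistic, BH-adjusted over
#' all tested pairs); a linkage is retained when correlation exceeds
#' `cor_threshold` and FDR is below `fdr_threshold`.
#'
#' @param agg1,agg2 [make_aggregates()] results for the two conditions.
#' @param peaks peak table (chrom, start, end, name).
#' @param genes gene table (name, chrom, tss, strand).
#' @param cfg a [linkage_config()].
#' @return A list of class `peak_to_gene`: `linkages` (all tested pairs
#'   with correlation, pvalue, fdr, retained flag and per-condition means)
#'   and the per-aggregate `profiles` of retained linkages for clustering.
#' @export
peak_to_gene <- function(agg1, agg2, peaks, genes,
                         cfg = linkage_config()) {
  acc <- rbind(agg1$access, agg2$access)
  ex <- rbind(agg1$expr, agg2$expr)
  cond <- c(rep(agg1$condition, nrow(agg1$access)),
            rep(agg2$condition, nrow(agg2$access)))
  n <- nrow(acc)
  if (n < 3) stop("need at least 3 aggregates in total")
  tot <- pmax(rowSums(ex), 1)
  exn <- log1p(ex / tot * 1e4)
  ctr <- (peaks$start + peaks$end) / 2
  cand <- list()
  for (g in seq_len(nrow(genes))) {
    pk <- which(peaks$chrom == genes$chrom[g] &
                  abs(genes$tss[g] - ctr) <= cfg$max_dist)
    if (length(pk))
      cand[[length(cand) + 1L]] <- data.frame(peak = pk, gene = g)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || !nrow(cand))
    stop("no peak-gene pairs within max_dist")
  r <- vapply(seq_len(nrow(cand)), function(q) {
    a <- acc[, cand$peak[q]]; e <- exn[, cand$gene[q]]
    if (stats::sd(a) == 0 || stats::sd(e) == 0) return(NA_real_)
    stats::cor(a, e)
  }, numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fdr <- stats::p.adjust(pv, "BH")
  retained <- !is.na(r) & r > cfg$cor_threshold & fdr < cfg$fdr_threshold
  is1 <- cond == agg1$condition
  linkages <- data.frame(
    peak = peaks$name[cand$peak], gene = genes$name[cand$gene],
    chrom = peaks$chrom[cand$peak],
    peak_start = peaks$start[cand$peak], peak_end = peaks$end[cand$peak],
    tss = genes$tss[cand$gene],
    distance = abs(genes$tss[cand$gene] - ctr[cand$peak]),
    correlation = r, pvalue = pv, fdr = fdr, retained = retained,
    acc_mean_1 = colMeans(acc[is1, cand$peak, drop = FALSE]),
    acc_mean_2 = colMeans(acc[!is1, cand$peak, drop = FALSE]),
    expr_mean_1 = colMeans(exn[is1, cand$gene, drop = FALSE]),
    expr_mean_2 = colMeans(exn[!is1, cand$gene, drop = FALSE]))
  rownames(linkages) <- NULL
  profiles <- list(
    access = t(acc[, cand$peak[retained], drop = FALSE]),
    expr = t(exn[, cand$gene[retained], drop = FALSE]),
    condition = cond)
  structure(list(linkages = linkages, profiles = profiles,
                 conditions = c(agg1$condition, agg2$condition),
                 cfg = cfg),
            class = "peak_to_gene")
}

#' @export
print.peak_to_gene <- function(x, ...) {
  cat("<peak_to_gene> ", sum(x$linkages$retained), " retained of ",
      nrow(x$linkages), " tested peak-gene pairs\n", sep = "")
  invisible(x)
}

#' Cluster retained linkages by their paired aggregate profiles
#'
#' Features are the per-aggregate accessibility and expression profiles of
#' each retained linkage, each row standardized to mean 0 / variance 1
#' separately before concatenation; k-means with a fixed seed and 10
#' restarts.
#'
#' @param p2g a [peak_to_gene()] result.
#' @param n_clusters number of clusters.
#' @param seed RNG seed.
#' @return The retained linkages with a `cluster` column.
#' @export
cluster_linkages <- function(p2g, n_clusters = 5, seed = 1L) {
  ret <- p2g$linkages[p2g$linkages$retained, , drop = FALSE]
  if (nrow(ret) < n_clusters)
    stop("fewer retained linkages (", nrow(ret), ") than clusters")
  row_scale <- function(m) {
    mu <- rowMeans(m)
    sg <- apply(m, 1, stats::sd)
    sg[sg == 0] <- 1
    (m - mu) / sg
  }
  feat <- cbind(row_scale(p2g$profiles$access),
                row_scale(p2g$profiles$expr))
  km <- withr::with_seed(seed,
    stats::kmeans(feat, centers = n_clusters, nstart = 10,
                  iter.max = 100))
  ret$cluster <- km$cluster
  ret
}

#' Mean fraction of co-accessible peak pairs within linkages
#'
#' For each gene with at least two linked peaks, the fraction of unordered
#' linked-peak pairs present in the co-accessible pair set; reported as
#' the mean over such genes (`NA` with a message when no gene qualifies).
#'
#' @param linkages retained linkage data.frame (needs peak coordinates and
#'   gene, as produced by [peak_to_gene()] / [cluster_linkages()]).
#' @param pairs co-accessible site pairs over the same peak universe.
#' @return A list with `mean_fraction`, and `per_gene` fractions.
#' @export
linkage_coaccess_fraction <- function(linkages, pairs) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  nm <- site_names(pairs)
  pair_keys <- unique(key(nm$s1, nm$s2))
  lk <- linkages[linkages$retained %||% TRUE, , drop = FALSE]
  lk$site <- paste0(lk$chrom, ":", lk$peak_start, "-", lk$peak_end)
  per_gene <- c()
  for (g in unique(lk$gene)) {
    sites <- unique(lk$site[lk$gene == g])
    if (length(sites) < 2) next
    cmb <- utils::combn(sites, 2)
    frac <- mean(key(cmb[1, ], cmb[2, ]) %in% pair_keys)
    per_gene[g] <- frac
  }
  if (!length(per_gene)) {
    message("no gene has two or more linked peaks")
    return(list(mean_fraction = NA_real_, per_gene = per_gene))
  }
  list(mean_fraction = mean(per_gene), per_gene = per_gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
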