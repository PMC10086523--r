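#' Parameters for the synthetic single-cell multiome generator
#'
#' Each cell carries a latent state `z` (a smooth continuum shared by both
#' conditions). A planted peak-gene linkage with latent correlation `rho`
#' gives the peak the latent `u = sqrt(rho) z + sqrt(1 - rho) e1` and the
#' gene `v = sqrt(rho) z + sqrt(1 - rho) e2`, so `cor(u, v) = rho`.
#' Accessibility is Bernoulli in the latent logit; expression is Poisson in
#' the latent log-rate. Condition-specific links are loaded on `z` only in
#' their condition (independent noise elsewhere). Unlinked features are
#' independent noise; planted co-accessibility communities share a
#' per-community latent factor.
#'
#' @param n_cells cells per condition.
#' @param n_peaks,n_genes feature counts.
#' @param chrom,chrom_len synthetic chromosome name and length (bp).
#' @param peak_spacing distance between consecutive peak starts (bp).
#' @param peak_width peak width (bp).
#' @param links data.frame with columns `peak` (index), `gene` (index),
#'   `rho` in [0, 1], `condition` in {"both", conditions[1], conditions[2]},
#'   or `NULL` for the default planting: 25 shared links (`rho = 0.8`), 5
#'   per condition condition-specific (`rho = 0.8`), 10 null links
#'   (`rho = 0`), and 5 distance negatives placed beyond `far_dist`.
#' @param rho default latent correlation used by the default planting.
#' @param communities list of peak-index vectors forming planted
#'   co-accessibility communities, or `NULL` for 3 communities of 6 peaks.
#' @param link_dist maximum planted TSS-to-peak distance for positive
#'   controls (bp).
#' @param far_dist TSS offset for distance-negative links (bp; beyond the
#'   linkage search window).
#' @param noise `"sampling"` for Bernoulli/Poisson observation noise,
#'   `"none"` for the continuous latent limit.
#' @param conditions two condition labels.
#' @param agg_k downstream cells-per-aggregate; `n_cells < agg_k` is an
#'   error because aggregation would be impossible.
#' @param seed RNG seed.
#' @return A list of class `multiome_sim_params`.
#' @export
multiome_sim_params <- function(n_cells = 500, n_peaks = 200, n_genes = 100,
                                chrom = "chrS", chrom_len = 2.6e6,
                                peak_spacing = 8000, peak_width = 400,
                                links = NULL, rho = 0.8,
                                communities = NULL, link_dist = 2e5,
                                far_dist = 6e5,
                                noise = c("sampling", "none"),
                                conditions = c("young", "aged"),
                                agg_k = 40, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(conditions) == 2, n_peaks >= 2, n_genes >= 1)
  if (n_cells < agg_k)
    stop("n_cells (", n_cells, ") is below the aggregate size k (", agg_k,
         "); aggregation downstream would be impossible")
  if ((n_peaks - 1) * peak_spacing + peak_width > chrom_len)
    stop("chrom_len too short for the requested peaks")
  if (is.null(links)) {
    links <- rbind(
      data.frame(peak = 1:25, gene = 1:25, rho = rho, condition = "both"),
      data.frame(peak = 26:30, gene = 26:30, rho = rho,
                 condition = conditions[1]),
      data.frame(peak = 31:35, gene = 31:35, rho = rho,
                 condition = conditions[2]),
      data.frame(peak = 36:45, gene = 36:45, rho = 0, condition = "both"),
      data.frame(peak = 46:50, gene = 46:50, rho = rho, condition = "both",
                 row.names = NULL))
    links$far <- c(rep(FALSE, 45), rep(TRUE, 5))
  } else if (is.null(links$far)) {
    links$far <- FALSE
  }
  stopifnot(all(links$rho >= 0), all(links$rho <= 1),
            all(links$peak <= n_peaks), all(links$gene <= n_genes))
  if (is.null(communities)) {
    base <- max(links$peak) + 1L
    communities <- lapply(0:2, function(m) base + m * 6L + 0:5)
    if (max(unlist(communities)) > n_peaks)
      stop("n_peaks too small for the default communities")
  }
  structure(list(n_cells = as.integer(n_cells), n_peaks = n_peaks,
                 n_genes = n_genes, chrom = chrom, chrom_len = chrom_len,
                 peak_spacing = peak_spacing, peak_width = peak_width,
                 links = links, communities = communities,
                 link_dist = link_dist, far_dist = far_dist,
                 noise = noise, conditions = conditions,
                 agg_k = as.integer(agg_k), seed = as.integer(seed)),
            class = "multiome_sim_params")
}

#' Simulate a two-condition single-cell multiome dataset with planted truth
#'
#' @param params a [multiome_sim_params()].
#' @return A list with `cells` (a [cell_matrices()]), `truth` (per-cell
#'   latent `z`, the planted link table with peak/gene names, community
#'   membership), and `params`.
#' @export
simulate_multiome <- function(params) {
  stopifnot(inherits(params, "multiome_sim_params"))
  n_cells_total <- 2L * params$n_cells
  conds <- rep(params$conditions, each = params$n_cells)
  peaks <- data.frame(
    chrom = params$chrom,
    start = (seq_len(params$n_peaks) - 1) * params$peak_spacing,
    end = (seq_len(params$n_peaks) - 1) * params$peak_spacing +
      params$peak_width,
    name = sprintf("peak_%03d", seq_len(params$n_peaks)))
  peak_center <- (peaks$start + peaks$end) / 2
  # gene TSSs: linked genes sit within link_dist of their peak (alternating
  # sides), distance negatives beyond far_dist, the rest spread uniformly
  tss <- round(seq(0, params$chrom_len - 1,
                   length.out = params$n_genes))
  lk <- params$links
  for (r in seq_len(nrow(lk))) {
    off <- if (lk$far[r]) params$far_dist else
      ((r %% 4) + 1) / 5 * params$link_dist
    side <- if (r %% 2 == 0) 1 else -1
    cand <- peak_center[lk$peak[r]] + side * off
    if (cand < 0 || cand > params$chrom_len - 1)
      cand <- peak_center[lk$peak[r]] - side * off
    tss[lk$gene[r]] <- round(max(0, min(params$chrom_len - 1, cand)))
  }
  genes <- data.frame(name = sprintf("gene_%03d", seq_len(params$n_genes)),
                      chrom = params$chrom, tss = tss,
                      strand = rep(c("+", "-"),
                                   length.out = params$n_genes))
  sim <- withr::with_seed(params$seed, {
    z <- stats::runif(n_cells_total, -2, 2)
    # latent peak logits
    u <- matrix(stats::rnorm(n_cells_total * params$n_peaks),
                n_cells_total, params$n_peaks)
    for (m in seq_along(params$communities)) {
      w <- stats::rnorm(n_cells_total)
      for (p in params$communities[[m]])
        u[, p] <- sqrt(0.6) * w + sqrt(0.4) * stats::rnorm(n_cells_total)
    }
    v <- matrix(stats::rnorm(n_cells_total * params$n_genes),
                n_cells_total, params$n_genes)
    for (r in seq_len(nrow(lk))) {
      rho <- lk$rho[r]
      on <- if (lk$condition[r] == "both") rep(TRUE, n_cells_total)
            else conds == lk$condition[r]
      if (rho > 0 && any(on)) {
        u[on, lk$peak[r]] <- sqrt(rho) * z[on] +
          sqrt(1 - rho) * stats::rnorm(sum(on))
        v[on, lk$gene[r]] <- sqrt(rho) * z[on] +
          sqrt(1 - rho) * stats::rnorm(sum(on))
      }
    }
    p_open <- stats::plogis(-0.5 + 1.5 * u)
    rate <- exp(0.3 + 0.8 * v)
    if (params$noise == "sampling") {
      acc <- matrix(stats::rbinom(length(p_open), 1, p_open),
                    nrow(p_open), ncol(p_open))
      ex <- matrix(stats::rpois(length(rate), rate),
                   nrow(rate), ncol(rate))
    } else {
      acc <- p_open
      ex <- rate
    }
    list(z = z, acc = acc, ex = ex, u = u, v = v)
  })
  cells <- data.frame(cell = sprintf("cell_%04d", seq_len(n_cells_total)),
                      condition = conds)
  cm <- cell_matrices(methods::as(Matrix::Matrix(sim$acc, sparse = TRUE),
                                  "CsparseMatrix"),
                      methods::as(Matrix::Matrix(sim$ex, sparse = TRUE),
                                  "CsparseMatrix"),
                      peaks, genes, cells)
  link_truth <- cbind(lk,
                      peak_name = peaks$name[lk$peak],
                      gene_name = genes$name[lk$gene],
                      distance = abs(tss[lk$gene] - peak_center[lk$peak]))
  membership <- rep(NA_integer_, params$n_peaks)
  for (m in seq_along(params$communities))
    membership[params$communities[[m]]] <- m
  truth <- list(z = sim$z, links = link_truth,
                communities = stats::setNames(membership, peaks$name),
                latent_u = sim$u, latent_v = sim$v)
  list(cells = cm, truth = truth, params = params)
}

#' Simulate scored site pairs with planted co-accessibility communities
#'
#' Emits all within-community pairs with scores around `score_within` and
#' random cross-community pairs around `score_between`; the recovery
#' fixture for CCAN detection.
#'
#' @param n_communities number of planted communities.
#' @param sites_per_community community size.
#' @param score_within,score_between mean scores (Gaussian, sd 0.05/0.02,
#'   clipped to `[-1, 1]`).
#' @param n_between_pairs number of cross-community background pairs.
#' @param spacing site spacing (bp).
#' @param chrom chromosome name.
#' @param condition condition label.
#' @param seed RNG seed.
#' @return A list with `pairs` (site-pair data.frame) and `truth`
#'   (named community membership per site).
#' @export
simulate_coaccess_pairs <- function(n_communities = 4,
                                    sites_per_community = 6,
                                    score_within = 0.4,
                                    score_between = 0.02,
                                    n_between_pairs = 40,
                                    spacing = 5000, chrom = "chrS",
                                    condition = "young", seed = 1L) {
  n_sites <- n_communities * sites_per_community
  start <- (seq_len(n_sites) - 1) * spacing
  site <- data.frame(chrom = chrom, start = start, end = start + 200)
  member <- rep(seq_len(n_communities), each = sites_per_community)
  withr::with_seed(seed, {
    rows <- list()
    for (m in seq_len(n_communities)) {
      idx <- which(member == m)
      cmb <- utils::combn(idx, 2)
      rows[[m]] <- data.frame(i = cmb[1, ], j = cmb[2, ],
                              score = pmin(1, pmax(-1,
                                stats::rnorm(ncol(cmb), score_within,
                                             0.05))))
    }
    bg <- matrix(NA_integer_, 0, 2)
    while (nrow(bg) < n_between_pairs) {
      cand <- cbind(sample(n_sites, n_between_pairs, replace = TRUE),
                    sample(n_sites, n_between_pairs, replace = TRUE))
      cand <- cand[member[cand[, 1]] != member[cand[, 2]], , drop = FALSE]
      bg <- unique(rbind(bg, t(apply(cand, 1, sort))))
    }
    bg <- bg[seq_len(n_between_pairs), , drop = FALSE]
    rows$bg <- data.frame(i = bg[, 1], j = bg[, 2],
                          score = pmin(1, pmax(-1,
                            stats::rnorm(nrow(bg), score_between, 0.02))))
    df <- do.call(rbind, rows)
    pairs <- data.frame(chrom = chrom,
                        start1 = site$start[df$i], end1 = site$end[df$i],
                        start2 = site$start[df$j], end2 = site$end[df$j],
                        score = df$score, condition = condition)
    swap <- pairs$start1 > pairs$start2
    if (any(swap)) {
      tmp <- pairs[swap, c("start1", "end1")]
      pairs[swap, c("start1", "end1")] <- pairs[swap, c("start2", "end2")]
      pairs[swap, c("start2", "end2")] <- tmp
    }
    truth <- stats::setNames(member,
                             paste0(chrom, ":", site$start, "-", site$end))
    list(pairs = pairs, truth = truth)
  })
}
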