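#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage with the package defaults.
#' Each sub-configuration can also be built on its own.
#'
#' @param compartment see [compartment_config()].
#' @param tad see [tad_config()].
#' @param dod see [dod_config()].
#' @param loop see [loop_config()].
#' @param ccan see [ccan_config()].
#' @param aggregate see [aggregate_config()].
#' @param linkage see [linkage_config()].
#' @param seed global seed used by stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(compartment = compartment_config(),
                            tad = tad_config(), dod = dod_config(),
                            loop = loop_config(), ccan = ccan_config(),
                            aggregate = aggregate_config(),
                            linkage = linkage_config(), seed = 1L) {
  structure(list(compartment = compartment, tad = tad, dod = dod,
                 loop = loop, ccan = ccan, aggregate = aggregate,
                 linkage = linkage, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param resolution analysis resolution in bp (compartments default 100 kb).
#' @param n_quantiles number of eigenvector quantiles in the saddle plot.
#' @param corner_frac fraction of extreme quantiles defining saddle corners.
#' @export
compartment_config <- function(resolution = 100000, n_quantiles = 50,
                               corner_frac = 0.2) {
  list(resolution = resolution, n_quantiles = n_quantiles,
       corner_frac = corner_frac)
}

#' @rdname pipeline_config
#' @param window_sizes insulation window sizes in bins.
#' @param fdr boundary FDR threshold (Benjamini-Hochberg).
#' @param delta minimum score drop versus flanking maxima.
#' @param tol_bins matching/rearrangement tolerance in bins.
#' @param min_domain_bins minimum domain size in bins.
#' @param inter_mode intra-TAD connectivity denominator: `"sum"` of flanking
#'   inter-TAD counts (default) or `"mean"` per inter pixel.
#' @export
tad_config <- function(resolution = 40000, window_sizes = c(4, 6, 8, 10),
                       fdr = 0.01, delta = 0.01, tol_bins = 1,
                       min_domain_bins = 3, inter_mode = c("sum", "mean")) {
  stopifnot(fdr > 0, fdr <= 1)
  list(resolution = resolution, window_sizes = window_sizes, fdr = fdr,
       delta = delta, tol_bins = tol_bins,
       min_domain_bins = min_domain_bins,
       inter_mode = match.arg(inter_mode))
}

#' @rdname pipeline_config
#' @param k number of nearest significant pixels averaged per pixel.
#' @param ww,pw,ratio,gap accepted for interface compatibility with the
#'   reference degree-of-disorder tool; unused by the simplified statistic
#'   (a message notes this when they differ from defaults).
#' @param top quantile threshold selecting significant pixels (pixels with
#'   O/E at or above this empirical quantile).
#' @export
dod_config <- function(k = 3, ww = 5, pw = 2, top = 0.7, ratio = 0.05,
                       gap = 0.2, resolution = 10000) {
  list(k = k, ww = ww, pw = pw, top = top, ratio = ratio, gap = gap,
       resolution = resolution)
}

#' @rdname pipeline_config
#' @param resolutions loop-calling resolutions in bp, finest first.
#' @param loop_fdr per-resolution BH FDR levels.
#' @param peak_widths per-resolution peak half-widths p (bins).
#' @param windows per-resolution donut half-widths i (bins), i > p.
#' @param min_dists per-resolution minimum diagonal distances (bp).
#' @param merge_dists per-resolution cross-resolution merge distances (bp).
#' @param thresholds length-4 post-hoc filter: max q-value, then minimum
#'   observed/expected ratios over the horizontal+vertical stripes, the
#'   donut, and the lower-left quadrant.
#' @export
loop_config <- function(resolutions = c(5000, 10000, 25000),
                        loop_fdr = c(0.1, 0.1, 0.1),
                        peak_widths = c(4, 2, 1),
                        windows = c(7, 5, 3),
                        min_dists = c(20000, 20000, 50000),
                        merge_dists = c(20000, 20000, 50000),
                        thresholds = c(0.02, 1.5, 1.75, 2)) {
  n <- length(resolutions)
  if (any(lengths(list(loop_fdr, peak_widths, windows, min_dists,
                       merge_dists)) != n))
    stop("per-resolution parameter lists must match resolutions in length")
  if (any(windows <= peak_widths))
    stop("windows must exceed peak widths")
  stopifnot(all(loop_fdr > 0), all(loop_fdr <= 1), length(thresholds) == 4)
  list(resolutions = resolutions, loop_fdr = loop_fdr,
       peak_widths = peak_widths, windows = windows, min_dists = min_dists,
       merge_dists = merge_dists, thresholds = thresholds)
}

#' @rdname pipeline_config
#' @param cutoff co-accessibility score cutoff defining graph edges.
#' @param min_size minimum number of member sites per CCAN.
#' @export
ccan_config <- function(cutoff = 0.1, min_size = 3) {
  stopifnot(min_size >= 1)
  list(cutoff = cutoff, min_size = min_size)
}

#' @rdname pipeline_config
#' @param k cells per aggregate.
#' @param max_overlap maximum mean pairwise shared-cell fraction.
#' @param max_median_shared required median pairwise shared-cell count.
#' @param n_aggregates target number of aggregates per condition.
#' @param n_dims principal directions used for the neighbor search.
#' @export
aggregate_config <- function(k = 40, max_overlap = 0.10,
                             max_median_shared = 0, n_aggregates = 50,
                             n_dims = 10) {
  stopifnot(k >= 1, max_overlap >= 0, max_overlap <= 1)
  list(k = k, max_overlap = max_overlap,
       max_median_shared = max_median_shared,
       n_aggregates = n_aggregates, n_dims = n_dims)
}

#' @rdname pipeline_config
#' @param max_dist maximum TSS-to-peak-center distance (bp).
#' @param cor_threshold minimum retained peak-to-gene correlation.
#' @param fdr_threshold maximum retained BH FDR.
#' @param n_clusters number of k-means clusters of retained linkages.
#' @export
linkage_config <- function(max_dist = 500000, cor_threshold = 0.45,
                           fdr_threshold = 1e-4, n_clusters = 5) {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  list(max_dist = max_dist, cor_threshold = cor_threshold,
       fdr_threshold = fdr_threshold, n_clusters = n_clusters)
}

#' Write / read a flat text configuration mirroring [pipeline_config()]
#'
#' The format is one `section.key<TAB>value` line per scalar or
#' comma-separated vector.
#'
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  lines <- character()
  for (section in setdiff(names(cfg), "seed")) {
    for (key in names(cfg[[section]])) {
      v <- cfg[[section]][[key]]
      lines <- c(lines, paste0(section, ".", key, "\t",
                               paste(v, collapse = ",")))
    }
  }
  lines <- c(lines, paste0("seed\t", cfg$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- pipeline_config()
  for (line in readLines(path)) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed config line: ", line)
    vals <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) vals <- num
    if (parts[1] == "seed") { cfg$seed <- as.integer(vals); next }
    key <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    cfg[[key[1]]][[key[2]]] <- vals
  }
  cfg
}
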