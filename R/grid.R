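#' Genome assembly
#'
#' A minimal description of a (possibly synthetic) genome: chromosome names
#' and lengths in base pairs. All coordinates in the package are 0-based,
#' half-open, following the BED/cooler convention.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer-ish vector of chromosome lengths (bp), > 0,
#'   one per chromosome.
#' @return An object of class `genome_assembly`.
#' @examples
#' genome_assembly("chrS", 2e7)
#' @export
genome_assembly <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names)),
    class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$chrom_names), " chromosome(s), ",
      format(sum(x$chrom_lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Fixed-resolution bin grid over an assembly
#'
#' Bin `i` (0-based) of a chromosome covers `[i * resolution,
#' (i + 1) * resolution)`; the last bin is truncated at the chromosome end.
#'
#' @param assembly a [genome_assembly()].
#' @param resolution bin size in base pairs (> 0).
#' @return An object of class `bin_grid` with per-chromosome bin counts.
#' @examples
#' bin_grid(genome_assembly("chrS", 2e7), 40000)
#' @export
bin_grid <- function(assembly, resolution) {
  stopifnot(inherits(assembly, "genome_assembly"))
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("resolution must be a single positive number")
  n_bins <- as.integer(ceiling(assembly$chrom_lengths / resolution))
  structure(
    list(assembly = assembly, resolution = resolution,
         n_bins = stats::setNames(n_bins, assembly$chrom_names)),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> resolution ", format(x$resolution, big.mark = ","),
      " bp; bins:", sep = "")
  for (ch in x$assembly$chrom_names)
    cat(" ", ch, "=", x$n_bins[[ch]], sep = "")
  cat("\n")
  invisible(x)
}

grid_chroms <- function(grid) grid$assembly$chrom_names

check_chrom <- function(grid, chrom) {
  if (!chrom %in% grid_chroms(grid))
    stop("unknown chromosome: ", chrom)
  chrom
}

#' Convert genomic positions to 0-based bin indices
#'
#' @param grid a [bin_grid()].
#' @param chrom chromosome name.
#' @param pos 0-based genomic positions (bp).
#' @return Integer vector of 0-based bin indices (`floor(pos / resolution)`).
#' @export
bin_of <- function(grid, chrom, pos) {
  check_chrom(grid, chrom)
  idx <- as.integer(floor(pos / grid$resolution))
  if (any(idx < 0L | idx >= grid$n_bins[[chrom]]))
    stop("position out of range for ", chrom)
  idx
}

#' Convert 0-based bin indices to half-open intervals
#'
#' @inheritParams bin_of
#' @param bins 0-based bin indices.
#' @return data.frame with columns chrom, start, end (0-based, half-open;
#'   last bin truncated at the chromosome end).
#' @export
bin_interval <- function(grid, chrom, bins) {
  check_chrom(grid, chrom)
  bins <- as.integer(bins)
  if (any(bins < 0L | bins >= grid$n_bins[[chrom]]))
    stop("bin index out of range for ", chrom)
  len <- grid$assembly$chrom_lengths[[chrom]]
  data.frame(chrom = chrom,
             start = bins * grid$resolution,
             end = pmin((bins + 1) * grid$resolution, len),
             stringsAsFactors = FALSE)
}

same_grid <- function(a, b) {
  identical(a$resolution, b$resolution) &&
    identical(a$n_bins, b$n_bins) &&
    identical(a$assembly$chrom_names, b$assembly$chrom_names)
}
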