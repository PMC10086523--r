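#' Binned intra-chromosomal contact map
#'
#' Stores one symmetric contact matrix per chromosome as a sparse
#' upper-triangular matrix (only pixels with bin1 <= bin2 are kept; entries
#' below the diagonal are folded onto the upper triangle). Balancing weights,
#' when present, are per-bin multipliers with `NA` on masked bins.
#'
#' @param grid a [bin_grid()].
#' @param counts named list (by chromosome) of upper-triangular sparse
#'   matrices (`Matrix::sparseMatrix`), or of triplet data.frames with
#'   columns `bin1`, `bin2`, `count` (0-based bins). Chromosomes absent from
#'   the list get an empty matrix.
#' @param weights optional named list of per-bin balancing weight vectors
#'   (`NA` = masked bin).
#' @param normalized logical; `TRUE` once balancing weights are attached.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(grid, counts = list(), weights = NULL,
                        normalized = FALSE) {
  stopifnot(inherits(grid, "bin_grid"))
  out <- stats::setNames(vector("list", length(grid_chroms(grid))),
                         grid_chroms(grid))
  for (ch in grid_chroms(grid)) {
    n <- grid$n_bins[[ch]]
    m <- counts[[ch]]
    if (is.null(m)) {
      m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n))
    } else if (is.data.frame(m)) {
      m <- triplets_to_ut(m, n)
    } else {
      if (!all(dim(m) == c(n, n)))
        stop("count matrix for ", ch, " has wrong dimensions")
      m <- fold_upper(methods::as(m, "CsparseMatrix"))
    }
    if (any(m@x < 0)) stop("negative counts in contact matrix for ", ch)
    out[[ch]] <- Matrix::drop0(m)
  }
  if (!is.null(weights)) {
    for (ch in names(weights))
      if (length(weights[[ch]]) != grid$n_bins[[check_chrom(grid, ch)]])
        stop("weights length mismatch for ", ch)
  }
  structure(list(grid = grid, counts = out, weights = weights,
                 normalized = isTRUE(normalized)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  nnz <- sum(vapply(x$counts, function(m) length(m@x), numeric(1)))
  tot <- sum(vapply(x$counts, function(m) sum(m@x), numeric(1)))
  cat("<contact_map> ", length(x$counts), " chromosome(s) at ",
      format(x$grid$resolution, big.mark = ","), " bp; ",
      format(nnz, big.mark = ","), " stored pixels, ",
      format(tot, big.mark = ","), " total counts; ",
      if (x$normalized) "balanced" else "raw", "\n", sep = "")
  invisible(x)
}

# fold a square sparse matrix onto the upper triangle, summing (i,j) + (j,i)
fold_upper <- function(m) {
  tm <- methods::as(m, "TsparseMatrix")
  i <- tm@i; j <- tm@j; x <- tm@x
  lower <- i > j
  ii <- ifelse(lower, j, i)
  jj <- ifelse(lower, i, j)
  Matrix::sparseMatrix(i = ii + 1L, j = jj + 1L, x = x, dims = dim(m))
}

triplets_to_ut <- function(df, n) {
  b1 <- as.integer(df$bin1); b2 <- as.integer(df$bin2)
  x <- as.numeric(df$count)
  if (any(b1 < 0L | b2 < 0L | b1 >= n | b2 >= n))
    stop("bin index out of range (n_bins = ", n, ")")
  lower <- b1 > b2
  i <- ifelse(lower, b2, b1)
  j <- ifelse(lower, b1, b2)
  Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = x, dims = c(n, n))
}

cm_chroms <- function(map) names(map$counts)

#' Dense symmetric matrix view of one chromosome
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @param what `"raw"` for counts, `"balanced"` for `w_i * c_ij * w_j`
#'   (requires balancing weights; masked rows/columns are `NA`).
#' @return A dense symmetric `n x n` base matrix.
#' @export
cm_dense <- function(map, chrom, what = c("raw", "balanced")) {
  what <- match.arg(what)
  check_chrom(map$grid, chrom)
  ut <- as.matrix(map$counts[[chrom]])
  m <- ut + t(ut)
  diag(m) <- diag(ut)
  if (what == "balanced") {
    w <- map$weights[[chrom]]
    if (is.null(w)) stop("contact map is not balanced; run kr_balance()")
    m <- m * outer(w, w)
  }
  m
}

cm_total <- function(map) {
  sum(vapply(map$counts, function(m) sum(m@x), numeric(1)))
}

#' Read a contact map from COO triplet text
#'
#' The expected format is whitespace-separated columns
#' `chrom bin_i bin_j count` with 0-based bin indices. Entries with
#' `bin_i > bin_j` are folded onto the upper triangle and duplicate pixels
#' are summed. Lines whose two chromosome fields differ (inter-chromosomal
#' input in 6-column `chrom1 bin1 chrom2 bin2 count` form) are not supported;
#' only intra-chromosomal maps are modeled.
#'
#' @param path path to the triplet text file (may be empty).
#' @param grid a [bin_grid()] describing the binning.
#' @return A raw [contact_map()].
#' @export
read_contact_map <- function(path, grid) {
  if (file.size(path) == 0)
    return(contact_map(grid))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "bin1", "bin2", "count"),
                          colClasses = list(character = 1))
  bad <- which(!dt$chrom %in% grid_chroms(grid))
  if (length(bad))
    stop("unknown chromosome '", dt$chrom[bad[1]], "' at line ", bad[1])
  bad <- which(dt$count < 0)
  if (length(bad))
    stop("negative count at line ", bad[1])
  nb <- grid$n_bins[dt$chrom]
  bad <- which(dt$bin1 < 0 | dt$bin2 < 0 | dt$bin1 >= nb | dt$bin2 >= nb)
  if (length(bad))
    stop("bin index out of range at line ", bad[1])
  counts <- lapply(split(dt, dt$chrom), function(d)
    data.frame(bin1 = d$bin1, bin2 = d$bin2, count = d$count))
  contact_map(grid, counts)
}

#' Write a contact map as COO triplet text
#'
#' Inverse of [read_contact_map()]: emits `chrom bin_i bin_j count` for the
#' stored upper-triangular pixels in deterministic (chrom, bin1, bin2) order.
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  recs <- lapply(cm_chroms(map), function(ch) {
    tm <- methods::as(map$counts[[ch]], "TsparseMatrix")
    if (!length(tm@x)) return(NULL)
    data.table::data.table(chrom = ch, bin1 = tm@i, bin2 = tm@j,
                           count = tm@x)
  })
  dt <- data.table::rbindlist(recs)
  if (nrow(dt)) data.table::setorder(dt, chrom, bin1, bin2)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}
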