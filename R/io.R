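#' Per-bin signal track
#'
#' One scalar per bin (GC fraction, eigenvector value, mean signal);
#' `NA` marks missing/masked bins.
#'
#' @param grid a [bin_grid()].
#' @param values named list (by chromosome) of numeric vectors, one value
#'   per bin.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(grid, values) {
  stopifnot(inherits(grid, "bin_grid"))
  for (ch in names(values)) {
    check_chrom(grid, ch)
    if (length(values[[ch]]) != grid$n_bins[[ch]])
      stop("values length mismatch for ", ch)
  }
  structure(list(grid = grid, values = values), class = "signal_track")
}

validate_intervals <- function(df, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop(what, " records need columns chrom, start, end")
  if (any(df$start >= df$end))
    stop(what, " records must satisfy start < end")
  if (any(df$start < 0)) stop(what, " records must have start >= 0")
  invisible(df)
}

validate_loops <- function(df) {
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(df)))
    stop("loop records need columns chrom, start1, end1, start2, end2")
  if (any(df$start1 >= df$end1 | df$start2 >= df$end2))
    stop("loop anchors must satisfy start < end")
  if (any(df$start1 > df$start2))
    stop("loop anchor1 must be upstream of anchor2")
  invisible(df)
}

#' Write genomic intervals as BED (0-based, half-open)
#'
#' Records are sorted deterministically by (chrom, start, end); any columns
#' beyond chrom/start/end are appended after the three BED fields.
#'
#' @param records data.frame with columns chrom, start, end (+ extras).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  validate_intervals(records)
  dt <- data.table::as.data.table(records)
  extra <- setdiff(names(dt), c("chrom", "start", "end"))
  data.table::setcolorder(dt, c("chrom", "start", "end", extra))
  data.table::setorder(dt, chrom, start, end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path input path.
#' @param extra_cols names for any columns beyond chrom/start/end.
#' @return data.frame with columns chrom, start, end, and `extra_cols`.
#' @export
read_bed <- function(path, extra_cols = character()) {
  cn <- c("chrom", "start", "end", extra_cols)
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(), numeric(), numeric(),
                 matrix(numeric(), 0, length(extra_cols)))[0, , drop = FALSE],
      cn))
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                        colClasses = list(character = 1)))
  names(df) <- cn[seq_len(ncol(df))]
  validate_intervals(df)
  df
}

#' Write paired anchors (loops) as BEDPE
#'
#' @param records data.frame with columns chrom, start1, end1, start2, end2
#'   (+ extras); both anchors are on `chrom`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(records, path) {
  validate_loops(records)
  dt <- data.table::as.data.table(records)
  extra <- setdiff(names(dt), c("chrom", "start1", "end1", "start2", "end2"))
  out <- data.table::data.table(
    chrom1 = dt$chrom, start1 = dt$start1, end1 = dt$end1,
    chrom2 = dt$chrom, start2 = dt$start2, end2 = dt$end2)
  for (cc in extra) out[[cc]] <- dt[[cc]]
  data.table::setorder(out, chrom1, start1, start2)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a BEDPE file written by [write_bedpe()]
#'
#' @param path input path.
#' @param extra_cols names for columns beyond the six BEDPE fields.
#' @return data.frame with columns chrom, start1, end1, start2, end2 + extras.
#' @export
read_bedpe <- function(path, extra_cols = character()) {
  cn <- c("chrom", "start1", "end1", "start2", "end2", extra_cols)
  if (file.size(path) == 0) {
    out <- data.frame(chrom = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(),
                      end2 = numeric())
    for (cc in extra_cols) out[[cc]] <- numeric()
    return(out)
  }
  df <- as.data.frame(data.table::fread(path, header = FALSE, sep = "\t",
                                        colClasses = list(character = c(1, 4))))
  if (any(df[[1]] != df[[4]]))
    stop("inter-chromosomal loop records are not supported")
  df <- df[, -4]
  names(df) <- cn[seq_len(ncol(df))]
  validate_loops(df)
  df
}

#' Write a per-bin signal track as bedGraph
#'
#' Bins with `NA` values are omitted. Spans are 0-based half-open; the last
#' bin is truncated at the chromosome end.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  grid <- track$grid
  recs <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    keep <- which(!is.na(v))
    if (!length(keep)) return(NULL)
    iv <- bin_interval(grid, ch, keep - 1L)
    data.table::data.table(chrom = ch, start = iv$start, end = iv$end,
                           value = v[keep])
  })
  dt <- data.table::rbindlist(recs)
  if (nrow(dt)) data.table::setorder(dt, chrom, start)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a bedGraph written on a known grid
#'
#' @param path input path.
#' @param grid the [bin_grid()] the track was written on.
#' @return A [signal_track()]; bins absent from the file are `NA`.
#' @export
read_bedgraph <- function(path, grid) {
  values <- lapply(stats::setNames(grid_chroms(grid), grid_chroms(grid)),
                   function(ch) rep(NA_real_, grid$n_bins[[ch]]))
  if (file.size(path) > 0) {
    df <- data.table::fread(path, header = FALSE, sep = "\t",
                            col.names = c("chrom", "start", "end", "value"),
                            colClasses = list(character = 1))
    for (ch in unique(df$chrom)) {
      check_chrom(grid, ch)
      d <- df[df$chrom == ch, ]
      values[[ch]][bin_of(grid, ch, d$start) + 1L] <- d$value
    }
  }
  signal_track(grid, values)
}

#' Write / read tab-separated records with a header
#'
#' Deterministic column order is the caller's; rows are written as given.
#'
#' @param records data.frame.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv_file` a data.frame.
#' @export
write_tsv <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t", col.names = TRUE, scipen = 50)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_file <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' Sparse cell matrices with condition labels
#'
#' Container for a two-condition single-cell multiome dataset: a sparse
#' cell-by-peak accessibility matrix and a sparse cell-by-gene expression
#' matrix over the same cells.
#'
#' @param access sparse cells-by-peaks matrix.
#' @param expr sparse cells-by-genes matrix.
#' @param peaks data.frame (chrom, start, end, name), one row per peak.
#' @param genes data.frame (name, chrom, tss, strand), one row per gene.
#' @param cells data.frame (cell, condition); exactly two condition levels.
#' @return An object of class `cell_matrices`.
#' @export
cell_matrices <- function(access, expr, peaks, genes, cells) {
  access <- methods::as(access, "CsparseMatrix")
  expr <- methods::as(expr, "CsparseMatrix")
  if (nrow(access) != nrow(cells) || nrow(expr) != nrow(cells))
    stop("matrix row count does not match the number of labeled cells")
  if (ncol(access) != nrow(peaks))
    stop("accessibility matrix column count does not match peaks")
  if (ncol(expr) != nrow(genes))
    stop("expression matrix column count does not match genes")
  validate_intervals(peaks, "peak")
  conds <- unique(as.character(cells$condition))
  if (length(conds) != 2L)
    stop("exactly two condition labels required, found ", length(conds))
  rownames(access) <- rownames(expr) <- as.character(cells$cell)
  colnames(access) <- as.character(peaks$name)
  colnames(expr) <- as.character(genes$name)
  structure(list(access = access, expr = expr, peaks = peaks, genes = genes,
                 cells = cells, conditions = conds),
            class = "cell_matrices")
}

#' @export
print.cell_matrices <- function(x, ...) {
  cat("<cell_matrices> ", nrow(x$cells), " cells (",
      paste(sprintf("%s: %d", x$conditions,
                    tabulate(factor(x$cells$condition, x$conditions))),
            collapse = ", "),
      "), ", nrow(x$peaks), " peaks, ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read sparse cell matrices from MatrixMarket + name files
#'
#' @param mtx_access path to the cells-by-peaks accessibility MTX.
#' @param mtx_expr path to the cells-by-genes expression MTX.
#' @param peak_bed BED of peaks with a 4th `name` column.
#' @param gene_tsv TSV with header columns name, chrom, tss, strand.
#' @param labels_tsv TSV with header columns cell, condition; row order
#'   names the matrix rows. Exactly two conditions are required.
#' @return A [cell_matrices()] object.
#' @export
read_cell_matrices <- function(mtx_access, mtx_expr, peak_bed, gene_tsv,
                               labels_tsv) {
  access <- methods::as(Matrix::readMM(mtx_access), "CsparseMatrix")
  expr <- methods::as(Matrix::readMM(mtx_expr), "CsparseMatrix")
  peaks <- read_bed(peak_bed, extra_cols = "name")
  genes <- read_tsv_file(gene_tsv)
  cells <- read_tsv_file(labels_tsv)
  cell_matrices(access, expr, peaks, genes, cells)
}

#' Write cell matrices in the format [read_cell_matrices()] expects
#'
#' @param cm a [cell_matrices()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the five written paths, invisibly.
#' @export
write_cell_matrices <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(access = file.path(dir, "access.mtx"),
             expr = file.path(dir, "expr.mtx"),
             peaks = file.path(dir, "peaks.bed"),
             genes = file.path(dir, "genes.tsv"),
             labels = file.path(dir, "labels.tsv"))
  Matrix::writeMM(cm$access, paths[["access"]])
  Matrix::writeMM(cm$expr, paths[["expr"]])
  write_bed(cm$peaks[, c("chrom", "start", "end", "name")], paths[["peaks"]])
  write_tsv(cm$genes, paths[["genes"]])
  write_tsv(cm$cells, paths[["labels"]])
  invisible(paths)
}
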