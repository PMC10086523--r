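# shared fixtures and independent oracles used across test files

# contact map from a dense symmetric matrix
map_from_dense <- function(m, resolution = 40000, chrom = "chrT") {
  n <- nrow(m)
  grid <- bin_grid(genome_assembly(chrom, n * resolution), resolution)
  ut <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  counts <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                       count = m[ut])
  contact_map(grid, stats::setNames(list(counts), chrom))
}

# independent balancing oracle: plain alternating row/column normalization
# (Sinkhorn-Knopp) run to a fixed point; returns the balanced matrix
sinkhorn_oracle <- function(m, iters = 50000, tol = 1e-12) {
  a <- m
  for (i in seq_len(iters)) {
    a <- a / rowSums(a)
    a <- t(t(a) / colSums(a))
    if (max(abs(rowSums(a) - 1)) < tol &&
        max(abs(colSums(a) - 1)) < tol) break
  }
  a
}

# brute-force maximum-weight one-to-one matching over a weight matrix
# (rows may stay unmatched); recursion over rows
brute_force_matching <- function(W) {
  n1 <- nrow(W); n2 <- ncol(W)
  best <- 0
  rec <- function(row, used, acc) {
    if (row > n1) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(row + 1, used, acc)                        # leave row unmatched
    for (b in seq_len(n2)) {
      if (!used[b] && W[row, b] > 0) {
        used[b] <- TRUE
        rec(row + 1, used, acc + W[row, b])
        used[b] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, n2), 0)
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# brute-force diamond-mean separation score (independent of the package's
# integral-image-free implementation)
naive_separation_score <- function(b, windows) {
  n <- nrow(b)
  zs <- sapply(windows, function(w) {
    dm <- rep(NA_real_, n)
    for (i in w:(n - w)) {
      vals <- c()
      for (a in (i - w):(i - 1)) for (bb in i:(i + w - 1))
        vals <- c(vals, b[a + 1, bb + 1])
      dm[i + 1] <- mean(vals, na.rm = TRUE)
    }
    (dm - mean(dm, na.rm = TRUE)) / stats::sd(dm, na.rm = TRUE)
  })
  rowMeans(zs, na.rm = TRUE)
}

# boundary recall/precision against planted boundary bins
boundary_recovery <- function(called_bins, truth_bins, tol = 1) {
  recall <- if (length(truth_bins) == 0) NA_real_ else
    mean(vapply(truth_bins, function(t)
      any(abs(called_bins - t) <= tol), logical(1)))
  precision <- if (length(called_bins) == 0) NA_real_ else
    mean(vapply(called_bins, function(b)
      any(abs(truth_bins - b) <= tol), logical(1)))
  list(recall = recall, precision = precision)
}

# minimal compartment_call object for switch/saddle tests
fake_call <- function(labels, e1 = NULL, resolution = 100000,
                      chrom = "chrT") {
  n <- length(labels)
  grid <- bin_grid(genome_assembly(chrom, n * resolution), resolution)
  if (is.null(e1)) e1 <- ifelse(is.na(labels), NA_real_,
                                ifelse(labels == "A", 1, -1))
  structure(list(grid = grid,
                 e1 = stats::setNames(list(e1), chrom),
                 labels = stats::setNames(list(labels), chrom)),
            class = "compartment_call")
}
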