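#' Call A/B compartments from the contact correlation eigenvector
#'
#' Per chromosome, computes the Pearson correlation matrix of the
#' observed/expected rows, takes the eigenvector of the largest algebraic
#' eigenvalue, and orients its sign so that bins with positive values have
#' mean GC content at least that of negative bins (A = open/GC-rich).
#' Labels are A where the eigenvector is positive, B where negative, and
#' missing on masked bins. Chromosomes with fewer than `min_bins` unmasked
#' bins are skipped with a message.
#'
#' @param map a balanced [contact_map()] (conventionally at 100 kb).
#' @param gc a [signal_track()] of per-bin GC fractions on the same grid.
#' @param min_bins minimum unmasked bins per chromosome.
#' @return An object of class `compartment_call` with per-chromosome
#'   eigenvector values `e1` and labels in {"A", "B", NA}.
#' @export
call_compartments <- function(map, gc, min_bins = 10) {
  if (!map$normalized) stop("map must be balanced first (kr_balance)")
  if (!same_grid(map$grid, gc$grid)) stop("gc track grid mismatch")
  profile <- expected_by_distance(map)
  oe <- observed_over_expected(map, profile)
  e1 <- list(); labels <- list()
  for (ch in cm_chroms(map)) {
    n <- map$grid$n_bins[[ch]]
    e <- rep(NA_real_, n)
    keep <- which(!is.na(map$weights[[ch]]))
    if (length(keep) < min_bins) {
      message("skipping ", ch, ": fewer than ", min_bins, " unmasked bins")
    } else {
      sub <- oe[[ch]][keep, keep, drop = FALSE]
      # rows without variation carry no compartment signal; drop them too
      ok <- apply(sub, 1, function(r) stats::sd(r, na.rm = TRUE) > 0)
      ok[is.na(ok)] <- FALSE
      keep <- keep[ok]
      if (length(keep) >= min_bins) {
        sub <- oe[[ch]][keep, keep, drop = FALSE]
        cc <- suppressWarnings(
          stats::cor(sub, use = "pairwise.complete.obs"))
        cc[!is.finite(cc)] <- 0
        ev <- eigen(cc, symmetric = TRUE)
        vec <- ev$vectors[, 1]
        gcv <- gc$values[[ch]][keep]
        pos_gc <- mean(gcv[vec > 0], na.rm = TRUE)
        neg_gc <- mean(gcv[vec < 0], na.rm = TRUE)
        if (is.finite(pos_gc) && is.finite(neg_gc) && pos_gc < neg_gc)
          vec <- -vec
        e[keep] <- vec
      } else {
        message("skipping ", ch, ": fewer than ", min_bins,
                " informative bins")
      }
    }
    e1[[ch]] <- e
    labels[[ch]] <- ifelse(is.na(e), NA_character_,
                           ifelse(e > 0, "A", ifelse(e < 0, "B",
                                                     NA_character_)))
  }
  structure(list(grid = map$grid, e1 = e1, labels = labels),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  lab <- unlist(x$labels)
  cat("<compartment_call> ", sum(lab == "A", na.rm = TRUE), " A bins, ",
      sum(lab == "B", na.rm = TRUE), " B bins, ", sum(is.na(lab)),
      " missing\n", sep = "")
  invisible(x)
}

#' Quantify compartment switching between two conditions
#'
#' Bins missing in either call are excluded; the four transition fractions
#' sum to 1 over the included bins.
#'
#' @param call1,call2 [call_compartments()] results on the same grid
#'   (condition 1 -> condition 2, e.g. young -> aged).
#' @return Named list: `fractions` (A->A, A->B, B->A, B->B),
#'   `switch_fraction` (A->B + B->A), and `n_bins` included.
#' @export
compartment_switches <- function(call1, call2) {
  if (!same_grid(call1$grid, call2$grid))
    stop("compartment calls are on different grids")
  l1 <- unlist(call1$labels); l2 <- unlist(call2$labels)
  keep <- !is.na(l1) & !is.na(l2)
  n <- sum(keep)
  if (n == 0) stop("no bins shared between the two calls")
  tab <- table(factor(l1[keep], c("A", "B")), factor(l2[keep], c("A", "B")))
  fr <- as.numeric(tab) / n
  names(fr) <- c("A->A", "B->A", "A->B", "B->B")
  fr <- fr[c("A->A", "A->B", "B->A", "B->B")]
  list(fractions = fr, switch_fraction = unname(fr["A->B"] + fr["B->A"]),
       n_bins = n)
}

#' Saddle plot and compartment strength
#'
#' Unmasked bins are ranked by eigenvector value into `n_quantiles`
#' equal-occupancy groups (quantile 1 = strongest B, `n_quantiles` =
#' strongest A); cell (a, b) holds the mean O/E over all pixel pairs in
#' quantiles (a, b). Compartment strength is
#' `(mean AA corner + mean BB corner) / (2 * mean of the two AB corners)`
#' with corners the extreme `corner_frac` of quantiles.
#'
#' @param oe named list of O/E matrices from [observed_over_expected()].
#' @param call a [call_compartments()] result on the same grid.
#' @param n_quantiles number of eigenvector quantiles (>= 5).
#' @param corner_frac fraction of quantiles forming each corner.
#' @return A list of class `saddle_result` with the `n_quantiles` square
#'   `matrix` and the `strength` scalar.
#' @export
saddle <- function(oe, call, n_quantiles = 50, corner_frac = 0.2) {
  if (n_quantiles < 5) stop("n_quantiles must be at least 5")
  e1 <- unlist(call$e1)
  idx_chrom <- rep(names(call$e1), lengths(call$e1))
  ok <- !is.na(e1)
  n_ok <- sum(ok)
  if (n_ok < n_quantiles) stop("fewer unmasked bins than quantiles")
  q <- integer(length(e1))
  q[ok] <- ceiling(n_quantiles *
                     rank(e1[ok], ties.method = "first") / n_ok)
  sums <- matrix(0, n_quantiles, n_quantiles)
  cnts <- matrix(0, n_quantiles, n_quantiles)
  off <- 0L
  for (ch in names(call$e1)) {
    nb <- length(call$e1[[ch]])
    qs <- q[off + seq_len(nb)]
    m <- oe[[ch]]
    ut <- which(upper.tri(m, diag = TRUE) & !is.na(m), arr.ind = TRUE)
    if (nrow(ut)) {
      qa <- qs[ut[, 1]]; qb <- qs[ut[, 2]]
      val <- m[ut]
      keep <- qa > 0 & qb > 0
      a <- qa[keep]; b <- qb[keep]; v <- val[keep]
      mirror <- a != b
      A <- c(a, b[mirror]); B <- c(b, a[mirror]); V <- c(v, v[mirror])
      key <- (B - 1L) * n_quantiles + A
      sv <- rowsum(V, key)
      cv <- rowsum(rep(1, length(V)), key)
      k <- as.integer(rownames(sv))
      sums[k] <- sums[k] + sv[, 1]
      cnts[k] <- cnts[k] + cv[, 1]
    }
    off <- off + nb
  }
  S <- sums / cnts
  m <- max(1L, floor(corner_frac * n_quantiles))
  lo <- seq_len(m); hi <- n_quantiles - m + seq_len(m)
  aa <- mean(S[hi, hi], na.rm = TRUE)
  bb <- mean(S[lo, lo], na.rm = TRUE)
  ab <- mean(S[lo, hi], na.rm = TRUE)
  ba <- mean(S[hi, lo], na.rm = TRUE)
  strength <- (aa + bb) / (ab + ba)
  structure(list(matrix = S, strength = strength,
                 n_quantiles = n_quantiles, corner_frac = corner_frac),
            class = "saddle_result")
}
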