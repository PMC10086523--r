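#' Knight-Ruiz balancing of a contact map
#'
#' Computes per-bin weights `w` such that the balanced matrix
#' `b(i,j) = w_i * c(i,j) * w_j` has every unmasked row summing to 1.
#' Bins whose row has fewer than `min_nnz_frac` non-zero pixels are masked
#' before balancing (weight `NA`). The solver is a Newton-type inner-outer
#' iteration; a damped symmetric Sinkhorn fixed-point iteration is used as
#' a fallback when the Newton iteration fails to converge.
#'
#' @param map a raw [contact_map()].
#' @param tol convergence tolerance on the balanced row sums.
#' @param max_iter maximum outer iterations.
#' @param min_nnz_frac minimum fraction of non-zero pixels per retained row.
#' @return The map with `weights` attached and `normalized = TRUE`.
#' @export
kr_balance <- function(map, tol = 1e-8, max_iter = 1000,
                       min_nnz_frac = 0.1) {
  stopifnot(inherits(map, "contact_map"))
  weights <- list()
  for (ch in cm_chroms(map)) {
    m <- cm_dense(map, ch)
    n <- nrow(m)
    nnz <- rowSums(m > 0)
    keep <- nnz / n >= min_nnz_frac & nnz > 0
    w <- rep(NA_real_, n)
    if (sum(keep) >= 2) {
      A <- m[keep, keep, drop = FALSE]
      x <- kr_core(A, tol = tol, max_iter = max_iter)
      if (is.null(x)) x <- sinkhorn_core(A, tol = tol,
                                         max_iter = 50 * max_iter)
      if (is.null(x))
        stop("balancing did not converge for ", ch,
             "; review the sparsity mask (min_nnz_frac)")
      w[keep] <- x
    }
    weights[[ch]] <- w
  }
  map$weights <- weights
  map$normalized <- TRUE
  map
}

# Newton-type inner-outer iteration for symmetric matrix balancing
# (conjugate-gradient inner solves; returns NULL on failure).
kr_core <- function(A, tol = 1e-8, max_iter = 1000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3; g <- 0.9; etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * drop(A %*% x)
  if (any(v <= 0)) return(NULL)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  i <- 0
  while (rout > rt) {
    i <- i + 1
    if (i > max_iter) return(NULL)
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- rk / v
    p <- Z
    rho_km1 <- sum(rk * Z)
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k > 1) {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom == 0) return(NULL)
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > n) break
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta <- g * rat
    if (g * etamax^2 > 0.1) eta <- max(eta, g * etamax^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, stop_tol))
  }
  x
}

# damped symmetric Sinkhorn fixed point: x <- sqrt(x / (A x))
sinkhorn_core <- function(A, tol = 1e-8, max_iter = 50000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    Ax <- drop(A %*% x)
    if (any(Ax <= 0)) return(NULL)
    x <- sqrt(x / Ax)
    if (it %% 10 == 0) {
      r <- x * drop(A %*% x) - 1
      if (sqrt(sum(r * r)) <= tol) return(x)
    }
  }
  r <- x * drop(A %*% x) - 1
  if (sqrt(sum(r * r)) <= tol) x else NULL
}

#' Mean balanced contact per diagonal (distance-decay expectation)
#'
#' Entry `d + 1` of each chromosome's profile is the mean balanced value
#' over all pixels with both bins unmasked at separation `|i - j| = d`
#' (zero-valued pixels included in the mean; empty diagonals are `NA`).
#'
#' @param map a balanced [contact_map()].
#' @return An object of class `expected_profile`: list with `grid` and a
#'   per-chromosome numeric `profile` of length `n_bins`.
#' @export
expected_by_distance <- function(map) {
  if (!map$normalized) stop("map must be balanced first (kr_balance)")
  profile <- list()
  for (ch in cm_chroms(map)) {
    b <- balanced_dense(map, ch)
    n <- nrow(b)
    p <- rep(NA_real_, n)
    for (d in 0:(n - 1)) {
      v <- b[cbind(seq_len(n - d), seq_len(n - d) + d)]
      v <- v[!is.na(v)]
      if (length(v)) p[d + 1] <- mean(v)
    }
    profile[[ch]] <- p
  }
  structure(list(grid = map$grid, profile = profile),
            class = "expected_profile")
}

# dense balanced matrix with NA rows/cols at masked bins
balanced_dense <- function(map, chrom) {
  m <- cm_dense(map, chrom)
  w <- map$weights[[chrom]]
  if (is.null(w)) stop("map has no balancing weights")
  b <- m * outer(w, w)
  b
}

#' Observed-over-expected matrices
#'
#' Divides each balanced pixel by the expected value at its diagonal.
#' Pixels on masked bins or on diagonals with zero/missing expectation are
#' `NA` (never infinite).
#'
#' @param map a balanced [contact_map()].
#' @param profile an [expected_by_distance()] result computed from `map`.
#' @return Named list (by chromosome) of dense symmetric O/E matrices.
#' @export
observed_over_expected <- function(map, profile) {
  if (!same_grid(map$grid, profile$grid))
    stop("profile grid does not match the contact map")
  out <- list()
  for (ch in cm_chroms(map)) {
    b <- balanced_dense(map, ch)
    n <- nrow(b)
    p <- profile$profile[[ch]]
    d <- abs(row(b) - col(b))
    e <- matrix(p[d + 1], n, n)
    oe <- b / e
    oe[!is.finite(oe)] <- NA_real_
    out[[ch]] <- oe
  }
  out
}

#' Write an expected profile as TSV
#'
#' @param profile an [expected_by_distance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expected_profile <- function(profile, path) {
  recs <- lapply(names(profile$profile), function(ch)
    data.frame(chrom = ch,
               distance_bins = seq_along(profile$profile[[ch]]) - 1L,
               expected = profile$profile[[ch]]))
  write_tsv(do.call(rbind, recs), path)
}
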