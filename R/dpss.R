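#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth product
#' `nw`, as the top eigenvectors of the classical symmetric tridiagonal
#' matrix whose eigenvectors are the Slepian sequences. Short windows use a
#' dense symmetric eigendecomposition; long windows use Sturm-sequence
#' bisection for the leading eigenvalues followed by tridiagonal inverse
#' iteration, so the cost stays linear in `n`. Tapers are returned with unit
#' energy (`sum(h^2) = 1`), ordered by decreasing in-band energy
#' concentration, with the conventional polarity (non-negative sum for
#' symmetric tapers, positive leading lobe for antisymmetric ones).
#'
#' @param n taper length in samples (>= 16).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5; `k < 2*nw` for good concentration,
#'   not enforced).
#' @return an `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  n <- as.integer(n)
  stopifnot(n >= 16L, nw > 0, k >= 1, k < n)
  w <- nw / n
  t0 <- 0:(n - 1L)
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  e <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2
  V <- if (n <= 512L) dpss_dense(d, e, k) else dpss_bisect(d, e, k)
  for (j in seq_len(k)) {
    v <- V[, j]
    v <- v / sqrt(sum(v^2))
    if (j %% 2L == 1L) {
      if (sum(v) < 0) v <- -v            # symmetric: non-negative mean
    } else {
      if (sum(v[seq_len(max(2L, n %/% 8L))]) < 0) v <- -v  # antisymmetric
    }
    V[, j] <- v
  }
  V
}

dpss_dense <- function(d, e, k) {
  n <- length(d)
  A <- diag(d)
  A[cbind(1:(n - 1L), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1L))] <- e
  eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
}

# count of eigenvalues below each x, by Sturm sequences (vectorized over x)
sturm_counts <- function(d, e2, xs) {
  m <- length(xs)
  q <- d[1L] - xs
  cnt <- as.integer(q < 0)
  tiny <- 1e-300
  for (i in 2:length(d)) {
    q <- ifelse(abs(q) < tiny, tiny * sign(q + (q == 0)), q)
    q <- d[i] - xs - e2[i - 1L] / q
    cnt <- cnt + (q < 0)
  }
  cnt
}

dpss_bisect <- function(d, e, k) {
  n <- length(d)
  e2 <- e^2
  r <- c(abs(e[1L]), abs(e[-1L]) + abs(e[-(n - 1L)]), abs(e[n - 1L]))
  lo <- rep(min(d - r), k)
  hi <- rep(max(d + r), k)
  want <- n - seq_len(k)        # eigenvalue j-th largest: count below = n - j
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    cnt <- sturm_counts(d, e2, mid)
    below <- cnt <= want        # eigenvalue above mid
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-8 * max(abs(hi), 1)) break
  }
  lam <- (lo + hi) / 2
  Tm <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                           diagonals = list(e, d, e))
  V <- matrix(0, n, k)
  ts <- seq_len(n)
  for (j in seq_len(k)) {
    A <- Tm - Matrix::Diagonal(n, lam[j] * (1 + 1e-9))
    # deterministic start close to the j-th Slepian shape (no RNG use:
    # spectral estimation must not perturb the caller's random stream)
    v <- sin(j * pi * ts / (n + 1))
    v <- v / sqrt(sum(v^2))
    for (it in 1:5) {
      v <- tryCatch(as.numeric(Matrix::solve(A, v)), error = function(err) v)
      # orthogonalize against previously found tapers for safety
      if (j > 1L) v <- v - V[, 1:(j - 1L), drop = FALSE] %*%
          crossprod(V[, 1:(j - 1L), drop = FALSE], v)
      nv <- sqrt(sum(v^2))
      if (!is.finite(nv) || nv == 0) {
        v <- cos(j * pi * ts / (n + 1)); nv <- sqrt(sum(v^2))
      }
      v <- as.numeric(v / nv)
    }
    V[, j] <- v
  }
  V
}
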