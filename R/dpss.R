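# Discrete prolate spheroidal (Slepian) sequences.
#
# Computed from the classic symmetric tridiagonal operator whose eigenvectors
# are the DPSS: diagonal ((N-1-2i)/2)^2 cos(2*pi*W), off-diagonal i(N-i)/2.
# The top-k eigenpairs are found by Sturm-sequence bisection plus inverse
# iteration with tridiagonal solves, O(N) per taper, so tapers for 10-s
# segments at 1250 Hz (N = 12500) take well under a second.

tridiag_count_below <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    if (q == 0) q <- .Machine$double.eps * (abs(e[i - 1]) + 1)
    q <- d[i] - x - e[i - 1]^2 / q
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

tridiag_solve_shifted <- function(d, e, lam, b) {
  n <- length(d)
  dd <- d - lam
  x <- b
  for (i in 1:(n - 1)) {
    if (abs(dd[i]) < 1e-300) dd[i] <- 1e-300
    m <- e[i] / dd[i]
    dd[i + 1] <- dd[i + 1] - m * e[i]
    x[i + 1] <- x[i + 1] - m * x[i]
  }
  if (abs(dd[n]) < 1e-300) dd[n] <- 1e-300
  x[n] <- x[n] / dd[n]
  for (i in (n - 1):1) x[i] <- (x[i] - e[i] * x[i + 1]) / dd[i]
  x
}

dpss_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' Returns the first `k` discrete prolate spheroidal sequences for a given
#' length and time-bandwidth product, unit-normalised and orthonormal, with
#' the usual sign convention (symmetric tapers have positive mean,
#' antisymmetric ones a positive initial slope). Results are cached per
#' `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5); must satisfy `k <= 2 * nw` for the
#'   tapers to remain band-concentrated.
#' @return n x k matrix of tapers, columns orthonormal.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  assert_scalar_num(n, "n", lower = 8)
  assert_scalar_num(nw, "nw", lower = 0, strict = TRUE)
  assert_scalar_num(k, "k", lower = 1)
  if (k > 2 * nw) {
    abort(sprintf(
      "k = %d tapers with nw = %g violates k <= 2*nw; higher-order tapers lose band concentration.",
      k, nw
    ))
  }
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  lo <- min(d - c(0, e) - c(e, 0))
  hi <- max(d + c(0, e) + c(e, 0))
  eigs <- numeric(k)
  for (j in seq_len(k)) {
    a <- lo
    b <- hi
    target <- n - j
    repeat {
      m <- (a + b) / 2
      if (tridiag_count_below(d, e, m) > target) b <- m else a <- m
      if (b - a < 1e-10 * max(abs(a), abs(b), 1)) break
    }
    eigs[j] <- (a + b) / 2
  }
  V <- matrix(0, n, k)
  for (j in seq_len(k)) {
    # deterministic start vector; orthogonalised against earlier tapers
    v <- sin(pi * j * (i + 1) / (n + 1))
    v <- v / sqrt(sum(v^2))
    lam <- eigs[j] * (1 + 1e-12)
    for (it in 1:6) {
      v <- tridiag_solve_shifted(d, e, lam, v)
      if (j > 1) for (q in 1:(j - 1)) v <- v - sum(v * V[, q]) * V[, q]
      v <- v / sqrt(sum(v^2))
    }
    V[, j] <- v
  }
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (V[2, j] - V[1, j] < 0) {
      V[, j] <- -V[, j]
    }
  }
  dpss_cache[[key]] <- V
  V
}
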