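# Small numeric helpers shared across modules. All are deterministic and
# allocation-light; image-scale work stays vectorised.

#' Sliding-window box statistics with missing-value support
#'
#' Computes the local mean and standard deviation of a matrix over a square
#' window via integral images, counting only finite entries. Used by the
#' lumen classifier and kept exact (no FFT round-off).
#'
#' @param x numeric matrix; `NA` entries are excluded from the statistics.
#' @param window odd integer window side length in pixels.
#' @return list with matrices `mean`, `sd` and `n` (valid count per window).
#' @keywords internal
#' @noRd
box_stats <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1L) / 2L
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  cum2 <- function(m) {
    m <- apply(m, 2L, cumsum)
    t(apply(m, 1L, cumsum))
  }
  pad_sum <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    S <- matrix(0, nr + 1L, nc + 1L)
    S[-1L, -1L] <- cum2(m)
    i1 <- pmax(seq_len(nr) - h, 1L); i2 <- pmin(seq_len(nr) + h, nr)
    j1 <- pmax(seq_len(nc) - h, 1L); j2 <- pmin(seq_len(nc) + h, nc)
    S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
      S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  }
  n <- pad_sum(ok + 0)
  s1 <- pad_sum(x0)
  s2 <- pad_sum(x0 * x0)
  mu <- ifelse(n > 0, s1 / n, NA_real_)
  v <- ifelse(n > 1, pmax(0, (s2 - n * mu^2) / (n - 1)), 0)
  list(mean = mu, sd = sqrt(v), n = n)
}

#' Separable 2D Gaussian smoothing (replicate boundary), NA-aware
#' @keywords internal
#' @noRd
gauss_smooth2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  conv1 <- function(m) {
    # convolve columns with k, replicate padding
    nr <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nr, r), , drop = FALSE])
    out <- matrix(0, nr, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[seq_len(nr) + (i - 1L), , drop = FALSE]
    out
  }
  num <- t(conv1(t(conv1(x0))))
  den <- t(conv1(t(conv1(ok + 0))))
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[!ok & den <= 1e-12] <- NA_real_
  out
}

#' Axial (first-dimension) Gaussian blur of a z-by-n matrix or 3D array
#' @keywords internal
#' @noRd
gauss_smooth_axial <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  m <- matrix(a, nrow = d[1L])
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  nz <- d[1L]
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nz, r), , drop = FALSE])
  out <- matrix(0, nz, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[seq_len(nz) + (i - 1L), , drop = FALSE]
  array(out, dim = d)
}

#' Centered moving average with shrinking window at the edges
#' @keywords internal
#' @noRd
moving_average <- function(x, window = 3L) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(x[j])
  }, numeric(1))
}

#' Derive a reproducible 31-bit child seed from a parent seed and an index
#' @keywords internal
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647)
}

stop_enface <- function(class, message, ...) {
  abort(message, class = paste0("enfacechoroid_error_", class), ...)
}
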