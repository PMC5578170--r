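#' Analysis filter pair for a named wavelet
#'
#' Returns the decomposition low-pass filter `g` and the quadrature-mirror
#' high-pass filter `h` for the supported orthogonal wavelets. `h` is derived
#' from `g` by reversing and alternating signs, so the pair forms an
#' orthogonal two-channel filter bank.
#'
#' @param name `"haar"`, `"db2"` or `"db4"` (Daubechies with 2 resp. 4
#'   vanishing moments; filter lengths 2, 4, 8).
#' @return list with `lo`, `hi` (numeric filters), `length`, `name`,
#'   `orthogonal` (always `TRUE` for the shipped families).
#' @export
wavelet_filters <- function(name = c("db4", "db2", "haar")) {
  name <- match.arg(name)
  lo <- switch(name,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079, 0.48296291314453416),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965))
  hi <- rev(lo)
  odd <- seq(1L, length(hi), by = 2L)
  hi[odd] <- -hi[odd]
  list(name = name, lo = lo, hi = hi, length = length(lo), orthogonal = TRUE)
}

# correlate `ext` with filter f and keep every second output starting at the
# second position (the downsampling phase that matches the standard
# filter-bank convention)
.correlate_downsample <- function(ext, f) {
  n_out <- length(ext) - length(f) + 1L
  full <- convolve(ext, f, type = "open")   # sum ext[i+k-1] * f[m-k+1]
  valid <- full[length(f):(length(f) + n_out - 1L)]
  valid[seq(2L, n_out, by = 2L)]
}

# boundary extension of x for one analysis step
.extend_signal <- function(x, flen, mode) {
  n <- length(x)
  switch(mode,
    symmetric = {
      # half-point symmetric: ... x2 x1 | x1 ... xn | xn xn-1 ...
      left <- x[pmin(n, (flen - 1L):1L)]
      right <- x[pmax(1L, n:(n - flen + 2L))]
      c(left, x, right)
    },
    zero = c(numeric(flen - 1L), x, numeric(flen - 1L)),
    periodization = {
      idx_l <- ((n - flen / 2):(n - 1L)) %% n + 1L
      idx_r <- (0:(flen - 1L)) %% n + 1L
      c(x[idx_l], x, x[idx_r])
    },
    stop("unknown boundary mode: ", mode, call. = FALSE))
}

# single analysis step -> list(approx, detail)
.dwt_step <- function(x, filt, mode) {
  ext <- .extend_signal(x, filt$length, mode)
  a <- .correlate_downsample(ext, rev(filt$lo))
  d <- .correlate_downsample(ext, rev(filt$hi))
  if (mode == "periodization") {
    keep <- seq_len(length(x) / 2L)
    a <- a[keep]
    d <- d[keep]
  }
  list(approx = a, detail = d)
}

# number of levels a signal of length n supports under the feasibility rule:
# a step is taken only while the current band is at least one filter long
# (periodization additionally requires an even length at every level, which
# keeps the transform exactly orthogonal)
#' @rdname dwt_decompose
#' @param n signal length.
#' @export
dwt_max_levels <- function(n, wavelet = "db4", mode = "symmetric") {
  filt <- wavelet_filters(wavelet)
  lev <- 0L
  while (n >= filt$length && (mode != "periodization" || n %% 2L == 0L)) {
    n <- if (mode == "periodization") n %/% 2L else (n + filt$length - 1L) %/% 2L
    lev <- lev + 1L
  }
  lev
}

#' Multi-level discrete wavelet transform of a 1-D signal
#'
#' Recursive two-channel filter bank: at each level the current approximation
#' band is correlated with the low-pass and high-pass analysis filters and
#' downsampled by two; level l + 1 is computed from the level-l approximation
#' band only. Boundary handling is half-point symmetric extension by default;
#' `"periodization"` gives an exactly orthogonal transform (coefficient count
#' equals signal length, energy preserved) but requires the band length to be
#' even at every level; `"zero"` pads with zeros.
#'
#' @param x numeric signal.
#' @param wavelet wavelet name, see [wavelet_filters()].
#' @param levels decomposition depth (default 4).
#' @param mode `"symmetric"`, `"periodization"` or `"zero"`.
#' @return a `dwt_decomposition`: list with `approx` and `detail` (lists of
#'   coefficient vectors, one per level), `wavelet`, `mode`, `levels`, and
#'   `input_length`.
#' @examples
#' d <- dwt_decompose(sin(seq(0, 4 * pi, length.out = 64)), "db4", levels = 4)
#' lengths(d$detail)
#' @export
dwt_decompose <- function(x, wavelet = "db4", levels = 4L,
                          mode = c("symmetric", "periodization", "zero")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), levels >= 1L)
  filt <- wavelet_filters(wavelet)
  feasible <- dwt_max_levels(length(x), wavelet, mode)
  if (levels > feasible) {
    stop(sprintf(paste0(
      "signal of length %d supports only %d level(s) with wavelet '%s' ",
      "(mode '%s'); need length >= %d for %d level(s)"),
      length(x), feasible, wavelet, mode,
      .min_length_for_levels(levels, filt$length, mode), levels),
      call. = FALSE)
  }
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  cur <- as.numeric(x)
  for (l in seq_len(levels)) {
    st <- .dwt_step(cur, filt, mode)
    approx[[l]] <- st$approx
    detail[[l]] <- st$detail
    cur <- st$approx
  }
  structure(list(approx = approx, detail = detail, wavelet = wavelet,
                 mode = mode, levels = levels, input_length = length(x)),
            class = "dwt_decomposition")
}

# smallest n with dwt_max_levels(n) >= levels (for the error message)
.min_length_for_levels <- function(levels, flen, mode) {
  n <- flen
  repeat {
    m <- n
    ok <- TRUE
    for (l in seq_len(levels)) {
      if (m < flen || (mode == "periodization" && m %% 2L != 0L)) {
        ok <- FALSE
        break
      }
      m <- if (mode == "periodization") m %/% 2L else (m + flen - 1L) %/% 2L
    }
    if (ok) return(n)
    n <- n + 1L
  }
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  cat(sprintf("%d-level DWT (%s, %s boundary) of a length-%d signal\n",
              x$levels, x$wavelet, x$mode, x$input_length))
  cat("band lengths:",
      paste(sprintf("L%d:%d", seq_len(x$levels), lengths(x$detail)),
            collapse = " "), "\n")
  invisible(x)
}

#' Inverse multi-level DWT
#'
#' Reconstructs the original signal from a [dwt_decompose()] result by
#' running the synthesis filter bank from the deepest level upward. For the
#' orthogonal wavelet families shipped with the package the reconstruction is
#' exact to machine precision in all boundary modes except `"zero"` (which is
#' not information-preserving at the edges).
#'
#' @param decomp a `dwt_decomposition`.
#' @return numeric vector of length `decomp$input_length`.
#' @export
idwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "dwt_decomposition"))
  filt <- wavelet_filters(decomp$wavelet)
  # lengths of the approximation band entering each level
  in_len <- integer(decomp$levels)
  n <- decomp$input_length
  for (l in seq_len(decomp$levels)) {
    in_len[l] <- n
    n <- length(decomp$approx[[l]])
  }
  cur <- decomp$approx[[decomp$levels]]
  for (l in rev(seq_len(decomp$levels))) {
    cur <- .idwt_step(cur, decomp$detail[[l]], filt, decomp$mode, in_len[l])
  }
  cur
}

.idwt_step <- function(a, d, filt, mode, n_out) {
  flen <- filt$length
  if (mode == "periodization") {
    # adjoint of the (orthogonal) circular analysis operator
    x <- numeric(n_out)
    rlo <- rev(filt$lo)
    rhi <- rev(filt$hi)
    for (k in seq_along(a)) {
      pos <- ((2L * k + 0:(flen - 1L) - flen / 2 - 1L) %% n_out) + 1L
      x[pos] <- x[pos] + a[k] * rlo + d[k] * rhi
    }
    return(x)
  }
  upsample <- function(cf) {
    u <- numeric(2L * length(cf))
    u[seq(1L, length(u), by = 2L)] <- cf
    u
  }
  full_conv <- function(u, f) {
    out <- numeric(length(u) + length(f) - 1L)
    for (k in seq_along(f)) {
      out[k:(k + length(u) - 1L)] <- out[k:(k + length(u) - 1L)] + u * f[k]
    }
    out
  }
  y <- full_conv(upsample(a), rev(filt$lo)) + full_conv(upsample(d), rev(filt$hi))
  y <- y[(flen - 1L):length(y)]
  y[seq_len(n_out)]
}

#' Orthonormal DCT-II of a numeric vector
#'
#' \deqn{c_k = s_k \sum_{t=0}^{N-1} x_t \cos[\pi k (2t + 1) / (2N)]}
#' with \eqn{s_0 = \sqrt{1/N}} and \eqn{s_k = \sqrt{2/N}} otherwise, so the
#' transform matrix is orthonormal.
#'
#' @param x numeric vector.
#' @return numeric vector of DCT-II coefficients, same length as `x`.
#' @export
dct_ii <- function(x) {
  n <- length(x)
  stopifnot(n >= 1L)
  k <- 0:(n - 1L)
  t <- 0:(n - 1L)
  basis <- cos(pi * outer(k, 2 * t + 1) / (2 * n))
  coefs <- drop(basis %*% x)
  coefs * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' Leading DCT coefficients of an approximation band
#'
#' The first `n` orthonormal DCT-II coefficients; if the band is shorter than
#' `n` the missing coefficients are zero-filled (with a warning) so that
#' downstream feature vectors keep a fixed length.
#'
#' @param x numeric vector (an approximation band).
#' @param n how many leading coefficients to keep (default 5).
#' @return numeric vector of length `n`.
#' @export
dct_head <- function(x, n = 5L) {
  stopifnot(length(x) >= 1L, n >= 1L)
  coefs <- dct_ii(x)
  if (length(coefs) >= n) {
    coefs[seq_len(n)]
  } else {
    warning(sprintf("band of length %d shorter than %d DCT coefficients; zero-filled",
                    length(x), n), call. = FALSE)
    c(coefs, numeric(n - length(coefs)))
  }
}
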