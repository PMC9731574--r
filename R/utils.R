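# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed (kept below 2^31).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * k) %% 2147483647
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Analytic signal via the frequency-domain method: negative frequencies
# zeroed, positive doubled. Returns a complex vector of the same length.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Wrap angles to [-pi, pi).
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == pi] <- -pi
  y
}

# Gaussian smoothing kernel with a finite support (seconds). The kernel is
# scaled to integrate to 1 over time, so convolving a binary spike series
# sampled at `fs` yields a rate in Hz. `sigma` defaults to support/6 so that
# >= 99.7% of the mass lies inside the support.
gauss_kernel <- function(support, fs, sigma = support / 6) {
  half <- floor(support * fs / 2)
  tt <- (-half:half) / fs
  k <- exp(-tt^2 / (2 * sigma^2))
  k / sum(k) * fs
}

# Convolve each row of `x` with kernel `k` (centered, same-length output).
conv_rows_same <- function(x, k) {
  n <- ncol(x)
  nk <- length(k)
  L <- next_pow2(n + nk)
  K <- stats::fft(c(k, numeric(L - nk)))
  out <- matrix(0, nrow(x), n)
  shift <- (nk - 1) %/% 2
  for (i in seq_len(nrow(x))) {
    X <- stats::fft(c(x[i, ], numeric(L - n)))
    full <- Re(stats::fft(X * K, inverse = TRUE) / L)
    out[i, ] <- full[(1 + shift):(n + shift)]
  }
  out
}

# Bin spike times (seconds, same clock as `t`) into a binary series on the
# sample grid `t`. Spikes outside the grid are dropped.
bin_spikes <- function(spikes, t, fs) {
  n <- length(t)
  y <- numeric(n)
  if (length(spikes) == 0L) return(y)
  idx <- round((spikes - t[1]) * fs) + 1
  idx <- idx[idx >= 1 & idx <= n]
  for (i in idx) y[i] <- y[i] + 1
  y
}

# Indices of `times` on the grid starting at t0 with rate fs (NA if outside).
time_to_index <- function(times, t0, fs, n) {
  idx <- round((times - t0) * fs) + 1
  idx[idx < 1 | idx > n] <- NA_integer_
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
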