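#' @useDynLib dqskit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft uniroot lm coef approx spline splinefun sd mad
#'   quantile optimize setNames rnorm
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal quadrature on an arbitrary (increasing) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Deterministic seed-splitting rule
#'
#' Expands one user-facing seed into independent per-component seeds
#' (ensemble members, sweep points), staying below 2^31:
#' `(seed + 1000003 * k) mod (2^31 - 1)`.
#'
#' @param seed integer base seed.
#' @param k component index.
#' @export
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

stop_config <- function(...) {
  stop(structure(class = c("dqs_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

stop_numerical <- function(...) {
  stop(structure(class = c("dqs_numerical_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# complex interpolant over an omega grid; spline through real and imaginary
# parts (linear fallback for very short grids)
complex_interpolant <- function(omega, value) {
  if (length(omega) >= 4) {
    fr <- stats::splinefun(omega, Re(value), method = "natural")
    fi <- stats::splinefun(omega, Im(value), method = "natural")
  } else {
    fr <- function(w) stats::approx(omega, Re(value), w, rule = 2)$y
    fi <- function(w) stats::approx(omega, Im(value), w, rule = 2)$y
  }
  function(w) complex(real = fr(w), imaginary = fi(w))
}

# largest 5-smooth (2^a 3^b 5^c) integer <= n; R's mixed-radix FFT is
# O(n log n) only for smooth lengths, so series are truncated before FFT
smooth_length <- function(n) {
  for (m in n:1) {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
  }
  1L
}

# Welch-style segment-averaged periodogram (Hann window, 50% overlap).
# Normalised as a two-sided spectral density evaluated at positive
# frequencies: for an equilibrium Ornstein-Uhlenbeck process the
# fluctuation-dissipation ratio omega*C/(2T*R'') evaluates to 1.
welch_psd <- function(x, dt, segments = 8, overlap = 0.5) {
  n <- length(x)
  L <- floor(n / (1 + (segments - 1) * (1 - overlap)))
  L <- smooth_length(max(8, L))
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # Hann
  norm <- sum(w^2) * dt                            # |FT|^2 dt^2 / (sum w^2 dt)
  acc <- numeric(L %/% 2)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    acc <- acc + (Mod(ft[2:(L %/% 2 + 1)])^2) * dt^2 / norm
  }
  omega <- 2 * pi * seq_len(L %/% 2) / (L * dt)
  list(omega = omega, psd = acc / length(starts), n_segments = length(starts))
}

# Savitzky-Golay first-derivative filter on a uniform grid; one-sided
# windows at the record edges.
sg_derivative <- function(y, dt, window = 5, order = 2) {
  n <- length(y)
  if (n < window) stop_config("record too short for smoothing window")
  half <- (window - 1) %/% 2
  d <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    if (hi - lo + 1 < window) { lo <- max(1, hi - window + 1); hi <- min(n, lo + window - 1) }
    t0 <- (seq(lo, hi) - i) * dt
    X <- outer(t0, 0:order, `^`)
    cf <- qr.coef(qr(X), y[lo:hi])
    d[i] <- cf[2]
  }
  d
}
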