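# Internal numerical helpers: circular arithmetic, FFT-based analytic signal,
# moving averages, von Mises sampling.

# wrap angles into (-pi, pi]
wrap_angle <- function(theta) {
  w <- atan2(sin(theta), cos(theta))
  # atan2 returns -pi for odd multiples of pi; convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# signed circular distance a - b wrapped into (-pi, pi]
circ_dist <- function(a, b) wrap_angle(a - b)

# circular mean and resultant length of a vector of angles
circ_mean <- function(theta) Arg(sum(exp(1i * theta)))

circ_resultant <- function(theta) Mod(mean(exp(1i * theta)))

# next fast FFT length (power of two; fine for our sizes)
next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Analytic signal of a real vector via the one-sided spectrum construction:
# double positive frequencies, zero negative ones, keep DC/Nyquist.
fft_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Centered moving average with shrinking windows at the edges.
# kernel k is forced odd so the window is symmetric in the interior.
runmean_shrink <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 reduces
# to the circular uniform. Draws from the session RNG stream.
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, is.finite(kappa))
  if (kappa < 0) abort("`kappa` must be nonnegative.")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nok <- sum(ok)
    if (nok > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1L):(got + nok)] <- theta
      got <- got + nok
    }
  }
  wrap_angle(mu + out)
}

# 1/f^alpha spectrally shaped Gaussian noise, unit variance, zero mean.
# The shaping is flattened below f_floor to keep finite power at DC.
colored_noise <- function(n, fs, alpha, f_floor = 0.1) {
  nfft <- next_pow2(n)
  white <- stats::rnorm(nfft)
  X <- stats::fft(white)
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  shape <- pmax(abs(f), f_floor)^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE) / nfft)[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s] (got %g).", name,
                  format(lower), format(upper), x))
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be an integer.", name))
  }
  invisible(x)
}
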