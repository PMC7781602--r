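# Internal numerical helpers shared across modules.

# Error function via pnorm (better tail behaviour than 1 - exp forms).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# Gauss-Legendre nodes/weights on [0, 1], Golub-Welsch. Cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1) {
    out <- list(x = 0.5, w = 1)
  } else {
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    E <- eigen(J, symmetric = TRUE)
    out <- list(x = (E$values + 1) / 2, w = E$vectors[1, ]^2)
  }
  .gl_cache[[key]] <- out
  out
}

# Exponentially scaled modified Bessel I0(z) * exp(-z). base::besselI is
# the reference but slow at the extremes; use the Taylor series below z = 4
# (18 terms reach machine precision there) and the standard asymptotic
# series beyond z = 50 (relative error < 1e-12), besselI in between.
i0e <- function(z) {
  out <- numeric(length(z))
  sm <- z < 4
  lg <- z >= 50
  md <- !sm & !lg
  if (any(sm)) {
    t <- (z[sm] / 2)^2
    term <- rep(1, length(t)); acc <- term
    for (k in 1:17) { term <- term * t / k^2; acc <- acc + term }
    out[sm] <- acc * exp(-z[sm])
  }
  if (any(md)) out[md] <- besselI(z[md], 0, expon.scaled = TRUE)
  if (any(lg)) {
    zi <- 1 / z[lg]
    out[lg] <- (1 + zi / 8 + 9 * zi^2 / 128 + 75 * zi^3 / 1024 +
                  3675 * zi^4 / 32768) / sqrt(2 * pi * z[lg])
  }
  out
}

# exp(-x) - exp(-y) computed stably when both are tiny or nearly equal.
.expdiff <- function(x, y) exp(-x) * (1 - exp(x - y))

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
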