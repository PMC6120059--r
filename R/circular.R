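# Circular kernel: von Mises density/sampling and the kappa <-> circular-SD
# bijection used by every other module. Internal unit is radians on the full
# circle (-pi, pi]; degrees appear only at I/O boundaries.

#' @keywords internal
KAPPA_MAX <- 700

#' @keywords internal
SD_MAX_DEG <- 1e4

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles onto (-pi, pi]
#'
#' Reduces any finite angle (radians) to its canonical representative on the
#' half-open circle `(-pi, pi]`. Idempotent; the response space of the
#' circular mixture model.
#'
#' @param x Numeric vector of angles in radians. Must be finite.
#' @return Numeric vector of the same length, each element in `(-pi, pi]`.
#' @examples
#' wrap_angle(3 * pi)    # pi
#' wrap_angle(-3 * pi / 2) # pi/2
#' @export
wrap_angle <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("wrap_angle(): input must be finite numeric", call. = FALSE)
  }
  w <- x %% (2 * pi)          # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  # %% can return exactly -pi via rounding of the subtraction; fold to pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' von Mises probability density
#'
#' Density `exp(kappa * cos(x)) / (2 * pi * I0(kappa))` of a von Mises
#' distribution with mean zero and concentration `kappa`, evaluated with
#' exponentially scaled Bessel functions so large `kappa` does not overflow.
#'
#' @param x Angles in radians (wrapped or not; the density is periodic).
#' @param kappa Concentration, a single non-negative number `<= 700`.
#' @return Density values (1/radian).
#' @export
vm_pdf <- function(x, kappa) {
  stopifnot(length(kappa) == 1L, is.finite(kappa))
  if (kappa < 0) stop("vm_pdf(): kappa must be >= 0", call. = FALSE)
  if (kappa > KAPPA_MAX) {
    stop("vm_pdf(): kappa exceeds overflow guard KAPPA_MAX = 700", call. = FALSE)
  }
  # exp(kappa*cos x)/(2 pi I0(kappa)) = exp(kappa*(cos x - 1)) / (2 pi I0.scaled)
  exp(kappa * (cos(x) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Mean resultant length of a von Mises distribution
#'
#' `A1(kappa) = I1(kappa) / I0(kappa)`, computed with scaled Bessel functions.
#'
#' @param kappa Non-negative concentration(s).
#' @return Mean resultant length in `[0, 1)`.
#' @export
a1 <- function(kappa) {
  r <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  r[kappa == 0] <- 0
  r
}

# d A1 / d kappa, used for Newton refinement in a1inv()
a1_prime <- function(kappa) {
  r <- a1(kappa)
  ifelse(kappa == 0, 0.5, 1 - r / kappa - r^2)
}

#' Invert the mean resultant length to a concentration
#'
#' Solves `A1(kappa) = r` with the standard three-branch rational
#' approximation refined by Newton steps to 1e-8. Values `r <= 0` map to
#' `kappa = 0`; the result is capped at `KAPPA_MAX`. Vectorized.
#'
#' @param r Mean resultant length(s) in `[0, 1)`.
#' @return Concentration(s) `kappa >= 0`.
#' @export
a1inv <- function(r) {
  if (any(!is.finite(r))) stop("a1inv(): non-finite input", call. = FALSE)
  .a1inv_cpp(r)
}

#' Concentration to circular standard deviation
#'
#' `sd = sqrt(-2 * log(A1(kappa)))` in radians; strictly decreasing in
#' `kappa`. At `kappa = 0` the circular SD diverges and is capped at
#' `SD_MAX_DEG` (1e4 degrees) so degenerate EM iterates stay finite.
#'
#' @param kappa Non-negative concentration(s).
#' @return Circular standard deviation(s) in radians.
#' @export
kappa_to_sd <- function(kappa) {
  sd_cap <- deg2rad(SD_MAX_DEG)
  vapply(kappa, function(k) {
    if (!is.finite(k) || k < 0) stop("kappa_to_sd(): kappa must be >= 0", call. = FALSE)
    r <- a1(k)
    if (r <= 0) return(sd_cap)
    min(sqrt(-2 * log(r)), sd_cap)
  }, numeric(1))
}

#' Circular standard deviation to concentration
#'
#' Numeric inverse of [kappa_to_sd()]: `kappa = A1inv(exp(-sd^2 / 2))`.
#'
#' @param sd Circular standard deviation(s) in radians, `> 0`.
#' @return Concentration(s).
#' @export
sd_to_kappa <- function(sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("sd_to_kappa(): sd must be finite and > 0", call. = FALSE)
  }
  a1inv(exp(-sd^2 / 2))
}

#' Sample from a von Mises distribution
#'
#' Best–Fisher rejection sampler; `kappa = 0` falls back to the uniform
#' circle. Uses R's global RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration `>= 0`.
#' @return `n` angles in `(-pi, pi]`.
#' @export
vm_sample <- function(n, mu = 0, kappa = 1) {
  stopifnot(length(n) == 1L, n >= 1, length(kappa) == 1L, kappa >= 0,
            kappa <= KAPPA_MAX, is.finite(mu))
  if (kappa == 0) {
    return(wrap_angle(stats::runif(n, -pi, pi)))
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    ccf <- kappa * (rr - f)
    keep <- (ccf * (2 - ccf) - u2 > 0) | (log(ccf / u2) + 1 - ccf >= 0)
    f <- f[keep]
    u3 <- u3[keep]
    if (length(f) > 0L) {
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      take <- seq_len(min(length(theta), n - got))
      out[got + take] <- theta[take]
      got <- got + length(take)
    }
  }
  wrap_angle(out + mu)
}

#' Circular summary statistics of a sample
#'
#' Mean resultant length and circular standard deviation of a vector of
#' angles (radians).
#'
#' @param x Angles in radians.
#' @return List with `r` (mean resultant length), `mean` (mean direction,
#'   radians) and `sd` (circular SD, radians).
#' @export
circ_stats <- function(x) {
  c_ <- mean(cos(x))
  s_ <- mean(sin(x))
  r <- sqrt(c_^2 + s_^2)
  list(
    r = r,
    mean = atan2(s_, c_),
    sd = if (r > 0) sqrt(-2 * log(r)) else deg2rad(SD_MAX_DEG)
  )
}
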