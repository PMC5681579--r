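# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different numerics than the implementation:
# the rectangle potential integral is checked by 1D analytic reduction
# (asinh) + adaptive quadrature over y, the ellipse perimeter by the
# complete elliptic integral, smoothing by brute-force discrete
# convolution.

# int over [xlo,xhi] x [-q,q] of dx dy / sqrt((x-xe)^2 + y^2),
# computed as 2 * int_0^q [asinh((xhi-xe)/y) - asinh((xlo-xe)/y)] dy.
# The y -> 0 log divergence (electrode inside/on the x-range) is
# integrable; adaptive quadrature handles it.
oracle_rect_integral <- function(xlo, xhi, q, xe) {
  inner <- function(y) asinh((xhi - xe) / y) - asinh((xlo - xe) / y)
  2 * stats::integrate(function(y) vapply(y, inner, numeric(1)),
                       0, q, rel.tol = 1e-9)$value
}

# exact ellipse perimeter: 4 a E(e), via numerical elliptic integral
oracle_ellipse_perimeter <- function(a, b) {
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  e2 <- 1 - (b / a)^2
  4 * a * stats::integrate(function(t) sqrt(1 - e2 * sin(t)^2),
                           0, pi / 2, rel.tol = 1e-12)$value
}

# brute-force zero-phase discrete convolution with reflect padding
oracle_gaussian_smooth <- function(x, width_s, rate_hz) {
  sd_samp <- width_s * rate_hz
  half <- ceiling(4 * sd_samp)
  kern <- dnorm(seq(-half, half), sd = sd_samp)
  kern <- kern / sum(kern)
  n <- length(x)
  xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(xp[i:(i + 2 * half)] * rev(kern))
  }
  out
}

test_geometry <- function(length_mm = 0.6, width_mm = 0.3,
                          thickness_mm = 0.25, ...) {
  funiculus_geometry(length_mm, width_mm, thickness_mm, ...)
}

random_geometry <- function(seed) {
  set.seed(seed)
  funiculus_geometry(
    length_mm = runif(1, 0.2, 1.5),
    width_mm = runif(1, 0.1, 0.6),
    thickness_mm = runif(1, 0.08, 0.5),
    sigma = runif(1, 1, 50)
  )
}

# participation ratio: (sum w)^2 / sum(w^2); 1 = all mass in one bin,
# N = evenly spread. The spatial-spread summary used for the
# CSD-sharper-than-EAG contract.
participation_ratio <- function(w) {
  w <- abs(w)
  sum(w)^2 / sum(w^2)
}
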