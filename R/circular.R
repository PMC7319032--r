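# Circular error coding and the von Mises + uniform mixture density.

#' Signed response error relative to target and distractor
#'
#' Computes the circular difference between a reported and a true orientation,
#' with the sign recoded so that positive errors point from the target toward
#' the distractor (the direction of a potential attraction bias) and negative
#' errors point away from it.
#'
#' @param response reported orientation in degrees (any representative on the
#'   360 degree circle).
#' @param target true orientation of the probed item, degrees.
#' @param distractor orientation of the unprobed item, degrees. Must differ
#'   from `target` on the circle, otherwise the sign is undefined.
#' @return signed error in degrees in (-180, 180]. Vectorized over all three
#'   arguments; `NA` responses propagate.
#' @examples
#' signed_error(110, 100, 140) # +10, toward the distractor
#' signed_error(355, 10, 350)  # +15, across the 360 wrap
#' @export
signed_error <- function(response, target, distractor) {
  n <- max(length(response), length(target), length(distractor))
  response <- rep_len(response, n)
  target <- rep_len(target, n)
  distractor <- rep_len(distractor, n)
  d_dt <- circ_diff(distractor, target)
  if (any(d_dt == 0, na.rm = TRUE)) {
    stop("signed_error(): target and distractor coincide; sign toward the distractor is undefined")
  }
  d_rt <- circ_diff(response, target)
  out <- ifelse(sign(d_rt) == sign(d_dt) | d_rt == 0, abs(d_rt), -abs(d_rt))
  # keep the convention that exactly opposite responses (180) are positive
  out[!is.na(d_rt) & abs(d_rt) == 180] <- 180
  out
}

# von Mises density per *degree*: exp(kappa cos(x - mu)) / (360 I0(kappa)),
# with the cosine argument converted to radians. Computed with the
# exponentially scaled Bessel function so large kappa never overflows.
dvonmises_deg <- function(x, mu, kappa) {
  z <- cos((x - mu) * pi / 180)
  exp(kappa * (z - 1)) / (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Density of the bias-extended standard mixture model
#'
#' Mixture of a uniform guessing component (probability `g`) and a von Mises
#' memory component with concentration `kappa` and bias `mu` (degrees, positive
#' toward the distractor). The density is expressed per degree, i.e. the von
#' Mises normalization is `360 * I0(kappa)`, so the mixture integrates to 1
#' over (-180, 180].
#'
#' @param x signed errors in degrees.
#' @param kappa concentration of the von Mises component, > 0 (kappa = 0 is
#'   accepted and gives the uniform density).
#' @param mu bias in degrees in (-180, 180].
#' @param g guess probability in \[0, 1\].
#' @param log if `TRUE`, return the log density.
#' @return density per degree (strictly positive, never non-finite).
#' @examples
#' mixture_pdf(0, kappa = 0, mu = 0, g = 0) # 1/360
#' @export
mixture_pdf <- function(x, kappa, mu, g, log = FALSE) {
  stopifnot(kappa >= 0, g >= 0, g <= 1)
  z <- cos((x - mu) * pi / 180)
  # log von Mises density per degree, stable for arbitrarily large kappa
  log_vm <- kappa * (z - 1) - base::log(360) -
    base::log(besselI(kappa, 0, expon.scaled = TRUE))
  if (!log) return(g / 360 + (1 - g) * exp(log_vm))
  if (g == 0) return(log_vm)
  a <- base::log(g / 360)
  b <- if (g < 1) base::log(1 - g) + log_vm else rep(-Inf, length(log_vm))
  m <- pmax(a, b)
  m + base::log(exp(a - m) + exp(b - m))
}

#' Sample from a von Mises distribution in degrees
#'
#' Best-Fisher rejection sampler; exact for all `kappa`, falling back to the
#' circular uniform for vanishing concentration. Angles are returned wrapped
#' to (-180, 180].
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration, >= 0.
#' @return numeric vector of angles in degrees.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-9) return(wrap180(stats::runif(n, -180, 180) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]
    if (length(f)) {
      u3 <- stats::runif(length(f))
      theta <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
      out <- c(out, theta * 180 / pi)
    }
  }
  wrap180(out[seq_len(n)] + mu)
}

#' Sample signed errors from the mixture model
#'
#' With probability `g` a draw is uniform on (-180, 180]; otherwise von Mises
#' with concentration `kappa` and mean `mu`.
#'
#' @param n number of draws.
#' @param kappa,mu,g mixture parameters (see [mixture_pdf()]).
#' @return numeric vector of signed errors in degrees.
#' @export
rmixture <- function(n, kappa, mu, g) {
  guess <- stats::runif(n) < g
  x <- numeric(n)
  x[guess] <- stats::runif(sum(guess), -180, 180)
  x[!guess] <- rvonmises_deg(sum(!guess), mu, kappa)
  x
}
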