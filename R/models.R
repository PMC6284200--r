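# Probability models: negative binomial and double Poisson (DP).
#
# The DP density is Efron's exponential-dispersion extension of the Poisson.
# Its approximate form is
#   f(y; mu, theta) = sqrt(theta) e^{-theta mu} (e^{-y} y^y / y!) (e mu / y)^{theta y}
# with the y = 0 factors read as 1, and the exact density multiplies f by a
# normalizing constant c(mu, theta) close to 1.  Mean ~ mu, variance = mu/theta,
# so theta > 1 is underdispersion, theta = 1 Poisson, 0 < theta < 1
# overdispersion.  All work is done in log space: counts up to 1e6 must not
# overflow, and lgamma() stands in for factorials.

# log of e^{-y} y^y / y!, the saturated Poisson term; 1 at y = 0
.ldpois_sat <- function(y) {
  out <- -y + y * log(pmax(y, 1)) - lgamma(y + 1)
  out[y == 0] <- 0
  out
}

# unnormalized DP log density (vector y, scalar mu > 0, theta > 0)
.dp_lpmf_raw <- function(y, mu, theta) {
  out <- numeric(length(y))
  pos <- y > 0
  yp <- y[pos]
  ly <- log(yp)
  out[pos] <- -yp + yp * ly - lgamma(yp + 1) + theta * yp * (1 + log(mu) - ly)
  out + (0.5 * log(theta) - theta * mu)
}

# closed-form 1/c(mu, theta); a second-order expansion valid for large mu*theta
.dp_inv_c_approx <- function(mu, theta) {
  1 + (1 - theta) / (12 * mu * theta) * (1 + 1 / (mu * theta))
}

# scalar unnormalized DP log density, kept free of allocations for the
# support search below
.dp_lp1 <- function(y, mu, theta) {
  if (y == 0) return(0.5 * log(theta) - theta * mu)
  ly <- log(y)
  0.5 * log(theta) - theta * mu - y + y * ly - lgamma(y + 1) +
    theta * y * (1 + log(mu) - ly)
}

# support window [lo, hi] centered on the mode (~mu), initially 20 SDs wide
# on each side and widened adaptively until the log density sits 14 orders of
# magnitude below the peak (the overdispersed right tail decays like
# exp(-theta*y*log(y)), slower than Gaussian, so a fixed SD multiple is not
# enough at small mu*theta); numerically identical to summing from zero
.dp_support <- function(mu, theta) {
  sdv <- sqrt(mu / theta)
  lo <- max(0, floor(mu - 20 * sdv))
  hi <- max(50, ceiling(mu + 20 * sdv))
  peak <- .dp_lp1(max(1, round(mu)), mu, theta)
  drop <- log(1e-14)
  while (hi < 1e8 && .dp_lp1(hi, mu, theta) - peak > drop) {
    hi <- ceiling(hi * 1.5)
  }
  while (lo > 0 && .dp_lp1(lo, mu, theta) - peak > drop) {
    lo <- max(0, floor(lo - 5 * sdv))
  }
  c(lo, hi)
}

.dp_inv_c_sum <- function(mu, theta) {
  w <- .dp_support(mu, theta)
  sum(exp(.dp_lpmf_raw(w[1]:w[2], mu, theta)))
}

# log c for likelihood work.  The closed form is used only where it has been
# verified accurate (mu >= 10, mu*theta >= 3, theta <= 20: rel. error < 0.4%).
# Elsewhere the support is summed directly; when the window holds more than
# 512 integers the summand is smooth on that scale and a strided midpoint
# sum is used (relative error ~ (stride/SD)^2 / 24, < 1e-3 here).
.dp_log_c <- function(mu, theta) {
  if (mu >= 10 && mu * theta >= 3 && theta <= 20) {
    return(-log(.dp_inv_c_approx(mu, theta)))
  }
  w <- .dp_support(mu, theta)
  len <- w[2] - w[1] + 1
  k <- if (len > 512) ceiling(len / 512) else 1L
  y <- seq.int(w[1], w[2], by = k)
  if (y[1] == 0L) y <- y[-1L]
  ly <- log(y)
  lp <- -theta * mu - y + y * ly - lgamma(y + 1) + theta * y * (1 + log(mu) - ly)
  s <- sum(exp(lp))
  if (w[1] == 0L) s <- s + exp(-theta * mu)
  -(0.5 * log(theta) + log(s * k))
}

.check_counts_vec <- function(y) {
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(y != floor(y))) stop("counts must be integers", call. = FALSE)
}

#' Negative binomial log probability mass function
#'
#' Log pmf of the NB model parameterized by mean `mu` and dispersion `phi`,
#' with variance `mu + mu^2 * phi`.  `phi` below `1e-10` is treated as exactly
#' Poisson, the `phi -> 0` limit, avoiding overflow of `gamma(1/phi)`.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Mean (scalar, `>= 0`).
#' @param phi NB dispersion (scalar, `>= 0`).
#' @return Numeric vector of log-probabilities, one per element of `y`.
#' @examples
#' nb_log_pmf(0:3, mu = 2, phi = 0.5)
#' nb_log_pmf(0, mu = 2, phi = 0)  # Poisson limit: -2
#' @export
nb_log_pmf <- function(y, mu, phi) {
  .check_counts_vec(y)
  if (length(mu) != 1L || length(phi) != 1L) stop("mu and phi must be scalars", call. = FALSE)
  if (phi < 0) stop("phi must be non-negative", call. = FALSE)
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (mu == 0) return(ifelse(y == 0, 0, -Inf))
  if (phi < 1e-10) {
    dpois(y, lambda = mu, log = TRUE)
  } else {
    dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
  }
}

#' Double Poisson log probability mass function
#'
#' Log pmf of the DP model with mean `mu` and dispersion `theta` (variance
#' `mu / theta`).  With `exact = FALSE` the approximate density is returned;
#' with `exact = TRUE` (default) it is multiplied by the normalizing constant
#' `c(mu, theta)` obtained by truncated summation, so that the pmf sums to one
#' over the support.  The Poisson model is the `theta = 1` special case.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Mean (scalar, `>= 0`).
#' @param theta DP dispersion (scalar, `> 0`).
#' @param exact Multiply by the normalizing constant? Default `TRUE`.
#' @return Numeric vector of log-probabilities.
#' @examples
#' dp_log_pmf(0, mu = 1, theta = 1, exact = FALSE)  # -1
#' dp_log_pmf(0:5, mu = 2, theta = 2)
#' @export
dp_log_pmf <- function(y, mu, theta, exact = TRUE) {
  .check_counts_vec(y)
  if (length(mu) != 1L || length(theta) != 1L) stop("mu and theta must be scalars", call. = FALSE)
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (mu == 0) return(ifelse(y == 0, 0, -Inf))
  out <- .dp_lpmf_raw(y, mu, theta)
  if (exact) out <- out - log(.dp_inv_c_sum(mu, theta))
  out
}

#' Double Poisson normalizing constant
#'
#' The constant `c(mu, theta)` that turns the approximate DP density into a
#' proper pmf.  `mode = "approx"` uses the closed-form expansion
#' `1/c = 1 + (1 - theta) / (12 mu theta) * (1 + 1 / (mu theta))`, reliable for
#' large means; `mode = "exact"` sums the unnormalized density over a truncated
#' support.
#'
#' @param mu Mean (scalar, `> 0`).
#' @param theta DP dispersion (scalar, `> 0`).
#' @param mode `"exact"` (truncated summation, default) or `"approx"`.
#' @return The scalar normalizing constant `c(mu, theta)`.
#' @examples
#' dp_normalizer(10, 0.5, mode = "approx")  # 1 / 1.01
#' dp_normalizer(10, 0.5, mode = "exact")
#' @export
dp_normalizer <- function(mu, theta, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  if (length(mu) != 1L || length(theta) != 1L) stop("mu and theta must be scalars", call. = FALSE)
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive (normalizer undefined at mu = 0)", call. = FALSE)
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  inv <- if (mode == "approx") .dp_inv_c_approx(mu, theta) else .dp_inv_c_sum(mu, theta)
  if (inv <= 0) {
    stop("closed-form normalizer invalid in this regime (mu*theta too small); use mode = \"exact\"",
         call. = FALSE)
  }
  1 / inv
}

#' Model mean and variance
#'
#' Moments implied by the NB (`variance = mu + mu^2 * dispersion`) or DP
#' (`variance = mu / dispersion`) parameterization.
#'
#' @param mu Vector of means.
#' @param dispersion Vector of dispersions (`phi` for NB, `theta` for DP),
#'   recycled against `mu`.
#' @param family `"DP"` or `"NB"`.
#' @return A tibble with columns `mean` and `variance`.
#' @examples
#' model_moments(10, 0.1, family = "NB")  # variance 20
#' model_moments(10, 2, family = "DP")    # variance 5
#' @export
model_moments <- function(mu, dispersion, family = c("DP", "NB")) {
  family <- match.arg(family)
  if (any(mu < 0)) stop("mu must be non-negative", call. = FALSE)
  if (family == "NB") {
    if (any(dispersion < 0)) stop("NB dispersion must be non-negative", call. = FALSE)
    v <- mu + mu^2 * dispersion
  } else {
    if (any(dispersion <= 0)) stop("DP dispersion must be positive", call. = FALSE)
    v <- mu / dispersion
  }
  tibble(mean = as.numeric(mu + 0 * v), variance = as.numeric(v))
}

# exact DP pmf table over the truncated support, normalized to sum to one;
# returns the support start and the probabilities
.dp_pmf_table <- function(mu, theta) {
  w <- .dp_support(mu, theta)
  raw <- exp(.dp_lpmf_raw(w[1]:w[2], mu, theta))
  s <- sum(raw)
  if (raw[length(raw)] / s > 1e-12 || (w[1] > 0 && raw[1] / s > 1e-12)) {
    stop("DP support truncation failed to capture the distribution mass", call. = FALSE)
  }
  list(offset = w[1], p = raw / s)
}

#' Sample counts from the double Poisson distribution
#'
#' Inverse-CDF draws from the exact (normalized) DP pmf over a truncated
#' support.  Identical seeds give identical output.
#'
#' @param n Number of draws.
#' @param mu Mean (scalar, `>= 0`).
#' @param theta DP dispersion (scalar, `> 0`).
#' @param seed Optional integer seed set before drawing.
#' @return Integer vector of `n` counts.
#' @examples
#' dp_sample(10, mu = 5, theta = 2, seed = 1)
#' @export
dp_sample <- function(n, mu, theta, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (mu == 0) return(integer(n))
  tab <- .dp_pmf_table(mu, theta)
  tab$offset + findInterval(runif(n), cumsum(tab$p))
}
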