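#' Annihilation-pathway decay model
#'
#' A positron entering tissue annihilates through several pathways: direct
#' annihilation, para-positronium (p-Ps) and ortho-positronium (o-Ps). Each
#' pathway `l` contributes an exponential lifetime component with intensity
#' `A_l` (the fraction of annihilations through that pathway) and annihilation
#' rate `lambda_l = 1/lifetime_l`. The lifetime measurement density is the
#' intensity-weighted exponential mixture convolved with the Gaussian detector
#' timing response (see [spectrum_pdf()]).
#'
#' @param intensities Numeric vector of pathway fractions `A_l`; must be
#'   nonnegative and sum to 1 (tolerance 1e-9).
#' @param lifetimes Numeric vector of pathway lifetimes in ns (`1/lambda_l`);
#'   must be positive and the same length as `intensities`.
#' @param labels Optional character vector of pathway names; defaults to
#'   `"o"`, `"p"`, `"d"` for three components, else `"c1"`, `"c2"`, ...
#'
#' @return An object of class `decay_model` with fields `intensities`,
#'   `lifetimes`, `rates` and `labels`.
#' @examples
#' lesion <- decay_model(c(0.30, 0.10, 0.60), c(2.0, 0.125, 0.4))
#' mean_lifetime(lesion) # 0.8525 ns
#' @export
decay_model <- function(intensities, lifetimes, labels = NULL) {
  intensities <- as.numeric(intensities)
  lifetimes <- as.numeric(lifetimes)
  if (length(intensities) != length(lifetimes))
    stop("`intensities` and `lifetimes` must have equal length")
  if (any(intensities < 0))
    stop("pathway intensities must be nonnegative")
  if (abs(sum(intensities) - 1) > 1e-9)
    stop("pathway intensities must sum to 1 (got ", sum(intensities), ")")
  if (any(lifetimes <= 0))
    stop("pathway lifetimes must be positive")
  if (is.null(labels)) {
    labels <- if (length(lifetimes) == 3L) c("o", "p", "d")
              else paste0("c", seq_along(lifetimes))
  }
  if (length(labels) != length(lifetimes))
    stop("`labels` must match the number of pathways")
  structure(
    list(intensities = intensities, lifetimes = lifetimes,
         rates = 1 / lifetimes, labels = as.character(labels)),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Decay model (", length(x$rates), " pathways)\n", sep = "")
  for (l in seq_along(x$rates))
    cat(sprintf("  %-3s A = %.4f  lifetime = %.4g ns\n",
                x$labels[l], x$intensities[l], x$lifetimes[l]))
  cat(sprintf("  mean positron lifetime: %.4f ns\n", mean_lifetime(x)))
  invisible(x)
}

#' Gaussian detector timing response
#'
#' The lifetime measurement of a triple coincidence is blurred by detector
#' timing jitter and residual travel-time-correction error, modelled as a
#' single effective Gaussian with standard deviation `sigma` centred at the
#' scanner timing offset `mu` (the systematic delay between the prompt-gamma
#' and 511-keV timing chains).
#'
#' @param sigma Effective Gaussian standard deviation, ns (`>= 0`).
#' @param mu Timing offset, ns.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(sigma = 0.092, mu = 0) {
  sigma <- as.numeric(sigma); mu <- as.numeric(mu)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be a single nonnegative number (ns)")
  if (length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a single finite number (ns)")
  structure(list(sigma = sigma, mu = mu), class = "timing_model")
}

#' Reconstruction and randoms-correction time windows
#'
#' Lifetime measurements inside the reconstruction window `[t_r1, t_r2]` are
#' used to build the sinogram data; measurements inside the disjoint,
#' shifted correction window `[t_c1, t_c2]` are dominated by type I random
#' coincidences (whose lifetime measurements are uniformly distributed) and
#' are only counted, to estimate the randoms contamination.
#'
#' @param recon Length-2 numeric, `c(t_r1, t_r2)` in ns.
#' @param correction Length-2 numeric, `c(t_c1, t_c2)` in ns; must not overlap
#'   the reconstruction window.
#' @return An object of class `time_windows`.
#' @export
time_windows <- function(recon = c(-1, 15), correction = c(-20, -5)) {
  recon <- as.numeric(recon); correction <- as.numeric(correction)
  if (length(recon) != 2L || recon[1] >= recon[2])
    stop("reconstruction window must be c(t_r1, t_r2) with t_r1 < t_r2")
  if (length(correction) != 2L || correction[1] >= correction[2])
    stop("correction window must be c(t_c1, t_c2) with t_c1 < t_c2")
  if (recon[1] <= correction[2] && correction[1] <= recon[2])
    stop("correction window must be disjoint from the reconstruction window")
  structure(list(t_r1 = recon[1], t_r2 = recon[2],
                 t_c1 = correction[1], t_c2 = correction[2]),
            class = "time_windows")
}

# scaled complementary error function, stable for large positive x
# (switches to the asymptotic series where exp(x^2) would overflow)
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  lo <- x < 15
  if (any(lo)) {
    xl <- x[lo]
    out[lo] <- exp(xl^2) * 2 * pnorm(-xl * sqrt(2))
  }
  if (any(!lo)) {
    xh <- x[!lo]
    u <- 1 / (2 * xh^2)
    out[!lo] <- (1 - u + 3 * u^2 - 15 * u^3 + 105 * u^4) / (xh * sqrt(pi))
  }
  out
}

#' Exponentially-modified-Gaussian lifetime component
#'
#' Closed-form convolution of a one-sided exponential `rate * exp(-rate*t)`
#' (for `t > 0`) with a Gaussian of mean `mu` and sd `sigma`: the density of
#' `T + G` with `T ~ Exp(rate)` and `G ~ N(mu, sigma^2)`. Evaluated in the
#' numerically stabilised erfcx form, exact for `sigma = 0`.
#'
#' @param tau Evaluation times, ns.
#' @param rate Exponential rate, 1/ns.
#' @param mu Gaussian mean (timing offset), ns.
#' @param sigma Gaussian sd, ns.
#' @return Density values, 1/ns.
#' @export
emg_density <- function(tau, rate, mu = 0, sigma = 0) {
  if (sigma <= 0) {
    d <- ifelse(tau >= mu, rate * exp(-rate * (tau - mu)), 0)
    return(as.numeric(d))
  }
  v <- (mu + rate * sigma^2 - tau) / (sigma * sqrt(2))
  out <- numeric(length(tau))
  neg <- v <= 0
  if (any(neg)) {
    a <- rate * (mu - tau[neg]) + 0.5 * rate^2 * sigma^2
    out[neg] <- 0.5 * rate * exp(a) * (2 * pnorm(-v[neg] * sqrt(2)))
  }
  if (any(!neg)) {
    out[!neg] <- 0.5 * rate * exp(-(tau[!neg] - mu)^2 / (2 * sigma^2)) *
      erfcx_stable(v[!neg])
  }
  out
}

#' Lifetime-measurement spectrum density
#'
#' Probability density of the lifetime measurement of a true triple
#' coincidence: the Gaussian timing response convolved with the
#' intensity-weighted mixture of exponential pathway components,
#' `g(tau - mu) * sum_l A_l lambda_l exp(-lambda_l tau) u(tau)`,
#' evaluated in closed form component-wise via [emg_density()]. Integrates
#' to 1 over the real line.
#'
#' @param tau Evaluation times, ns (vectorised).
#' @param model A [decay_model()].
#' @param timing A [timing_model()].
#' @return Density values, 1/ns.
#' @export
spectrum_pdf <- function(tau, model, timing = timing_model(0, 0)) {
  stopifnot(inherits(model, "decay_model"), inherits(timing, "timing_model"))
  d <- numeric(length(tau))
  for (l in seq_along(model$rates))
    d <- d + model$intensities[l] *
      emg_density(tau, model$rates[l], timing$mu, timing$sigma)
  d
}

#' Mean positron lifetime of a decay model
#'
#' The positron lifetime is the pathway-intensity-weighted mean lifetime,
#' `sum_l A_l / lambda_l`; the timing offset `mu` cancels because it is
#' subtracted from the spectrum mean.
#'
#' @param model A [decay_model()].
#' @return Mean lifetime, ns.
#' @examples
#' mean_lifetime(decay_model(c(0.3, 0.1, 0.6), c(2.5, 0.125, 0.4))) # 1.0025
#' @export
mean_lifetime <- function(model) {
  stopifnot(inherits(model, "decay_model"))
  sum(model$intensities * model$lifetimes)
}

#' Sample lifetime measurements
#'
#' Draws a pathway from the categorical intensity distribution, an
#' exponential delay at the pathway rate, and adds Gaussian timing noise
#' `N(mu, sigma^2)`.
#'
#' @param n Number of draws.
#' @param model A [decay_model()].
#' @param timing A [timing_model()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` lifetime measurements, ns.
#' @export
sample_lifetime <- function(n, model, timing = timing_model(0, 0), seed = NULL) {
  stopifnot(inherits(model, "decay_model"), inherits(timing, "timing_model"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  path <- sample.int(length(model$rates), n, replace = TRUE,
                     prob = model$intensities)
  tau <- rexp(n, rate = 1) / model$rates[path]
  if (timing$sigma > 0) tau <- tau + rnorm(n, 0, timing$sigma)
  tau + timing$mu
}

#' Cumulative distribution of the lifetime spectrum
#'
#' Closed-form CDF of [spectrum_pdf()] (mixture of EMG CDFs), used for
#' distributional goodness-of-fit checks.
#'
#' @inheritParams spectrum_pdf
#' @return CDF values in `[0, 1]`.
#' @export
spectrum_cdf <- function(tau, model, timing = timing_model(0, 0)) {
  stopifnot(inherits(model, "decay_model"), inherits(timing, "timing_model"))
  mu <- timing$mu; sg <- timing$sigma
  out <- numeric(length(tau))
  for (l in seq_along(model$rates)) {
    r <- model$rates[l]
    if (sg <= 0) {
      Fl <- ifelse(tau >= mu, 1 - exp(-r * (tau - mu)), 0)
    } else {
      u <- (tau - mu) / sg
      # F(t) = Phi(u) - emg tail term, stabilised like the density
      v <- (mu + r * sg^2 - tau) / (sg * sqrt(2))
      term <- numeric(length(tau))
      neg <- v <= 0
      if (any(neg)) {
        a <- r * (mu - tau[neg]) + 0.5 * r^2 * sg^2
        term[neg] <- 0.5 * exp(a) * (2 * pnorm(-v[neg] * sqrt(2)))
      }
      if (any(!neg)) {
        term[!neg] <- 0.5 * exp(-u[!neg]^2 / 2) * erfcx_stable(v[!neg])
      }
      Fl <- pnorm(u) - term
    }
    out <- out + model$intensities[l] * Fl
  }
  pmin(pmax(out, 0), 1)
}
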