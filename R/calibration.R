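#' Histogram a lifetime spectrum
#'
#' Fixed-width binning of lifetime measurements over a closed range; values
#' outside the range are dropped.
#'
#' @param taus Lifetime measurements, ns.
#' @param bin_width Bin width, ns (default 0.05 = 50 ps).
#' @param range Length-2 numeric histogram range, ns.
#' @return List with bin `centers` (ns) and integer `counts`;
#'   `sum(counts)` equals the number of measurements in range.
#' @export
histogram_spectrum <- function(taus, bin_width = 0.05, range = c(-15, 15)) {
  if (length(taus) == 0L) stop("empty lifetime spectrum")
  if (bin_width <= 0) stop("`bin_width` must be positive (ns)")
  n_b <- ceiling(diff(range) / bin_width)
  edges <- range[1] + bin_width * (0:n_b)
  keep <- taus >= range[1] & taus <= edges[n_b + 1]
  idx <- pmin(floor((taus[keep] - range[1]) / bin_width) + 1, n_b)
  list(centers = edges[-1] - bin_width / 2,
       counts = tabulate(idx, n_b))
}

#' Two-component spectrum model for offset calibration
#'
#' Evaluates `G * (g(tau - mu) * sum_l A_l lambda_l exp(-lambda_l tau) u(tau)
#' + b)`: a two-pathway exponential mixture convolved with the Gaussian
#' timing response, plus a uniform background level `b` accounting for
#' type I randoms, scaled by `G` to the histogram intensity.
#'
#' @param tau Evaluation times, ns.
#' @param pars Named list/vector with `lambda1`, `lambda2` (1/ns), `a1`
#'   (fraction of component 1; `a2 = 1 - a1`), `b` (background, 1/ns),
#'   `g` (scale), `mu` (ns), `sigma` (ns).
#' @return Model values.
#' @export
spectrum_model <- function(tau, pars) {
  pars <- as.list(pars)
  mix <- pars$a1 * emg_density(tau, pars$lambda1, pars$mu, pars$sigma) +
    (1 - pars$a1) * emg_density(tau, pars$lambda2, pars$mu, pars$sigma)
  pars$g * (mix + pars$b)
}

#' Fit the scanner timing offset from a lifetime spectrum
#'
#' Minimises the count-weighted least-squares loss
#' `sum_i (1/n_i) (p1(tau_i | theta) - n_i)^2` over the histogram bins
#' (zero-count bins are excluded: their weight is undefined), with the
#' two-component model of [spectrum_model()]. The loss is non-convex in the
#' offset `mu`, so a local Levenberg-Marquardt fit is run from a grid of
#' `mu` starting values and the best solution kept.
#'
#' @param centers,counts Histogram bin centers (ns) and counts, as from
#'   [histogram_spectrum()].
#' @param init Named list of starting values (`lambda1`, `lambda2`, `a1`,
#'   `b`, `g`, `mu`, `sigma`); missing entries get moment-based defaults.
#' @param fix_sigma Fix `sigma` at its initial value instead of fitting it.
#' @param mu_grid Starting offsets for the multi-start, ns.
#' @return List of class `spectrum_fit`: fitted `pars`, `loss`, `n_bins_fit`
#'   and `converged`. Errors if no start converges; flags (with a warning
#'   and `mu = NA`) a spectrum whose exponential amplitude is consistent
#'   with zero, where `mu` is unidentifiable.
#' @export
fit_offset <- function(centers, counts, init = list(), fix_sigma = FALSE,
                       mu_grid = seq(-0.5, 0.5, by = 0.25)) {
  use <- counts > 0
  if (sum(use) < 8L) stop("too few nonzero histogram bins to fit")
  tc <- centers[use]; nc <- counts[use]
  bw <- stats::median(diff(centers))
  n_tot <- sum(nc)
  defaults <- list(lambda1 = 1 / 0.4, lambda2 = 1 / 2.0, a1 = 0.6,
                   b = 0.1 * max(nc) / n_tot / bw / 10, g = n_tot * bw,
                   mu = 0, sigma = 0.15)
  init <- utils::modifyList(defaults, init)
  pack <- function(p) {
    v <- c(log(p$lambda1), log(p$lambda2), stats::qlogis(min(max(p$a1,
           1e-4), 1 - 1e-4)), log(max(p$b, 1e-12)), log(p$g), p$mu)
    if (!fix_sigma) v <- c(v, log(max(p$sigma, 1e-4)))
    v
  }
  unpack <- function(v) {
    list(lambda1 = exp(v[1]), lambda2 = exp(v[2]), a1 = stats::plogis(v[3]),
         b = exp(v[4]), g = exp(v[5]), mu = v[6],
         sigma = if (fix_sigma) init$sigma else exp(v[7]))
  }
  resid_fn <- function(v) {
    p <- unpack(v)
    (spectrum_model(tc, p) - nc) / sqrt(nc)
  }
  best <- NULL
  for (mu0 in mu_grid) {
    ini <- init; ini$mu <- mu0
    fit <- try(minpack.lm::nls.lm(
      par = pack(ini), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss)
      best <- list(fit = fit, loss = loss)
  }
  if (is.null(best))
    stop("timing-offset fit failed to converge from any starting offset")
  pars <- unpack(best$fit$par)
  # degenerate spectrum: exponential amplitude vanishes, mu unidentifiable
  model_sig <- pars$g * (pars$a1 * emg_density(pars$mu + 1e-6, pars$lambda1,
                 pars$mu, pars$sigma) + (1 - pars$a1) *
                 emg_density(pars$mu + 1e-6, pars$lambda2, pars$mu,
                             pars$sigma))
  bg_level <- pars$g * pars$b
  identifiable <- model_sig > 0.05 * max(bg_level, 1e-12)
  if (!identifiable) {
    warning("spectrum is background-dominated: timing offset unidentifiable")
    pars$mu <- NA_real_
  }
  structure(list(pars = pars, loss = best$loss, n_bins_fit = length(tc),
                 converged = best$fit$info %in% 1:4,
                 identifiable = identifiable),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "spectrum_fit: mu = %.4f ns, sigma = %.4f ns, loss %.4g (%d bins)\n",
    x$pars$mu, x$pars$sigma, x$loss, x$n_bins_fit))
  cat(sprintf("  components: %.3f @ %.3f ns + %.3f @ %.3f ns, bg %.3g\n",
              x$pars$a1, 1 / x$pars$lambda1, 1 - x$pars$a1,
              1 / x$pars$lambda2, x$pars$b))
  invisible(x)
}
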