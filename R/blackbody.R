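# CODATA 2018 constants (SI)
.h_planck <- 6.62607015e-34    # J s
.c_light <- 2.99792458e8       # m / s
.k_boltzmann <- 1.380649e-23   # J / K

# spectral radiance is handled in kW sr^-1 m^-2 nm^-1 so that, with the
# detector gain s in m^2 nm photons sr kW^-1, s * B is a photon count
.radiance_si_to_units <- 1e-12

#' Planck spectral radiance
#'
#' `B_P(lambda; T) = (2 h c^2 / lambda^5) / (exp(h c / (lambda k_B T)) - 1)`,
#' evaluated with CODATA 2018 constants. Wavelengths are in micrometres and
#' radiance in kW sr^-1 m^-2 nm^-1. The exponential is evaluated in log
#' space for very short wavelengths / low temperatures so the Wien tail
#' underflows gracefully instead of overflowing.
#'
#' @param lam Wavelength(s) in micrometres, > 0.
#' @param temperature Black-body temperature in kelvin, > 0 (default 4000 K,
#'   the package's standard simulated experiment).
#' @return Spectral radiance in kW sr^-1 m^-2 nm^-1.
#' @export
#' @examples
#' planck_radiance(10, 4000)
planck_radiance <- function(lam, temperature = 4000) {
  stopifnot(all(lam > 0), all(temperature > 0))
  lam_m <- lam * 1e-6
  x <- .h_planck * .c_light / (lam_m * .k_boltzmann * temperature)
  pref <- 2 * .h_planck * .c_light^2 / lam_m^5
  denom_inv <- ifelse(x > 700, exp(-x), 1 / expm1(x))
  pref * denom_inv * .radiance_si_to_units
}

#' Rayleigh-Jeans spectral radiance
#'
#' `B_RJ(lambda; T) = 2 c k_B T / lambda^4`: the classical long-wavelength
#' law, which agrees with the Planck law for
#' `h c / (lambda k_B T) << 1` and diverges from it (the ultraviolet
#' catastrophe) at short wavelengths. Same units as [planck_radiance()];
#' always an upper bound on the Planck radiance.
#'
#' @inheritParams planck_radiance
#' @return Spectral radiance in kW sr^-1 m^-2 nm^-1.
#' @export
rayleigh_jeans_radiance <- function(lam, temperature = 4000) {
  stopifnot(all(lam > 0), all(temperature > 0))
  lam_m <- lam * 1e-6
  2 * .c_light * .k_boltzmann * temperature / lam_m^4 * .radiance_si_to_units
}

radiance_law_fn <- function(law) {
  switch(match.arg(law, c("planck", "rayleigh_jeans")),
         planck = planck_radiance,
         rayleigh_jeans = rayleigh_jeans_radiance)
}

#' Simulate black-body radiance observations with Poisson counting noise
#'
#' Wavelengths are laid out on a uniform grid over the detection window
#' (equal-width spectrometer bins); each observed radiance is
#' `Poisson(s * B_law(lambda; T)) / s + b0`, where `s` is the detector gain
#' collecting sensor area, integration window and sensitivity (units
#' m^2 nm photons sr kW^-1, so `s * B` is a photon count) and `b0` is a
#' sensor bias (dark currents / photon losses) that candidate models
#' typically neglect. The observation mean is `B_law + b0` and its variance
#' `B_law / s`. Defaults are the package's standard simulated experiment:
#' T = 4000 K, s = 1e5, the long-wave ambiguous window 6-20 um, Planck
#' physics and no bias.
#'
#' @param n_points Number of wavelength bins.
#' @param lam_min,lam_max Detection window in micrometres.
#' @param temperature Temperature in kelvin.
#' @param s Detector gain (m^2 nm photons sr kW^-1).
#' @param b0 Additive sensor bias, radiance units.
#' @param law `"planck"` or `"rayleigh_jeans"` physics for the mean.
#' @return A `radiance_dataset`: data frame with columns `x` (wavelength,
#'   um) and `y` (radiance, kW sr^-1 m^-2 nm^-1), with the generating
#'   parameters attached as attribute `meta`.
#' @export
generate_blackbody_data <- function(n_points, lam_min = 6, lam_max = 20,
                                    temperature = 4000, s = 1e5, b0 = 0,
                                    law = "planck") {
  stopifnot(lam_min > 0, lam_min < lam_max, s > 0, n_points >= 2)
  lam <- seq(lam_min, lam_max, length.out = n_points)
  mu <- s * radiance_law_fn(law)(lam, temperature)
  if (any(!is.finite(mu)) || any(mu > .Machine$integer.max * 1e3)) {
    stop("s * B overflows a workable count; reduce `s` or the window")
  }
  y <- stats::rpois(n_points, mu) / s + b0
  out <- data.frame(x = lam, y = y)
  attr(out, "meta") <- list(temperature = temperature, s = s, b0 = b0,
                            physical_model = law,
                            lam_min = lam_min, lam_max = lam_max)
  class(out) <- c("radiance_dataset", "data.frame")
  out
}

#' Black-body candidate model with additive Gaussian noise
#'
#' The candidate assumes `B | lambda ~ N(B_law(lambda; T), sigma^2)` — the
#' common (and here deliberately incorrect) additive-Gaussian observation
#' model — and scores records with the Gaussian negative log likelihood
#' `log(2 pi sigma^2) / 2 + (y - B_law(x))^2 / (2 sigma^2)`. The temperature
#' is treated as known; the noise scale `sigma` is the per-dataset nuisance
#' parameter, fitted by [fit_sigma_mle()] (the candidate's `fit`
#' capability). Its sampler draws wavelengths on the same uniform grid used
#' for data generation and radiances from the assumed Gaussian.
#'
#' @param law `"planck"` or `"rayleigh_jeans"`.
#' @param sigma Gaussian noise standard deviation (radiance units); may be
#'   left `NULL` until fitted.
#' @param temperature Temperature in kelvin (known, not fitted by default).
#' @param lam_min,lam_max Detection window for the sampler, micrometres.
#' @param id Model label; defaults to the law name.
#' @return A [candidate_model()] (subclass `blackbody_candidate`) with
#'   fields `law`, `temperature`, `sigma`, and window bounds.
#' @export
blackbody_candidate <- function(law = c("planck", "rayleigh_jeans"),
                                sigma = NULL, temperature = 4000,
                                lam_min = 6, lam_max = 20, id = NULL) {
  law <- match.arg(law)
  if (is.null(id)) id <- law
  if (!is.null(sigma) && (!is.finite(sigma) || sigma <= 0)) {
    stop("`sigma` must be positive once set")
  }
  radiance <- radiance_law_fn(law)
  force(temperature); force(lam_min); force(lam_max)
  obj <- candidate_model(
    id = id,
    loss = function(d) {
      if (is.null(sigma)) {
        stop("candidate '", id, "' has no fitted sigma; call fit_sigma_mle()")
      }
      mu <- radiance(d$x, temperature)
      0.5 * log(2 * pi * sigma^2) + (d$y - mu)^2 / (2 * sigma^2)
    },
    sampler = function(n) {
      if (is.null(sigma)) {
        stop("candidate '", id, "' has no fitted sigma; call fit_sigma_mle()")
      }
      lam <- seq(lam_min, lam_max, length.out = n)
      data.frame(x = lam, y = stats::rnorm(n, radiance(lam, temperature),
                                           sigma))
    },
    fit = function(d) fit_sigma_mle(d, blackbody_candidate(
      law = law, sigma = NULL, temperature = temperature,
      lam_min = lam_min, lam_max = lam_max, id = id))
  )
  obj$law <- law
  obj$temperature <- temperature
  obj$sigma <- sigma
  obj$lam_min <- lam_min
  obj$lam_max <- lam_max
  class(obj) <- c("blackbody_candidate", class(obj))
  obj
}

#' Maximum-likelihood fit of the Gaussian noise scale
#'
#' With the radiance law and temperature fixed, the Gaussian MLE of the
#' noise variance is the mean squared residual between observed radiances
#' and the candidate's radiance curve. Zero residuals (exactly reproduced
#' data) would give a degenerate likelihood, so `sigma` is floored at a tiny
#' positive value with a warning.
#'
#' @param data Data frame with columns `x` (wavelength, um) and `y`
#'   (radiance).
#' @param candidate A [blackbody_candidate()].
#' @param sigma_floor Lower bound applied to the fitted sigma.
#' @return The candidate with `sigma` set.
#' @export
fit_sigma_mle <- function(data, candidate, sigma_floor = 1e-15) {
  stopifnot(inherits(candidate, "blackbody_candidate"))
  data <- as.data.frame(data)
  resid <- data$y - radiance_law_fn(candidate$law)(data$x,
                                                   candidate$temperature)
  sigma_hat <- sqrt(mean(resid^2))
  if (sigma_hat < sigma_floor) {
    warning("all residuals (near) zero; sigma floored at ", sigma_floor)
    sigma_hat <- sigma_floor
  }
  blackbody_candidate(law = candidate$law, sigma = sigma_hat,
                      temperature = candidate$temperature,
                      lam_min = candidate$lam_min,
                      lam_max = candidate$lam_max, id = candidate$id)
}

#' Epistemic distribution over black-body data-generating processes
#'
#' Each draw picks a physical law uniformly from `laws` and a sensor bias
#' uniformly from `b0_range`, holding all other parameters at the standard
#' experiment values; the drawn process generates datasets through the
#' Poisson counting model of [generate_blackbody_data()]. The defaults
#' reproduce the package's reference calibration ensemble: both laws
#' equally likely and a bias uniform on \[-1e-4, 1e-4\] radiance units.
#'
#' @param b0_range Length-2 interval for the bias draw.
#' @param laws Character subset of `c("planck", "rayleigh_jeans")`.
#' @param temperature,s,lam_min,lam_max Fixed process parameters.
#' @return An `epistemic_distribution`: list with `draw()` returning a
#'   data-generating process (list with `sampler(n)` and `omega`, the drawn
#'   hyperparameters) and a `description`.
#' @export
blackbody_epistemic_dist <- function(b0_range = c(-1e-4, 1e-4),
                                     laws = c("planck", "rayleigh_jeans"),
                                     temperature = 4000, s = 1e5,
                                     lam_min = 6, lam_max = 20) {
  stopifnot(length(b0_range) == 2L, b0_range[1L] <= b0_range[2L],
            length(laws) >= 1L,
            all(laws %in% c("planck", "rayleigh_jeans")))
  draw <- function() {
    law <- if (length(laws) == 1L) laws else sample(laws, 1L)
    b0 <- stats::runif(1L, b0_range[1L], b0_range[2L])
    list(
      sampler = function(n) {
        as.data.frame(generate_blackbody_data(
          n_points = n, lam_min = lam_min, lam_max = lam_max,
          temperature = temperature, s = s, b0 = b0, law = law))
      },
      omega = list(law = law, b0 = b0, temperature = temperature, s = s,
                   lam_min = lam_min, lam_max = lam_max)
    )
  }
  epistemic_distribution(
    draw,
    description = sprintf("black body: law in {%s}, b0 ~ Unif[%g, %g]",
                          paste(laws, collapse = ", "),
                          b0_range[1L], b0_range[2L]))
}
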