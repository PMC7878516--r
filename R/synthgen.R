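#' Seeded synthetic-data generators
#'
#' Every generator is a pure function of its parameters and seed; each
#' returns its data object together with a `manifest` attribute recording
#' the generator name, the ground-truth parameters and the seed, so recovery
#' tests read the truth from the manifest, never from the data.
#'
#' @name synthgen
NULL

#' Noise specification
#'
#' Gaussian noise with a relative component and an absolute floor:
#' `sd_i = relative_sd * |y_i| + floor`.
#'
#' @param relative_sd Fractional standard deviation.
#' @param floor Absolute standard deviation floor.
#' @param seed Integer seed.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(relative_sd = 0.02, floor = 0, seed = 1) {
  stopifnot(relative_sd >= 0, floor >= 0)
  structure(list(relative_sd = relative_sd, floor = floor, seed = seed),
            class = "noise_spec")
}

.manifest <- function(generator, params, seed) {
  list(generator = generator, params = params, seed = seed)
}

# analytic normalised form factors, x = q * size
.sphere_ff <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
}

#' Synthetic scattering profile of a geometric body
#'
#' Analytic orientation-averaged scattering: homogeneous sphere
#' (`I = F_sphere(qR)^2`), spherical shell (amplitude of outer minus inner
#' sphere, volume-weighted), or thin rod (the classical infinitely thin rod
#' of length `L`). Gaussian noise per the noise specification; the sigma
#' column records the standard deviation actually applied.
#'
#' @param shape `"sphere"`, `"shell"` or `"rod"`.
#' @param size For sphere: radius (nm). Shell: `c(outer, inner)` radii (nm).
#'   Rod: length (nm).
#' @param q q grid (nm^-1).
#' @param noise A [noise_spec()] (or `NULL` for noiseless).
#' @param i0 Forward intensity scale.
#' @return A `saxs_profile` with a `manifest` attribute holding the truth
#'   (including the analytic Rg of the body).
#' @export
gen_geometry_profile <- function(shape = c("sphere", "shell", "rod"),
                                 size, q = seq(0.05, 4, by = 0.01),
                                 noise = noise_spec(), i0 = 1) {
  shape <- match.arg(shape)
  stopifnot(all(size > 0))
  I <- switch(shape,
    sphere = i0 * .sphere_ff(q, size[1])^2,
    shell = {
      if (length(size) < 2 || size[2] >= size[1]) {
        stop("shell needs sizes c(outer, inner) with inner < outer")
      }
      Vo <- size[1]^3; Vi <- size[2]^3
      A <- (Vo * .sphere_ff(q, size[1]) - Vi * .sphere_ff(q, size[2])) /
        (Vo - Vi)
      i0 * A^2
    },
    rod = {
      L <- size[1]
      x <- q * L
      si <- vapply(x, function(xx) {
        stats::integrate(function(t) sin(t) / t, 1e-9, xx)$value
      }, numeric(1))
      i0 * (2 * si / x - 4 * sin(x / 2)^2 / x^2)
    })
  rg_true <- switch(shape,
    sphere = sqrt(3 / 5) * size[1],
    shell = sqrt(3 / 5 * (size[1]^5 - size[2]^5) / (size[1]^3 - size[2]^3)),
    rod = size[1] / sqrt(12))
  if (!is.null(noise)) {
    # a floor tied to the forward intensity keeps the weighting of the deep
    # form-factor minima finite, as detector counting statistics would
    sd <- noise$relative_sd * abs(I) + max(noise$floor, 1e-4 * i0)
    I <- .with_seed(noise$seed, I + stats::rnorm(length(I), 0, sd))
    sigma <- sd
  } else {
    # noiseless data still carries a nominal 1% uncertainty so that
    # sigma-weighted analyses remain well conditioned
    sigma <- abs(I) * 0.01 + 1e-4 * i0
  }
  p <- saxs_profile(q, I, sigma, label = sprintf("synthetic_%s", shape))
  attr(p, "manifest") <- .manifest(
    "gen_geometry_profile",
    list(shape = shape, size = size, i0 = i0, rg_true = rg_true,
         noise = unclass(noise)),
    if (is.null(noise)) NA_integer_ else noise$seed)
  p
}

#' Synthetic CD melting curve
#'
#' Forward evaluation of the two- or three-state equilibrium melting model
#' with linear baselines plus Gaussian noise. Noise sd is expressed relative
#' to the dynamic range of the noiseless curve.
#'
#' @param model `"two_state"` or `"three_state"`.
#' @param tm Transition midpoints (degrees C): one value (two-state) or two.
#' @param dh van't Hoff enthalpies (kJ/mol), same length as `tm`.
#' @param baselines `c(yn0, yn1, yd0, yd1)`: native / denatured intercepts
#'   and slopes (signal units, units per degree C).
#' @param w Intermediate-state mixing fraction (three-state only).
#' @param temperature Temperature grid (degrees C).
#' @param noise A [noise_spec()]; `relative_sd` scales the curve's dynamic
#'   range.
#' @return A `melting_curve` with a `manifest` attribute holding the truth.
#' @export
gen_melting_curve <- function(model = c("two_state", "three_state"),
                              tm, dh,
                              baselines = c(-30000, 20, -3000, 10),
                              w = 0.5,
                              temperature = seq(5, 92, by = 1),
                              noise = noise_spec(relative_sd = 0.015)) {
  model <- match.arg(model)
  TK <- temperature + 273.15
  y <- if (model == "two_state") {
    stopifnot(length(tm) == 1, length(dh) == 1)
    .melt2(TK, tm, dh, baselines[1], baselines[2], baselines[3], baselines[4])
  } else {
    stopifnot(length(tm) == 2, length(dh) == 2)
    .melt3(TK, tm[1], dh[1], tm[2], dh[2], w,
           baselines[1], baselines[2], baselines[3], baselines[4])
  }
  if (!is.null(noise)) {
    sd <- noise$relative_sd * diff(range(y)) + noise$floor
    y <- .with_seed(noise$seed, y + stats::rnorm(length(y), 0, sd))
  }
  curve <- melting_curve(temperature, y)
  attr(curve, "manifest") <- .manifest(
    "gen_melting_curve",
    list(model = model, tm = tm, dh = dh, baselines = baselines, w = w,
         noise = if (is.null(noise)) NULL else unclass(noise)),
    if (is.null(noise)) NA_integer_ else noise$seed)
  curve
}

#' Synthetic 1:1 ITC series
#'
#' Forward 1:1 model with dilution bookkeeping (see [itc_forward()]) plus
#' Gaussian noise scaled to the largest absolute injection heat.
#'
#' @param n Stoichiometry.
#' @param kd Dissociation constant (nM).
#' @param dh Binding enthalpy (kcal/mol).
#' @param offset Per-injection baseline heat (ucal).
#' @param cell_volume Cell volume (mL).
#' @param cell_conc Analyte concentration (uM).
#' @param syringe_conc Titrant concentration (uM).
#' @param injection_volumes Injection volumes (uL); default the protocol of
#'   a 2 uL priming injection followed by 27 injections of 10 uL.
#' @param noise A [noise_spec()]; `relative_sd` scales the peak heat.
#' @return An `itc_series` with a `manifest` attribute holding the truth.
#' @export
gen_itc_series <- function(n = 1, kd = 4.7, dh = -10, offset = 0,
                           cell_volume = 1.4, cell_conc = 1,
                           syringe_conc = 10,
                           injection_volumes = c(2, rep(10, 27)),
                           noise = noise_spec(relative_sd = 0.02)) {
  stopifnot(n > 0, kd > 0)
  series <- itc_series(injection_volumes,
                       heats = rep(0, length(injection_volumes)),
                       cell_volume = cell_volume,
                       syringe_conc = syringe_conc, cell_conc = cell_conc)
  q <- itc_forward(series, n = n, kd = kd, dh = dh, offset = offset)
  if (!is.null(noise)) {
    sd <- noise$relative_sd * max(abs(q)) + noise$floor
    q <- .with_seed(noise$seed, q + stats::rnorm(length(q), 0, sd))
  }
  series$heats <- q
  attr(series, "manifest") <- .manifest(
    "gen_itc_series",
    list(n = n, kd = kd, dh = dh, offset = offset,
         cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = injection_volumes,
         noise = if (is.null(noise)) NULL else unclass(noise)),
    if (is.null(noise)) NA_integer_ else noise$seed)
  series
}

#' Synthetic donor/acceptor emission spectra
#'
#' Sum of Gaussian emission bands for a Cy3-like donor (peak 566 nm) and a
#' Cy5-like acceptor (peak 668 nm). With transfer efficiency `E`, the donor
#' band is scaled by `1 - E` and the acceptor band by
#' `bleed + E * acceptor_yield`, where `bleed` models direct acceptor
#' excitation.
#'
#' @param efficiency Transfer efficiency in `[0, 1]`.
#' @param donor_peak,acceptor_peak Band centres (nm).
#' @param donor_width,acceptor_width Band standard deviations (nm).
#' @param donor_amp Donor band amplitude.
#' @param acceptor_yield Acceptor emission amplitude per unit transfer.
#' @param bleed Direct acceptor excitation fraction.
#' @param wavelength Wavelength grid (nm).
#' @param noise A [noise_spec()]; `relative_sd` scales the peak intensity.
#' @return An `emission_spectrum` with a `manifest` attribute.
#' @export
gen_fret_spectra <- function(efficiency = 0.5,
                             donor_peak = 566, acceptor_peak = 668,
                             donor_width = 18, acceptor_width = 20,
                             donor_amp = 1000, acceptor_yield = 0.8,
                             bleed = 0.05,
                             wavelength = seq(548, 800, by = 1),
                             noise = noise_spec(relative_sd = 0.01)) {
  stopifnot(efficiency >= 0, efficiency <= 1)
  if (donor_peak < min(wavelength) || acceptor_peak > max(wavelength)) {
    stop("peaks must be representable on the wavelength grid")
  }
  I <- donor_amp * (1 - efficiency) *
    exp(-(wavelength - donor_peak)^2 / (2 * donor_width^2)) +
    donor_amp * (bleed + efficiency * acceptor_yield) *
    exp(-(wavelength - acceptor_peak)^2 / (2 * acceptor_width^2))
  if (!is.null(noise)) {
    sd <- noise$relative_sd * max(I) + noise$floor
    I <- .with_seed(noise$seed, I + stats::rnorm(length(I), 0, sd))
  }
  sp <- emission_spectrum(wavelength, I)
  attr(sp, "manifest") <- .manifest(
    "gen_fret_spectra",
    list(efficiency = efficiency, donor_peak = donor_peak,
         acceptor_peak = acceptor_peak, donor_width = donor_width,
         acceptor_width = acceptor_width, donor_amp = donor_amp,
         acceptor_yield = acceptor_yield, bleed = bleed,
         noise = if (is.null(noise)) NULL else unclass(noise)),
    if (is.null(noise)) NA_integer_ else noise$seed)
  sp
}

#' Write a fixture manifest as JSON
#'
#' @param x An object produced by a generator (carrying a `manifest`
#'   attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  mf <- attr(x, "manifest")
  if (is.null(mf)) stop("object carries no manifest")
  jsonlite::write_json(mf, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
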