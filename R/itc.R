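#' Isothermal titration calorimetry: 1:1 binding model
#'
#' Forward model and weighted nonlinear fit for a single-site (1:1)
#' dissociation model with the standard displaced-volume dilution
#' bookkeeping of an overflow cell.
#'
#' @name itc
NULL

#' Construct an ITC injection series
#'
#' @param injection_volumes Per-injection volumes (uL).
#' @param heats Integrated per-injection heats (ucal), same length.
#' @param cell_volume Active cell volume (mL).
#' @param syringe_conc Titrant concentration in the syringe (uM).
#' @param cell_conc Analyte concentration initially in the cell (uM).
#' @param exclude_first Exclude the first (small, diffusion-corrupted)
#'   injection from fitting (default `TRUE`).
#' @return Object of class `itc_series`.
#' @export
itc_series <- function(injection_volumes, heats, cell_volume = 1.4,
                       syringe_conc, cell_conc, exclude_first = TRUE) {
  stopifnot(length(injection_volumes) == length(heats),
            all(injection_volumes > 0), cell_volume > 0,
            syringe_conc > 0, cell_conc > 0)
  structure(list(injection_volumes = as.numeric(injection_volumes),
                 heats = as.numeric(heats),
                 cell_volume = cell_volume,
                 syringe_conc = syringe_conc,
                 cell_conc = cell_conc,
                 exclude_first = exclude_first),
            class = "itc_series")
}

#' @export
print.itc_series <- function(x, ...) {
  cat(sprintf(
    "itc_series: %d injections, cell %.2f mL @ %.2f uM, syringe %.2f uM\n",
    length(x$heats), x$cell_volume, x$cell_conc, x$syringe_conc))
  invisible(x)
}

# bound complex concentration for 1:1 binding (uM), exact quadratic root
.ml_bound <- function(Mt, Lt, Kd) {
  b <- Mt + Lt + Kd
  (b - sqrt(pmax(b^2 - 4 * Mt * Lt, 0))) / 2
}

#' Forward 1:1 ITC model
#'
#' Per-injection heats for a 1:1 dissociation model. Each injection of
#' volume `dV` displaces a fraction `dV/V0` of the cell content; cell
#' concentrations are updated with the standard stepwise dilution rule
#' before the bound fraction is recomputed from the exact quadratic root.
#' The heat of injection i is `V0 * dH * ([ML]_i - [ML]_(i-1) (1 - dV/V0))`
#' plus a constant per-injection offset.
#'
#' @param series An `itc_series` (its `heats` are ignored).
#' @param n Stoichiometry (binding sites on the analyte).
#' @param kd Dissociation constant (nM).
#' @param dh Binding enthalpy (kcal/mol).
#' @param offset Per-injection baseline heat (ucal).
#' @return Numeric vector of per-injection heats (ucal).
#' @export
itc_forward <- function(series, n, kd, dh, offset = 0) {
  V0 <- series$cell_volume * 1e-3          # L
  kd_uM <- kd * 1e-3                       # nM -> uM
  M <- n * series$cell_conc                # binding-site concentration, uM
  L <- 0
  ml_prev <- 0
  q <- numeric(length(series$injection_volumes))
  for (i in seq_along(q)) {
    dV <- series$injection_volumes[i] * 1e-6   # L
    f <- dV / V0
    M <- M * (1 - f)
    L <- L * (1 - f) + series$syringe_conc * f
    ml <- .ml_bound(M, L, kd_uM)
    # dH kcal/mol * V0 L * d[ML] umol/L = ucal
    q[i] <- dh * 1e3 * V0 * (ml - ml_prev * (1 - f)) + offset
    ml_prev <- ml
  }
  q
}

#' Fit a 1:1 dissociation model to an ITC series
#'
#' Weighted nonlinear least squares over (n, Kd, dH, offset) using the
#' forward model of [itc_forward()], Levenberg-Marquardt with seeded
#' multi-start initialisation on log Kd. The first injection is excluded by
#' default. The Wiseman c-value (`n * [M] / Kd`) is reported and flagged
#' when outside the reliable 1-1000 window (the fit is still returned).
#'
#' @param series An `itc_series`.
#' @param weights Optional per-injection weights.
#' @param n_starts Multi-start attempts.
#' @param seed Seed for the multi-start jitter.
#' @return List of class `itc_fit`: `n`, `kd` (nM), `dh` (kcal/mol),
#'   `offset`, standard deviations, `c_value`, `c_reliable`, `rss`,
#'   `fitted`, `converged`.
#' @export
fit_itc <- function(series, weights = NULL, n_starts = 6, seed = 1) {
  use <- rep(TRUE, length(series$heats))
  if (series$exclude_first) use[1] <- FALSE
  if (sum(use) < 10) stop("need at least 10 usable injections")
  if (is.null(weights)) weights <- rep(1, length(series$heats))
  y <- series$heats

  resid_fn <- function(p) {
    # p = (n, log_kd, dh, offset)
    q <- itc_forward(series, n = p[1], kd = exp(p[2]), dh = p[3],
                     offset = p[4])
    ((y - q) * sqrt(weights))[use]
  }

  # crude initial guesses: dH from the initial plateau, n from the
  # molar-ratio position of the steepest heat change
  V0 <- series$cell_volume * 1e-3
  cum_L <- cumsum(series$injection_volumes * 1e-6 * series$syringe_conc) /
    (V0 * series$cell_conc)
  dh0 <- sum(y[use]) / (1e3 * V0 * series$cell_conc)
  step_i <- which.max(abs(diff(y)))
  n0 <- max(0.3, min(3, cum_L[step_i]))

  .with_seed(seed, {
    best <- NULL
    for (k in seq_len(n_starts)) {
      start <- c(n = n0 * stats::runif(1, 0.8, 1.2),
                 log_kd = log(10^stats::runif(1, -1, 3)),  # 0.1 nM .. 1 uM
                 dh = dh0 * stats::runif(1, 0.6, 1.4),
                 offset = 0)
      out <- try(minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
      if (inherits(out, "try-error")) next
      if (is.null(best) || out$deviance < best$deviance) best <- out
    }
    if (is.null(best)) stop("ITC fit did not converge")
    p <- best$par
    cov <- try(solve(best$hessian) * best$deviance / (sum(use) - 4),
               silent = TRUE)
    sds <- if (inherits(cov, "try-error")) rep(NA_real_, 4)
           else sqrt(pmax(diag(cov), 0))
    kd <- exp(p[2])
    c_value <- p[1] * series$cell_conc / (kd * 1e-3)
    structure(list(n = unname(p[1]), n_sd = unname(sds[1]),
                   kd = unname(kd), kd_sd = unname(kd * sds[2]),
                   dh = unname(p[3]), dh_sd = unname(sds[3]),
                   offset = unname(p[4]), offset_sd = unname(sds[4]),
                   c_value = unname(c_value),
                   c_reliable = c_value >= 1 && c_value <= 1000,
                   rss = best$deviance,
                   fitted = itc_forward(series, p[1], kd, p[3], p[4]),
                   converged = best$info %in% 1:4),
              class = "itc_fit")
  })
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "1:1 ITC fit: n = %.2f, Kd = %.2f nM, dH = %.2f kcal/mol (c = %.0f%s)\n",
    x$n, x$kd, x$dh, x$c_value,
    if (x$c_reliable) "" else ", outside reliable window"))
  invisible(x)
}

#' Read / write an ITC series as a delimited table
#'
#' Tab-separated columns `volume_uL` and `heat_ucal` plus a header of
#' `# key value` lines for the scalar fields.
#'
#' @param series An `itc_series`.
#' @param path File path.
#' @return `write_itc_series` returns `path` invisibly; `read_itc_series`
#'   an `itc_series`.
#' @export
write_itc_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_volume %.6g", series$cell_volume),
               sprintf("# syringe_conc %.6g", series$syringe_conc),
               sprintf("# cell_conc %.6g", series$cell_conc),
               sprintf("# exclude_first %d", as.integer(series$exclude_first)),
               "volume_uL\theat_ucal"), con)
  writeLines(sprintf("%.6g\t%.8g", series$injection_volumes, series$heats),
             con)
  invisible(path)
}

#' @rdname write_itc_series
#' @export
read_itc_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  itc_series(df$volume_uL, df$heat_ucal,
             cell_volume = getv("cell_volume"),
             syringe_conc = getv("syringe_conc"),
             cell_conc = getv("cell_conc"),
             exclude_first = getv("exclude_first") == 1)
}
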