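#' Circular dichroism analysis
#'
#' Helical content from mean residue ellipticity and equilibrium thermal
#' unfolding fits (two-state and sequential three-state).
#'
#' @name cd
NULL

.R_GAS <- 8.314462618e-3  # kJ / (mol K)

#' Helical content from MRE at 222 nm
#'
#' `alpha(%) = 100 * MRE222 / (MRE_H * (1 - 2.57/n))`, where `MRE_H` is the
#' mean residue ellipticity of an infinitely long helix (-39,500 deg cm^2
#' dmol^-1) and `n` the chain length in residues. Values may exceed 100% or
#' be negative; they are reported unclamped.
#'
#' @param mre222 Mean residue ellipticity at 222 nm (deg cm^2 dmol^-1).
#' @param n Number of residues (> 3).
#' @param mre_helix Infinite-helix reference MRE.
#' @return Helical content in percent.
#' @examples
#' helical_content(-39500 * (1 - 2.57 / 100), 100)  # 100
#' @export
helical_content <- function(mre222, n, mre_helix = -39500) {
  if (any(n <= 2.57)) stop("n must exceed 2.57 (denominator changes sign)")
  100 * mre222 / (mre_helix * (1 - 2.57 / n))
}

#' Mean residue ellipticity from raw ellipticity
#'
#' `MRE = theta / (10 * conc * path * n)` with theta in millidegrees,
#' molar concentration, path length in cm and `n` residues (the chain
#' length is used, not `n - 1` bonds; this matches the helical-content
#' convention above).
#'
#' @param theta Ellipticity (mdeg).
#' @param conc Molar protein concentration (M).
#' @param path Cuvette path length (cm).
#' @param n Number of residues.
#' @return MRE in deg cm^2 dmol^-1.
#' @export
mre_from_ellipticity <- function(theta, conc, path, n) {
  denom <- 10 * conc * path * n
  if (any(denom == 0)) stop("zero denominator")
  theta / denom
}

#' Construct a melting curve
#'
#' @param temperature Increasing temperature grid (degrees C, >= 10 points).
#' @param signal CD signal (MRE at 222 nm, deg cm^2 dmol^-1).
#' @return Object of class `melting_curve`.
#' @export
melting_curve <- function(temperature, signal) {
  if (length(temperature) < 10) stop("need at least 10 points")
  if (any(diff(temperature) <= 0)) stop("temperatures must increase")
  if (length(signal) != length(temperature)) stop("length mismatch")
  structure(list(temperature = as.numeric(temperature),
                 signal = as.numeric(signal)),
            class = "melting_curve")
}

# two-state forward model; T in K
.melt2 <- function(TK, tm, dh, yn0, yn1, yd0, yd1) {
  K <- exp(-dh * (1 - TK / (tm + 273.15)) / (.R_GAS * TK))
  yN <- yn0 + yn1 * (TK - 273.15)
  yD <- yd0 + yd1 * (TK - 273.15)
  (yN + yD * K) / (1 + K)
}

# sequential three-state N <-> I <-> D; intermediate signal is a fixed
# mixing fraction w between the native and denatured baselines
.melt3 <- function(TK, tm1, dh1, tm2, dh2, w, yn0, yn1, yd0, yd1) {
  K1 <- exp(-dh1 * (1 - TK / (tm1 + 273.15)) / (.R_GAS * TK))
  K2 <- exp(-dh2 * (1 - TK / (tm2 + 273.15)) / (.R_GAS * TK))
  Z <- 1 + K1 + K1 * K2
  fN <- 1 / Z; fI <- K1 / Z; fD <- K1 * K2 / Z
  yN <- yn0 + yn1 * (TK - 273.15)
  yD <- yd0 + yd1 * (TK - 273.15)
  yI <- w * yN + (1 - w) * yD
  fN * yN + fI * yI + fD * yD
}

#' Fit an equilibrium melting model to a CD thermal denaturation curve
#'
#' Two-state: `y(T) = (yN(T) + yD(T) K) / (1 + K)`,
#' `K = exp(-dH (1 - T/Tm) / (R T))` with linear native and denatured
#' baselines (van't Hoff enthalpy, delta-Cp fixed at 0). Three-state:
#' sequential N - I - D with two (Tm, dH) transitions; the intermediate's
#' signal is a fitted mixing fraction of the two baselines. Weighted
#' nonlinear least squares (Levenberg-Marquardt) with seeded multi-start
#' initialisation; parameter uncertainties from the covariance of the fit.
#'
#' @param curve A `melting_curve`.
#' @param model `"two_state"` or `"three_state"`.
#' @param weights Optional per-point weights.
#' @param n_starts Multi-start attempts.
#' @param seed Seed for the multi-start jitter.
#' @return List of class `melting_fit`: `model`, `tm` (degrees C, per
#'   transition) and `dh` (kJ/mol) with standard deviations, `baselines`,
#'   `rss`, `fitted`, `converged`, plus a boundary flag when a Tm sits at
#'   the edge of the data range.
#' @export
fit_melting <- function(curve, model = c("two_state", "three_state"),
                        weights = NULL, n_starts = 8, seed = 1) {
  model <- match.arg(model)
  TC <- curve$temperature
  TK <- TC + 273.15
  y <- curve$signal
  if (is.null(weights)) weights <- rep(1, length(y))

  # derivative-guided initial transition guesses
  dy <- diff(y) / diff(TC)
  sm <- stats::filter(dy, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- 0
  ord <- order(-abs(sm))
  guess_t <- TC[ord[1]]
  span <- diff(range(y))
  y_lo <- stats::median(y[TC <= stats::quantile(TC, 0.1)])
  y_hi <- stats::median(y[TC >= stats::quantile(TC, 0.9)])

  fit_once <- function(start) {
    ctl <- minpack.lm::nls.lm.control(maxiter = 200)
    if (model == "two_state") {
      ff <- function(p) {
        (y - .melt2(TK, p[1], p[2], p[3], p[4], p[5], p[6])) * sqrt(weights)
      }
    } else {
      ff <- function(p) {
        w <- 1 / (1 + exp(-p[5]))   # logistic-constrained mixing fraction
        (y - .melt3(TK, p[1], p[2], p[3], p[4], w,
                    p[6], p[7], p[8], p[9])) * sqrt(weights)
      }
    }
    out <- try(minpack.lm::nls.lm(par = start, fn = ff, control = ctl),
               silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    out
  }

  .with_seed(seed, {
    best <- NULL
    for (k in seq_len(n_starts)) {
      if (model == "two_state") {
        start <- c(tm = guess_t + stats::rnorm(1, 0, 4),
                   dh = stats::runif(1, 100, 500),
                   yn0 = y_lo, yn1 = 0, yd0 = y_hi, yd1 = 0)
      } else {
        t1 <- guess_t + stats::rnorm(1, 0, 5)
        gap <- stats::runif(1, 10, 30)
        start <- c(tm1 = min(t1, guess_t) - ifelse(k %% 2 == 0, gap / 2, 0),
                   dh1 = stats::runif(1, 150, 400),
                   tm2 = guess_t + ifelse(k %% 2 == 0, gap / 2, gap),
                   dh2 = stats::runif(1, 200, 500),
                   wlogit = 0,
                   yn0 = y_lo, yn1 = 0, yd0 = y_hi, yd1 = 0)
      }
      out <- fit_once(start)
      if (is.null(out)) next
      if (is.null(best) || out$deviance < best$deviance) best <- out
    }
    if (is.null(best)) stop("melting fit did not converge")

    p <- best$par
    cov <- try(solve(best$hessian) * best$deviance /
                 (length(y) - length(p)), silent = TRUE)
    sds <- if (inherits(cov, "try-error")) rep(NA_real_, length(p))
           else sqrt(pmax(diag(cov), 0))
    if (model == "two_state") {
      tm <- p[1]; dh <- p[2]
      tm_sd <- sds[1]; dh_sd <- sds[2]
      base <- p[3:6]
      fitted_y <- .melt2(TK, p[1], p[2], p[3], p[4], p[5], p[6])
    } else {
      o <- order(c(p[1], p[3]))
      tm <- c(p[1], p[3])[o]; dh <- c(p[2], p[4])[o]
      tm_sd <- c(sds[1], sds[3])[o]; dh_sd <- c(sds[2], sds[4])[o]
      base <- p[6:9]
      fitted_y <- .melt3(TK, p[1], p[2], p[3], p[4],
                         1 / (1 + exp(-p[5])), p[6], p[7], p[8], p[9])
    }
    structure(list(model = model,
                   tm = unname(tm), tm_sd = unname(tm_sd),
                   dh = unname(dh), dh_sd = unname(dh_sd),
                   baselines = unname(base),
                   rss = best$deviance,
                   fitted = fitted_y,
                   converged = best$info %in% 1:4,
                   tm_at_boundary = any(tm <= min(TC) + 1 | tm >= max(TC) - 1)),
              class = "melting_fit")
  })
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("%s melting fit: Tm = %s degC, dH = %s kJ/mol, rss = %.3g%s\n",
              x$model,
              paste(sprintf("%.1f", x$tm), collapse = ", "),
              paste(sprintf("%.0f", x$dh), collapse = ", "),
              x$rss,
              if (x$tm_at_boundary) " [Tm at boundary]" else ""))
  invisible(x)
}

#' Read a 2-column melting curve (or spectrum) text file
#' @param path File with two whitespace/tab-separated numeric columns.
#' @return A `melting_curve`.
#' @export
read_melting_curve <- function(path) {
  m <- utils::read.table(path, comment.char = "#")
  melting_curve(m[[1]], m[[2]])
}

#' @rdname read_melting_curve
#' @param curve A `melting_curve`.
#' @export
write_melting_curve <- function(curve, path) {
  utils::write.table(data.frame(curve$temperature, curve$signal), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
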