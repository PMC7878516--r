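#' Theoretical scattering by the Debye formula
#'
#' Computes the orientationally averaged scattering of a bead model as a
#' uniform dummy-residue Debye double sum over CA beads,
#' `I(q) = f^2 * sum_ij sin(q r_ij) / (q r_ij)`. Every bead carries the same
#' form factor `f`, so `I(0) = (N f)^2`. At coarse-grained resolution this is
#' accurate at low and intermediate angle; above roughly 2 nm^-1 the missing
#' side chains, excluded volume and hydration shell bias the curve, so
#' comparisons with experiment there are qualitative.
#'
#' @param model A `cg_model`, or a beads-by-3 coordinate matrix in Angstrom.
#' @param q q grid in nm^-1 (default 0.05..4.0).
#' @param form_factor Per-bead scattering amplitude `f` (arbitrary units).
#' @return A `saxs_profile` (no sigma).
#' @export
debye_intensity <- function(model, q = seq(0.05, 4, by = 0.02),
                            form_factor = 1) {
  X <- if (is.matrix(model)) model else model_beads(model)
  if (nrow(X) < 2) stop("need at least 2 beads")
  d <- as.vector(stats::dist(X)) / 10   # A -> nm
  N <- nrow(X)
  I <- vapply(q, function(qq) {
    x <- qq * d
    N + 2 * sum(ifelse(x < 1e-9, 1, sin(x) / x))
  }, numeric(1))
  saxs_profile(q, form_factor^2 * I,
               label = sprintf("debye_%d_beads", N))
}

#' Guinier fit
#'
#' Weighted linear fit of `ln I` against `q^2` over a low-q window that is
#' automatically shrunk until `qmax * Rg <= qmax_rg` (default 1.3, the
#' conventional validity limit for globular particles).
#'
#' @param profile A `saxs_profile` (q in nm^-1).
#' @param qmax_rg Window rule threshold.
#' @param min_points Minimum points in the window.
#' @return List of class `guinier_fit`: `rg` and `i0` with standard
#'   deviations, the q-window used, `qmax_rg` actually reached and the
#'   number of points.
#' @export
guinier_rg <- function(profile, qmax_rg = 1.3, min_points = 5) {
  ok <- profile$intensity > 0
  q <- profile$q[ok]; I <- profile$intensity[ok]
  sig <- if (is.null(profile$sigma)) rep(1, length(q)) else profile$sigma[ok]
  # weights for ln I: sd(ln I) = sigma / I
  w_all <- (I / sig)^2
  hi <- length(q)
  for (iter in 1:100) {
    idx <- seq_len(hi)
    if (length(idx) < min_points) {
      stop("no Guinier window satisfies the qmax*Rg rule")
    }
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2), weights = w_all[idx])
    slope <- stats::coef(fit)[2]
    if (slope >= 0) { hi <- hi - 1; next }
    rg <- sqrt(-3 * slope)
    if (q[hi] * rg <= qmax_rg) break
    # shrink towards the window implied by the current Rg estimate
    hi_new <- max(which(q * rg <= qmax_rg), min_points)
    hi <- if (hi_new >= hi) hi - 1 else hi_new
  }
  if (stats::coef(fit)[2] >= 0) stop("negative slope required for Guinier fit")
  cov <- stats::vcov(fit)
  rg_sd <- sqrt(9 * cov[2, 2] / (4 * -3 * stats::coef(fit)[2])) / sqrt(3)
  structure(list(rg = unname(rg),
                 rg_sd = unname(rg_sd),
                 i0 = unname(exp(stats::coef(fit)[1])),
                 i0_sd = unname(exp(stats::coef(fit)[1]) * sqrt(cov[1, 1])),
                 q_range = range(q[seq_len(hi)]),
                 qmax_rg = unname(q[hi] * rg),
                 n_points = hi),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.3f +/- %.3f nm, I0 = %.4g (%d pts, qmax*Rg = %.2f)\n",
              x$rg, x$rg_sd, x$i0, x$n_points, x$qmax_rg))
  invisible(x)
}

#' Pair-distance distribution of a bead model
#'
#' Normalised histogram of all pairwise bead distances. `dmax` is the largest
#' pairwise distance; the real-space radius of gyration follows from the
#' second moment, `rg^2 = integral(r^2 p) / (2 integral(p))`.
#'
#' @param model A `cg_model` or coordinate matrix (Angstrom).
#' @param bin_width Histogram bin width in nm.
#' @return List of class `pair_distribution`: `r` (bin centres, nm), `p`
#'   (density), `dmax` (nm), `rg` (nm).
#' @export
pr_from_model <- function(model, bin_width = 0.1) {
  X <- if (is.matrix(model)) model else model_beads(model)
  if (nrow(X) < 2) stop("need at least 2 beads")
  d <- as.vector(stats::dist(X)) / 10
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  p <- h$density
  r <- h$mids
  rg <- sqrt(sum(r^2 * p) / (2 * sum(p)))
  structure(list(r = r, p = p, dmax = dmax, rg = rg),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("p(r): dmax = %.2f nm, Rg = %.2f nm, %d bins\n",
              x$dmax, x$rg, length(x$r)))
  invisible(x)
}

# regularised IFT design matrix: I(q) = sum_j p_j * K(q, r_j)
.ift_solve <- function(q, I, sig, dmax, n_r = 60, lambda) {
  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  K <- outer(q, r, function(qq, rr) {
    x <- qq * rr
    s <- ifelse(x < 1e-12, 1, sin(x) / x)
    s * dr
  })
  # endpoint zeros: drop first and last columns from the unknowns
  Kin <- K[, 2:(n_r - 1), drop = FALSE]
  A <- Kin / sig
  b <- I / sig
  # second-difference smoothness rows
  ncol_in <- ncol(Kin)
  D <- matrix(0, ncol_in - 2, ncol_in)
  for (i in seq_len(ncol_in - 2)) D[i, i + 0:2] <- c(1, -2, 1)
  # normalise the system (uniform row scaling leaves the solution unchanged)
  sc <- sqrt(sum(b^2))
  A <- A / sc; b <- b / sc
  fnorm <- sqrt(sum(A^2) / nrow(A))   # RMS data-row magnitude
  Aaug <- rbind(A, sqrt(lambda) * fnorm * D)
  baug <- c(b, rep(0, nrow(D)))
  x <- try(pracma::lsqnonneg(Aaug, baug)$x, silent = TRUE)
  if (inherits(x, "try-error")) {
    # fall back to a box-constrained quadratic programme
    AtA <- crossprod(Aaug)
    Atb <- crossprod(Aaug, baug)
    obj <- function(x) sum((Aaug %*% x - baug)^2)
    grd <- function(x) as.vector(2 * (AtA %*% x - Atb))
    fit <- stats::optim(rep(mean(abs(baug)), ncol(Aaug)), obj, grd,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 2000))
    x <- fit$par
  }
  p <- c(0, x, 0)
  resid <- (I - as.vector(K %*% p)) / sig
  list(r = r, p = p, chi = sqrt(sum(resid^2) / (length(q) - 1)))
}

#' Indirect Fourier transform of a scattering profile
#'
#' Estimates the pair-distance distribution `p(r)` on `[0, dmax]` by
#' regularised least squares: non-negative `p`, zero endpoints, a
#' second-difference smoothness penalty, and sigma-weighted data misfit.
#' `dmax` is scanned over a range and selected as the smallest value whose
#' regularised misfit comes within 5% of the scan minimum (the start of the
#' misfit plateau, which stabilises the estimate).
#'
#' @param profile A `saxs_profile` with sigma.
#' @param dmax_scan Candidate dmax values (nm); default 4..25 nm.
#' @param lambda Smoothness weight.
#' @param n_r Number of r-grid points.
#' @param q_range q window used for the inversion (nm^-1).
#' @param sigma_floor_frac Uncertainties are floored at this fraction of the
#'   maximum intensity in the window, so that near-zero minima of
#'   low-noise profiles do not receive unbounded weight.
#' @return A `pair_distribution` with extra fields `chi` (weighted residual
#'   of the selected fit) and `scan` (data frame of the dmax scan).
#' @export
ift <- function(profile, dmax_scan = seq(4, 25, by = 0.5), lambda = 1e-3,
                n_r = 60, q_range = c(0.1, 3.5), sigma_floor_frac = 1e-4) {
  if (is.null(profile$sigma)) stop("ift needs a profile with sigma")
  sel <- profile$q >= q_range[1] & profile$q <= q_range[2] &
    profile$intensity > 0
  q <- profile$q[sel]; I <- profile$intensity[sel]; sig <- profile$sigma[sel]
  sig <- pmax(sig, sigma_floor_frac * max(I))
  if (length(q) < 10) stop("too few points in the fitting window")
  # normalise for conditioning
  scale <- max(I)
  I <- I / scale; sig <- sig / scale
  fits <- lapply(dmax_scan, function(dm) .ift_solve(q, I, sig, dm, n_r, lambda))
  chis <- vapply(fits, function(f) f$chi, numeric(1))
  feas <- which(is.finite(chis))
  if (!length(feas)) stop("dmax scan excludes all feasible values")
  best_chi <- min(chis[feas])
  pick <- feas[which(chis[feas] <= best_chi * 1.05)[1]]
  f <- fits[[pick]]
  p <- f$p
  nz <- which(p > 0)
  dmax_eff <- if (length(nz)) f$r[max(nz) + 1] else dmax_scan[pick]
  dmax_eff <- min(dmax_eff, dmax_scan[pick], na.rm = TRUE)
  rg <- sqrt(sum(f$r^2 * p) / (2 * sum(p)))
  structure(list(r = f$r, p = p, dmax = dmax_eff, rg = rg, chi = f$chi,
                 scan = data.frame(dmax = dmax_scan, chi = chis)),
            class = "pair_distribution")
}

#' Scale-fitted chi agreement between a model and an experimental profile
#'
#' The model profile is interpolated onto the experimental grid (linear in
#' log intensity); the scale `c` minimising the sigma-weighted squared
#' residual has a closed form, and
#' `chi = sqrt( sum(((I_e - c I_m)/sigma)^2) / (N - 1) )`.
#'
#' @param model_profile Theoretical `saxs_profile`.
#' @param exp_profile Experimental `saxs_profile` with sigma.
#' @param q_range Optional q window restriction (nm^-1).
#' @return List of class `chi_fit`: `scale`, `chi`, `n_points`.
#' @export
chi_fit <- function(model_profile, exp_profile, q_range = NULL) {
  if (is.null(exp_profile$sigma)) stop("experimental profile needs sigma")
  lo <- max(min(model_profile$q), min(exp_profile$q))
  hi <- min(max(model_profile$q), max(exp_profile$q))
  if (!is.null(q_range)) { lo <- max(lo, q_range[1]); hi <- min(hi, q_range[2]) }
  sel <- exp_profile$q >= lo & exp_profile$q <= hi
  if (sum(sel) < 3) stop("fewer than 3 overlapping points")
  qe <- exp_profile$q[sel]
  Ie <- exp_profile$intensity[sel]
  sig <- exp_profile$sigma[sel]
  Im <- .interp_log(model_profile, qe)
  cc <- sum(Ie * Im / sig^2) / sum(Im^2 / sig^2)
  chi <- sqrt(sum(((Ie - cc * Im) / sig)^2) / (sum(sel) - 1))
  structure(list(scale = cc, chi = chi, n_points = sum(sel)),
            class = "chi_fit")
}

#' @export
print.chi_fit <- function(x, ...) {
  cat(sprintf("chi fit: c = %.4g, chi = %.3f (%d pts)\n",
              x$scale, x$chi, x$n_points))
  invisible(x)
}

#' Volatility ratio between two scattering profiles
#'
#' The ratio `R(q) = I_a / I_b` is formed on profile `a`'s grid over
#' 0.15-1.5 nm^-1, averaged in bins of width `pi/d` (d = 40 nm, about
#' 0.0785 nm^-1; the final partial bin is included), and the volatility of
#' the binned ratio is
#' `V_r = (1/N) * sum |R(i) - R(i+1)| / ((R(i) + R(i+1))/2) * 100`.
#' The statistic is invariant under separate rescaling of either profile
#' and symmetric in its arguments.
#'
#' @param a,b `saxs_profile` objects covering (or interpolable over) the
#'   comparison range.
#' @param q_range Comparison window in nm^-1.
#' @param d Bin-defining length (nm).
#' @return List of class `vr_result`: `value`, `bins` (edges), `ratio`
#'   (per-bin means), `range`, `d`.
#' @export
volatility_ratio <- function(a, b, q_range = c(0.15, 1.5), d = 40) {
  lo <- max(q_range[1], min(a$q), min(b$q))
  hi <- min(q_range[2], max(a$q), max(b$q))
  sel <- a$q >= lo & a$q <= hi
  q <- a$q[sel]
  if (length(q) < 10) stop("profiles do not cover the comparison range")
  if (all(b$intensity[b$q >= lo & b$q <= hi] <= 0)) {
    stop("denominator profile has non-positive intensity in range")
  }
  # both profiles go through the same positive log-linear interpolation so
  # that swapping the arguments yields the exact reciprocal ratio
  Ia <- .interp_log(a, q)
  Ib <- .interp_log(b, q)
  R <- Ia / Ib
  width <- pi / d
  edges <- seq(q_range[1], hi + width, by = width)
  binid <- findInterval(q, edges, rightmost.closed = TRUE)
  # geometric per-bin average: the average of a ratio that is exactly
  # reciprocal under swapping the two profiles, which together with
  # |r - 1/r| / ((r + 1/r)/2) symmetry makes V_r(a, b) = V_r(b, a) exact
  Rbin <- exp(tapply(log(R), binid, mean))
  Rbin <- as.numeric(Rbin[!is.na(Rbin)])
  if (length(Rbin) < 2) stop("need at least two ratio bins")
  N <- length(Rbin) - 1
  vr <- sum(abs(diff(Rbin)) / ((Rbin[-length(Rbin)] + Rbin[-1]) / 2)) / N * 100
  structure(list(value = vr, bins = edges, ratio = Rbin,
                 range = c(lo, hi), d = d),
            class = "vr_result")
}

#' @export
print.vr_result <- function(x, ...) {
  cat(sprintf("V_r = %.3f over q = %.2f..%.2f nm^-1 (%d bins)\n",
              x$value, x$range[1], x$range[2], length(x$ratio)))
  invisible(x)
}

#' Pairwise volatility-ratio matrix
#'
#' @param profiles List of `saxs_profile` (>= 2), optionally named.
#' @param ... Passed to [volatility_ratio()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
vr_matrix <- function(profiles, ...) {
  n <- length(profiles)
  if (n < 2) stop("need at least two profiles")
  labs <- vapply(seq_len(n), function(i) {
    nm <- names(profiles)[i]
    if (!is.null(nm) && nzchar(nm)) nm else profiles[[i]]$label
  }, character(1))
  M <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- volatility_ratio(profiles[[i]], profiles[[j]], ...)$value
      M[i, j] <- M[j, i] <- v
    }
  }
  M
}

#' Export a p(r) curve as two-column text
#'
#' @param pr A `pair_distribution`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pr <- function(pr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p(r): dmax = %.4f nm, Rg = %.4f nm", pr$dmax, pr$rg),
             con)
  writeLines(sprintf("%.6e %.6e", pr$r, pr$p), con)
  invisible(path)
}
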