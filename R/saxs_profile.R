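#' SAXS profiles
#'
#' A small-angle scattering profile: momentum-transfer grid `q` (canonical
#' units nm^-1), intensities in arbitrary units, and optional per-point
#' uncertainties.
#'
#' @param q Strictly increasing positive grid (nm^-1).
#' @param intensity Intensities (same length).
#' @param sigma Optional per-point standard deviations (> 0).
#' @param label Name carried through analyses.
#' @return Object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "profile") {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(q <= 0) || any(diff(q) <= 0)) {
    stop("q must be strictly increasing and positive")
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs")
    if (any(sigma < 0)) stop("negative sigma")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma, label = label),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("saxs_profile '%s': %d points, q = %.4g..%.4g nm^-1%s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) " (no sigma)" else ""))
  invisible(x)
}

#' Read a 3-column scattering profile
#'
#' Reads the whitespace-delimited `q I [sigma]` dialect used by scattering
#' data banks. Comment and header lines are tolerated. Units are
#' auto-normalised to nm^-1: a grid whose maximum is below the `unit_threshold`
#' is taken to be in inverse Angstrom and multiplied by 10 (the heuristic can
#' be overridden with `units`). A missing sigma column is synthesised as
#' `sigma_fraction` of the intensity and flagged in the result.
#'
#' @param path File path.
#' @param units `"auto"`, `"nm"` or `"angstrom"`.
#' @param unit_threshold Heuristic threshold on max(q) (default 1.0).
#' @param sigma_fraction Fraction of I used when sigma is absent.
#' @param label Profile label (defaults to the file name).
#' @return A `saxs_profile`; attribute `synthetic_sigma` is `TRUE` when sigma
#'   was synthesised.
#' @export
read_profile <- function(path, units = c("auto", "nm", "angstrom"),
                         unit_threshold = 1.0, sigma_fraction = 0.02,
                         label = NULL) {
  units <- match.arg(units)
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2) return(NULL)
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals[1:2])) return(NULL)
    vals
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) < 2) stop("no data rows found in ", path)
  ncols <- min(vapply(rows, length, integer(1)))
  m <- t(vapply(rows, function(r) r[seq_len(min(ncols, 3))],
                numeric(min(ncols, 3))))
  keep <- m[, 1] > 0
  m <- m[keep, , drop = FALSE]
  q <- m[, 1]
  if (any(diff(q) <= 0)) stop("non-monotone q grid")
  if (units == "angstrom" || (units == "auto" && max(q) < unit_threshold)) {
    q <- q * 10
  }
  has_sigma <- ncol(m) >= 3 && all(is.finite(m[, 3]))
  if (has_sigma && any(m[, 3] < 0)) stop("negative sigma")
  sigma <- if (has_sigma) m[, 3] else abs(m[, 2]) * sigma_fraction
  p <- saxs_profile(q, m[, 2], sigma,
                    label = if (is.null(label)) basename(path) else label)
  attr(p, "synthetic_sigma") <- !has_sigma
  p
}

#' Write a profile as 3-column text
#'
#' @param profile A `saxs_profile`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", profile$label), con)
  writeLines("#  q(nm^-1)        I(q)          sigma", con)
  sig <- if (is.null(profile$sigma)) rep(NA_real_, length(profile$q))
         else profile$sigma
  writeLines(sprintf("%.8e %.8e %.8e", profile$q, profile$intensity, sig),
             con)
  invisible(path)
}

# interpolate a profile onto a new q grid, linear in (q, log I)
.interp_log <- function(profile, q_new) {
  ok <- profile$intensity > 0
  logI <- stats::approx(profile$q[ok], log(profile$intensity[ok]),
                        xout = q_new, rule = 2)$y
  exp(logI)
}
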