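#' Fluorescence spectra and FRET ratio
#'
#' @name fret
NULL

#' Construct an emission spectrum
#'
#' @param wavelength Increasing wavelength grid (nm).
#' @param intensity Relative fluorescence units.
#' @return Object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength, intensity) {
  if (length(wavelength) != length(intensity)) stop("length mismatch")
  if (any(diff(wavelength) <= 0)) stop("wavelengths must increase")
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity)),
            class = "emission_spectrum")
}

#' Acceptor / donor FRET ratio
#'
#' Ratio of the acceptor emission (default 668 nm, sulfo-Cy5) to the donor
#' emission (default 566 nm, sulfo-Cy3), read off the spectrum by linear
#' interpolation. Dimensionless and invariant under global intensity
#' scaling.
#'
#' @param spectrum An `emission_spectrum` covering both wavelengths.
#' @param acceptor_nm,donor_nm Evaluation wavelengths (nm).
#' @return FRET ratio F(A)/F(D).
#' @export
fret_ratio <- function(spectrum, acceptor_nm = 668, donor_nm = 566) {
  rng <- range(spectrum$wavelength)
  if (acceptor_nm < rng[1] || acceptor_nm > rng[2] ||
      donor_nm < rng[1] || donor_nm > rng[2]) {
    stop("spectrum does not cover both evaluation wavelengths")
  }
  fa <- stats::approx(spectrum$wavelength, spectrum$intensity,
                      xout = acceptor_nm)$y
  fd <- stats::approx(spectrum$wavelength, spectrum$intensity,
                      xout = donor_nm)$y
  if (fd == 0) stop("donor emission is zero")
  fa / fd
}

#' Read / write a 2-column emission spectrum
#' @param path File with wavelength and intensity columns.
#' @return An `emission_spectrum`.
#' @export
read_spectrum <- function(path) {
  m <- utils::read.table(path, comment.char = "#")
  emission_spectrum(m[[1]], m[[2]])
}

#' @rdname read_spectrum
#' @param spectrum An `emission_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(data.frame(spectrum$wavelength, spectrum$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
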