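# Spectra and the donor-acceptor spectral overlap integral.

#' Construct a spectrum
#'
#' A spectrum is a two-column table of wavelength (nm) versus either emission
#' intensity (arbitrary units) or molar extinction (M^-1 cm^-1).
#'
#' @param wavelength_nm strictly increasing wavelength grid, nm.
#' @param value non-negative finite intensities or extinction coefficients.
#' @param kind `"emission"` or `"extinction"`.
#' @return an object of class `fret_spectrum`.
#' @export
spectrum <- function(wavelength_nm, value, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2)
    stop("a spectrum needs at least 2 points")
  if (length(value) != length(wavelength_nm))
    stop("wavelength and value lengths differ")
  if (any(!is.finite(wavelength_nm)) || any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(value)) || any(value < 0))
    stop("spectrum values must be finite and non-negative")
  structure(list(wavelength_nm = wavelength_nm, value = value, kind = kind),
            class = "fret_spectrum")
}

#' Read a spectrum from a two-column CSV/TSV file
#'
#' The file must have a header; the first column is wavelength in nm, the
#' second the value. Tab-separated files are detected by the `.tsv`/`.tab`
#' extension.
#'
#' @param path file path.
#' @param kind `"emission"` or `"extinction"`.
#' @return a [spectrum()] object.
#' @export
read_spectrum <- function(path, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.csv(path, sep = sep)
  if (ncol(d) < 2) stop("expected two columns in ", path)
  spectrum(d[[1]], d[[2]], kind)
}

#' Spectral overlap integral J
#'
#' Computes the FRET overlap integral
#' \deqn{J = \frac{\int F_D(\lambda)\,\epsilon_A(\lambda)\,\lambda^4\,
#'   d\lambda}{\int F_D(\lambda)\, d\lambda}}
#' by trapezoid quadrature on the union grid of the two spectra restricted to
#' their common wavelength range, with linear interpolation of both spectra
#' onto that grid. Units: nm^4 M^-1 cm^-1 when wavelengths are in nm and the
#' acceptor spectrum is molar extinction in M^-1 cm^-1. Quadrature accuracy is
#' limited by the input grids; supply densely sampled spectra for converged
#' values.
#'
#' @param donor_em donor emission [spectrum()].
#' @param acceptor_ext acceptor extinction [spectrum()].
#' @return overlap integral J, nm^4 M^-1 cm^-1.
#' @export
overlap_integral <- function(donor_em, acceptor_ext) {
  stopifnot(inherits(donor_em, "fret_spectrum"),
            inherits(acceptor_ext, "fret_spectrum"))
  if (donor_em$kind != "emission")
    stop("donor_em must be an emission spectrum")
  if (acceptor_ext$kind != "extinction")
    stop("acceptor_ext must be an extinction spectrum")
  lo <- max(min(donor_em$wavelength_nm), min(acceptor_ext$wavelength_nm))
  hi <- min(max(donor_em$wavelength_nm), max(acceptor_ext$wavelength_nm))
  if (lo >= hi) stop("disjoint spectra: no common wavelength range")
  grid <- sort(unique(c(lo, hi,
                        donor_em$wavelength_nm[donor_em$wavelength_nm >= lo &
                                               donor_em$wavelength_nm <= hi],
                        acceptor_ext$wavelength_nm[
                          acceptor_ext$wavelength_nm >= lo &
                          acceptor_ext$wavelength_nm <= hi])))
  fd <- approx(donor_em$wavelength_nm, donor_em$value, grid)$y
  ea <- approx(acceptor_ext$wavelength_nm, acceptor_ext$value, grid)$y
  denom <- trapz(grid, fd)
  if (denom <= 0) stop("all-zero donor emission over the overlap range")
  trapz(grid, fd * ea * grid^4) / denom
}
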