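# Foerster radius, FRET efficiency and donor-acceptor distance inversion.

#' Dye-pair photophysics
#'
#' Bundles the quantities that determine the Foerster radius: the spectral
#' overlap integral J, the donor quantum yield, the orientation factor
#' kappa^2 and the refractive index of the medium (1.0 for vacuum / gas
#' phase, 1.33 for water).
#'
#' @param J overlap integral, nm^4 M^-1 cm^-1 (> 0).
#' @param phi_D donor fluorescence quantum yield, in (0, 1].
#' @param kappa2 orientation factor, in (0, 4]. Default 2/3, the isotropic
#'   dynamic-averaging value.
#' @param n refractive index of the medium, >= 1.
#' @return an object of class `dye_photophysics`.
#' @export
dye_photophysics <- function(J, phi_D, kappa2 = 2 / 3, n = 1.0) {
  if (!is.finite(J) || J <= 0) stop("J must be positive")
  if (!is.finite(phi_D) || phi_D <= 0 || phi_D > 1)
    stop("phi_D must be in (0, 1]")
  if (!is.finite(kappa2) || kappa2 <= 0 || kappa2 > 4)
    stop("kappa2 must be in (0, 4]")
  if (!is.finite(n) || n < 1) stop("refractive index must be >= 1")
  structure(list(J = J, phi_D = phi_D, kappa2 = kappa2, n = n),
            class = "dye_photophysics")
}

#' Foerster radius
#'
#' \deqn{R_0 = 0.211\,(\kappa^2\, n^{-4}\, \Phi_D\, J)^{1/6}\ \mathrm{\AA}}
#' with J in nm^4 M^-1 cm^-1. The 0.211 prefactor is the standard constant
#' for these units.
#'
#' @param p a [dye_photophysics()] object.
#' @return Foerster radius R0 in Angstrom.
#' @export
forster_radius <- function(p) {
  stopifnot(inherits(p, "dye_photophysics"))
  0.211 * (p$kappa2 * p$n^-4 * p$phi_D * p$J)^(1 / 6)
}

#' FRET efficiency from donor lifetimes
#'
#' \deqn{E = 1 - \tau_{DA}/\tau_D}
#' where `tau_DA` is the donor lifetime in presence of the acceptor and
#' `tau_D` the donor-only lifetime. A measured `tau_DA` exceeding `tau_D`
#' (a negative-transfer artifact) is clamped to E = 0 with a warning.
#'
#' @param tau_DA donor lifetime with acceptor, ns (vectorised).
#' @param tau_D donor-only lifetime, ns.
#' @return efficiency in \[0, 1).
#' @export
fret_efficiency <- function(tau_DA, tau_D) {
  if (!is.finite(tau_D) || tau_D <= 0) stop("tau_D must be positive")
  if (any(!is.finite(tau_DA)) || any(tau_DA <= 0))
    stop("tau_DA must be positive")
  E <- 1 - tau_DA / tau_D
  if (any(E < 0)) {
    warning("tau_DA > tau_D: negative-transfer artifact, efficiency ",
            "clamped to 0")
    E[E < 0] <- 0
  }
  E
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Inverts \eqn{E = 1/(1 + (r/R_0)^6)}:
#' \deqn{r_{DA} = R_0\,\left(\frac{1-E}{E}\right)^{1/6}.}
#'
#' @param E FRET efficiency, strictly inside (0, 1) (vectorised).
#' @param R0 Foerster radius, Angstrom.
#' @return distance r_DA in Angstrom.
#' @export
distance_from_efficiency <- function(E, R0) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("distance undefined at efficiency bound")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency at a given donor-acceptor distance
#'
#' \deqn{E = \frac{1}{1 + (r/R_0)^6}}
#'
#' @param r donor-acceptor distance, Angstrom (vectorised).
#' @param R0 Foerster radius, Angstrom.
#' @return efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, R0) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  1 / (1 + (r / R0)^6)
}
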