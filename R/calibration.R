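# TWIM CCS calibration against a calibrant table (power-law / log-log fit).

#' Construct a TWIM calibrant table
#'
#' @param mz calibrant m/z values, Th.
#' @param charge integer charge states.
#' @param ccs_ref_A2 reference CCS values, Angstrom^2.
#' @param drift_time_ms measured drift times, ms.
#' @param gas_mass_Da buffer-gas molecular mass; default 28.0134 (N2).
#' @return a data frame of class `calibrant_table`.
#' @export
calibrant_table <- function(mz, charge, ccs_ref_A2, drift_time_ms,
                            gas_mass_Da = 28.0134) {
  d <- data.frame(mz = as.numeric(mz), charge = as.integer(charge),
                  ccs_ref_A2 = as.numeric(ccs_ref_A2),
                  drift_time_ms = as.numeric(drift_time_ms))
  if (nrow(d) < 3) stop("need at least 3 calibrants")
  if (any(!is.finite(as.matrix(d))) || any(as.matrix(d) <= 0))
    stop("all calibrant values must be positive")
  # drift must increase with reduced CCS within each charge state
  for (z in unique(d$charge)) {
    s <- d[d$charge == z, ]
    if (nrow(s) >= 2) {
      o <- order(s$ccs_ref_A2 * sqrt(reduced_mass(s$mz * s$charge,
                                                  gas_mass_Da)) / s$charge)
      if (any(diff(s$drift_time_ms[o]) <= 0))
        stop("drift times not monotone in reduced CCS for charge ", z)
    }
  }
  attr(d, "gas_mass_Da") <- gas_mass_Da
  class(d) <- c("calibrant_table", "data.frame")
  d
}

#' Read a calibrant table from CSV
#'
#' Columns `mz`, `charge`, `ccs_ref_A2`, `drift_time_ms`.
#' @param path file path.
#' @param gas_mass_Da buffer-gas mass, Da.
#' @return a [calibrant_table()].
#' @export
read_calibrants <- function(path, gas_mass_Da = 28.0134) {
  d <- read.csv(path)
  calibrant_table(d$mz, d$charge, d$ccs_ref_A2, d$drift_time_ms, gas_mass_Da)
}

#' @noRd
reduced_mass <- function(ion_mass_Da, gas_mass_Da) {
  ion_mass_Da * gas_mass_Da / (ion_mass_Da + gas_mass_Da)
}

#' Calibrate an analyte CCS from TWIM drift time
#'
#' Standard travelling-wave power-law calibration: for each calibrant the
#' drift time is dead-time corrected, \eqn{t' = t_D - c\sqrt{m/z}}, and the
#' reference CCS reduced, \eqn{CCS' = CCS_{ref}\sqrt{\mu}/z} with \eqn{\mu}
#' the ion/buffer-gas reduced mass. A linear fit of \eqn{\ln CCS'} against
#' \eqn{\ln t'} then converts the analyte's corrected drift time into its
#' CCS.
#'
#' @param tab a [calibrant_table()].
#' @param analyte_mz analyte m/z, Th.
#' @param analyte_charge analyte charge.
#' @param analyte_drift_ms analyte drift time, ms.
#' @param edc_delay_coeff instrument dead-time coefficient c in
#'   \eqn{t' = t_D - c\sqrt{m/z}} (ms per sqrt(Th)); default 0.
#' @return list with `ccs_A2` and `fit` (class `twim_calibration`:
#'   `slope`, `intercept`, `r_squared`, `edc_delay_coeff`).
#' @export
twim_calibrate <- function(tab, analyte_mz, analyte_charge,
                           analyte_drift_ms, edc_delay_coeff = 0) {
  stopifnot(inherits(tab, "calibrant_table"))
  gas <- attr(tab, "gas_mass_Da")
  tp <- tab$drift_time_ms - edc_delay_coeff * sqrt(tab$mz)
  if (any(tp <= 0)) stop("dead-time correction produced non-positive drift")
  mu <- reduced_mass(tab$mz * tab$charge, gas)
  ccsp <- tab$ccs_ref_A2 * sqrt(mu) / tab$charge
  fit <- lm(log(ccsp) ~ log(tp))
  sst <- sum((log(ccsp) - mean(log(ccsp)))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  if (r2 < 0.98) warning("poor calibration: r^2 = ", signif(r2, 4))
  ta <- analyte_drift_ms - edc_delay_coeff * sqrt(analyte_mz)
  if (ta < min(tp) || ta > max(tp))
    warning("analyte drift time outside calibrated range; extrapolating")
  mua <- reduced_mass(analyte_mz * analyte_charge, gas)
  ccs <- exp(coef(fit)[[1]] + coef(fit)[[2]] * log(ta)) *
    analyte_charge / sqrt(mua)
  list(ccs_A2 = unname(ccs),
       fit = structure(list(slope = coef(fit)[[2]],
                            intercept = coef(fit)[[1]],
                            r_squared = r2,
                            edc_delay_coeff = edc_delay_coeff),
                       class = "twim_calibration"))
}

#' Simulate a calibrant table from an exact power law
#'
#' Generates drift times satisfying
#' \eqn{\ln CCS' = a \ln t' + b} exactly; useful as a fixture where the
#' calibration model class contains the truth.
#'
#' @param mz,charge,ccs_ref_A2 calibrant properties (equal lengths).
#' @param slope,intercept power-law parameters a, b.
#' @param gas_mass_Da buffer-gas mass, Da.
#' @return a [calibrant_table()].
#' @export
simulate_calibrant_table <- function(mz, charge, ccs_ref_A2, slope = 0.55,
                                     intercept = -1.0,
                                     gas_mass_Da = 28.0134) {
  mu <- reduced_mass(mz * charge, gas_mass_Da)
  ccsp <- ccs_ref_A2 * sqrt(mu) / charge
  drift <- exp((log(ccsp) - intercept) / slope)
  calibrant_table(mz, charge, ccs_ref_A2, drift, gas_mass_Da)
}
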