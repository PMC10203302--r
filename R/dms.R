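# Differential ion mobility (DMS) ionograms: simulation, peak detection
# and modifier-concentration CV-shift series.

#' Construct an ionogram
#'
#' Intensity versus compensation voltage (CV) for one species at one gas
#' modifier concentration.
#'
#' @param cv_V strictly increasing CV grid within \[-100, 100\] V.
#' @param intensity non-negative intensities.
#' @param modifier_mol_percent gas-modifier concentration, mol %.
#' @param dispersion_voltage_kV dispersion voltage metadata, kV.
#' @param species_label species identifier.
#' @return an object of class `ionogram`.
#' @export
ionogram <- function(cv_V, intensity, modifier_mol_percent = 0,
                     dispersion_voltage_kV = 4.5, species_label = "") {
  cv_V <- as.numeric(cv_V); intensity <- as.numeric(intensity)
  if (length(cv_V) < 3 || length(cv_V) != length(intensity))
    stop("cv_V and intensity must be equal-length (>= 3)")
  if (any(diff(cv_V) <= 0)) stop("CV grid must be strictly increasing")
  if (min(cv_V) < -100 || max(cv_V) > 100)
    stop("CV grid must lie within [-100, 100] V")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  structure(list(cv_V = cv_V, intensity = intensity,
                 modifier_mol_percent = modifier_mol_percent,
                 dispersion_voltage_kV = dispersion_voltage_kV,
                 species_label = species_label),
            class = "ionogram")
}

#' Read an ionogram from CSV
#'
#' Two columns `cv_V`, `intensity`; metadata in leading `#` lines
#' (`# modifier_mol_percent: x`, `# dispersion_voltage_kV: x`,
#' `# species_label: s`).
#'
#' @param path file path.
#' @return an [ionogram()].
#' @export
read_ionogram <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key, cast = as.numeric, default) {
    m <- grep(key, meta, value = TRUE)
    if (length(m)) cast(trimws(sub(paste0(".*", key, ":\\s*"), "", m[1])))
    else default
  }
  d <- read.csv(text = lines[!grepl("^#", lines)])
  ionogram(d[[1]], d[[2]],
           modifier_mol_percent = get("modifier_mol_percent", default = 0),
           dispersion_voltage_kV = get("dispersion_voltage_kV",
                                       default = 4.5),
           species_label = get("species_label", as.character, ""))
}

#' Simulate an ionogram
#'
#' Gaussian peak(s) centred at `base_cv_V + shift_slope * concentration`
#' plus seeded Gaussian noise (clipped at 0).
#'
#' @param base_cv_V peak CV position(s) at zero modifier, V.
#' @param shift_slope_V_per_molpct CV shift per mol % modifier.
#' @param width_V Gaussian sigma(s), V.
#' @param height peak height(s), counts.
#' @param noise_sd additive Gaussian noise sd, counts.
#' @param concentration modifier concentration, mol %.
#' @param seed RNG seed.
#' @param cv_grid CV axis, V.
#' @param species_label species identifier.
#' @return an [ionogram()].
#' @export
simulate_ionogram <- function(base_cv_V, shift_slope_V_per_molpct = 0,
                              width_V = 0.5, height = 1000, noise_sd = 0,
                              concentration = 0, seed = 1,
                              cv_grid = seq(-30, 30, by = 0.05),
                              species_label = "") {
  stopifnot(all(width_V > 0), concentration >= 0)
  k <- length(base_cv_V)
  width_V <- rep_len(width_V, k)
  height <- rep_len(height, k)
  slope <- rep_len(shift_slope_V_per_molpct, k)
  y <- rep(0, length(cv_grid))
  for (i in seq_len(k)) {
    mu <- base_cv_V[i] + slope[i] * concentration
    y <- y + height[i] * exp(-(cv_grid - mu)^2 / (2 * width_V[i]^2))
  }
  if (noise_sd > 0)
    y <- pmax(y + with_seed(seed, rnorm(length(y), 0, noise_sd)), 0)
  ionogram(cv_grid, y, modifier_mol_percent = concentration,
           species_label = species_label)
}

#' Detect peaks in an ionogram
#'
#' Gaussian smoothing (kernel FWHM `smooth_fwhm_V`), local maxima with
#' prominence at least `min_prominence_fraction` of the global maximum,
#' full width at half maximum by interpolated half-height crossings, and
#' the trapezoid area between the flanking half-height crossings.
#' Deterministic; a flat or sub-prominence signal yields an empty peak set.
#'
#' @param ion an [ionogram()].
#' @param smooth_fwhm_V smoothing kernel FWHM, V (0 disables smoothing).
#' @param min_prominence_fraction required prominence as a fraction of the
#'   maximum smoothed intensity, in (0, 1).
#' @return a data frame of class `peak_set` (`cv_V`, `height`, `fwhm_V`,
#'   `area`, `prominence`), sorted by CV.
#' @export
detect_peaks <- function(ion, smooth_fwhm_V = 0.5,
                         min_prominence_fraction = 0.05) {
  stopifnot(inherits(ion, "ionogram"))
  if (min_prominence_fraction <= 0 || min_prominence_fraction >= 1)
    stop("min_prominence_fraction must be in (0, 1)")
  x <- ion$cv_V; y <- ion$intensity
  if (smooth_fwhm_V > 0) {
    dx <- median(diff(x))
    sig <- smooth_fwhm_V / (2 * sqrt(2 * log(2))) / dx
    half <- max(1L, ceiling(3 * sig))
    kern <- exp(-(-half:half)^2 / (2 * sig^2))
    # renormalising convolution keeps the edges unbiased
    num <- as.numeric(stats::filter(y, kern, sides = 2))
    den <- as.numeric(stats::filter(rep(1, length(y)), kern, sides = 2))
    pad <- is.na(num)
    ys <- y
    ys[!pad] <- num[!pad] / den[!pad]
    # edge bins: renormalise over the available window
    for (i in which(pad)) {
      w <- max(1, i - half):min(length(y), i + half)
      kk <- kern[w - i + half + 1]
      ys[i] <- sum(y[w] * kk) / sum(kk)
    }
  } else ys <- y
  empty <- data.frame(cv_V = numeric(0), height = numeric(0),
                      fwhm_V = numeric(0), area = numeric(0),
                      prominence = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  ymax <- max(ys)
  if (ymax <= 0) return(empty)
  n <- length(ys)
  cand <- which(diff(sign(diff(ys))) < 0) + 1L
  cand <- cand[ys[cand] > 0]
  if (!length(cand)) return(empty)
  # prominence: height above the higher of the two key saddles
  prom <- vapply(cand, function(i) {
    h <- ys[i]
    lmin <- h; j <- i
    while (j > 1 && ys[j] <= h) { j <- j - 1; lmin <- min(lmin, ys[j]) }
    left <- if (ys[j] > h) lmin else min(ys[1:i])
    rmin <- h; j <- i
    while (j < n && ys[j] <= h) { j <- j + 1; rmin <- min(rmin, ys[j]) }
    right <- if (ys[j] > h) rmin else min(ys[i:n])
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence_fraction * ymax
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  rows <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    h <- ys[i]; hh <- h / 2
    # walk down each flank to the interpolated half-height crossing; a
    # valley above half height (merged peaks) truncates the width there
    j <- i
    while (j > 1 && ys[j] > hh && ys[j - 1] <= ys[j]) j <- j - 1
    lx <- if (ys[j] <= hh && j < i)
      x[j] + (hh - ys[j]) / (ys[j + 1] - ys[j]) * (x[j + 1] - x[j])
    else x[j]
    j <- i
    while (j < n && ys[j] > hh && ys[j + 1] <= ys[j]) j <- j + 1
    rx <- if (ys[j] <= hh && j > i)
      x[j - 1] + (hh - ys[j - 1]) / (ys[j] - ys[j - 1]) * (x[j] - x[j - 1])
    else x[j]
    sel <- x >= lx & x <= rx
    data.frame(cv_V = x[i], height = h, fwhm_V = rx - lx,
               area = trapz(x[sel], y[sel]), prominence = prom[k])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cv_V), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  attr(out, "smooth_fwhm_V") <- smooth_fwhm_V
  attr(out, "min_prominence_fraction") <- min_prominence_fraction
  out
}

#' CV shift versus modifier concentration
#'
#' Tracks the dominant (highest) peak across a series of ionograms of one
#' species at increasing modifier concentrations, reports the shift
#' relative to the lowest concentration and the least-squares slope.
#' Concentrations whose ionogram has no detectable peak are reported as
#' gaps and excluded from the fit. A larger |slope| indicates a stronger
#' clustering propensity with the modifier; the comparison across species
#' is qualitative (see [rank_clustering_propensity()]).
#'
#' @param series list of [ionogram()]s of the same species.
#' @param ... passed to [detect_peaks()].
#' @return a list of class `cv_shift_series`: `concentration`, `cv_V`,
#'   `shift_V`, `slope_V_per_molpct`, `species_label`, `gaps`.
#' @export
cv_shift_series <- function(series, ...) {
  stopifnot(is.list(series), length(series) >= 2)
  labs <- unique(vapply(series, function(x) x$species_label, character(1)))
  if (length(labs) > 1)
    stop("series mixes species: ", paste(labs, collapse = ", "))
  conc <- vapply(series, function(x) x$modifier_mol_percent, numeric(1))
  o <- order(conc)
  series <- series[o]; conc <- conc[o]
  cv <- vapply(series, function(ig) {
    pk <- detect_peaks(ig, ...)
    if (!nrow(pk)) return(NA_real_)
    pk$cv_V[which.max(pk$height)]
  }, numeric(1))
  gaps <- conc[is.na(cv)]
  ok <- !is.na(cv)
  if (sum(ok) < 2) stop("fewer than 2 concentrations with a dominant peak")
  ref <- cv[ok][1]
  slope <- unname(coef(lm(cv[ok] ~ conc[ok]))[2])
  structure(list(concentration = conc, cv_V = cv, shift_V = cv - ref,
                 slope_V_per_molpct = slope, species_label = labs,
                 gaps = gaps),
            class = "cv_shift_series")
}

#' Rank species by modifier clustering propensity
#'
#' Orders CV-shift series by decreasing |slope|; a purely qualitative
#' ranking of how strongly each species clusters with the gas modifier.
#'
#' @param series_list list of [cv_shift_series()] results.
#' @return data frame `species`, `slope_V_per_molpct`, `rank`.
#' @export
rank_clustering_propensity <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  d <- data.frame(
    species = vapply(series_list, function(s) s$species_label,
                     character(1)),
    slope_V_per_molpct = vapply(series_list,
                                function(s) s$slope_V_per_molpct,
                                numeric(1)))
  d <- d[order(-abs(d$slope_V_per_molpct)), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}
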