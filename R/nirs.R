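#' NIRS measurement geometry and chromophore constants
#'
#' Geometry for continuous-wave dual-wavelength oximetry: wavelengths,
#' source-detector separation, per-wavelength differential pathlength factor
#' (DPF) and the 2x2 extinction matrix `e[wavelength, chromophore]` in
#' 1/(uM*cm). Default extinction coefficients are the Prahl compendium molar
#' extinction values at 660 and 850 nm converted from 1/(M*cm); the DPF
#' default of 6.0 at both wavelengths is a common adult-head value and is
#' fully configurable, as is an optional partial-volume scaling.
#'
#' @param wavelengths Two wavelengths in nm (default 660, 850).
#' @param distance Source-detector distance in cm (default 3).
#' @param dpf Length-2 differential pathlength factors (default 6, 6).
#' @param extinction 2x2 matrix, rows = wavelengths, columns `hbo`, `hb`,
#'   units 1/(uM*cm).
#' @param partial_volume Optional scalar dividing recovered concentrations
#'   (default 1 = plain MBLL, no partial-volume correction).
#' @return An object of class `hp_nirs_geometry`.
#' @export
nirs_geometry <- function(wavelengths = c(660, 850),
                          distance = 3,
                          dpf = c(6, 6),
                          extinction = NULL,
                          partial_volume = 1) {
  if (distance <= 0) abort("`distance` must be > 0.", class = "hp_geometry_error")
  if (any(dpf <= 0)) abort("`dpf` must be > 0.", class = "hp_geometry_error")
  if (is.null(extinction)) {
    # Prahl tabulated molar extinction (1/(M*cm)) / 1e6 -> 1/(uM*cm)
    defaults <- rbind(`660` = c(hbo = 320.0, hb = 3226.56) / 1e6,
                      `850` = c(hbo = 1058.0, hb = 691.32) / 1e6)
    key <- as.character(wavelengths)
    if (!all(key %in% rownames(defaults)))
      abort("No default extinction values for these wavelengths; supply `extinction`.",
            class = "hp_geometry_error")
    extinction <- defaults[key, , drop = FALSE]
  }
  extinction <- as.matrix(extinction)
  if (!identical(dim(extinction), c(2L, 2L)))
    abort("`extinction` must be a 2x2 matrix (wavelength x {hbo, hb}).",
          class = "hp_geometry_error")
  colnames(extinction) <- c("hbo", "hb")
  if (kappa(extinction, exact = TRUE) > 1e6)
    abort("Extinction matrix is singular or ill-conditioned.", class = "hp_geometry_error")
  structure(list(wavelengths = wavelengths, distance = distance, dpf = dpf,
                 extinction = extinction, partial_volume = partial_volume),
            class = "hp_nirs_geometry")
}

#' @export
print.hp_nirs_geometry <- function(x, ...) {
  cat(sprintf("<hp_nirs_geometry> %g/%g nm, d = %g cm, DPF = %g/%g\n",
              x$wavelengths[1], x$wavelengths[2], x$distance, x$dpf[1], x$dpf[2]))
  invisible(x)
}

#' Optical-density change from a detected intensity channel
#'
#' `dOD(t) = -log10(I(t) / I_baseline)` with the baseline taken as the mean
#' intensity over `baseline_window`. Nonpositive intensity samples are a data
#' error (light cannot have negative counts; zeros make the log undefined).
#'
#' @param intensity A detected-intensity [timeseries()].
#' @param baseline_window Length-2 window (s) for the baseline mean; default
#'   the first 30 s (clipped to the recording).
#' @return A [timeseries()] of optical-density change (dimensionless).
#' @export
compute_delta_od <- function(intensity, baseline_window = c(0, 30)) {
  stopifnot(inherits(intensity, "hp_ts"))
  if (any(intensity$samples <= 0))
    abort("Nonpositive intensity sample: cannot form optical density.",
          class = "hp_data_error")
  tt <- ts_time(intensity)
  sel <- tt >= baseline_window[1] & tt <= baseline_window[2]
  if (!any(sel)) abort("Baseline window contains no samples.", class = "hp_param_error")
  i0 <- mean(intensity$samples[sel])
  timeseries(-log10(intensity$samples / i0), intensity$fs,
             start_time = intensity$start_time,
             label = paste0(intensity$label, "_dod"), units = "OD")
}

#' Hemoglobin concentration changes via the modified Beer-Lambert law
#'
#' Solves, sample by sample, the 2x2 linear system
#' `dOD(lambda) = d * DPF(lambda) * (e_HbO(lambda) dHbO + e_Hb(lambda) dHb)`
#' for the oxy- and deoxyhemoglobin concentration changes; total hemoglobin
#' is their sum by definition. Linear in the optical densities and
#' independent of the absolute baseline intensity.
#'
#' @param delta_od_1,delta_od_2 Optical-density [timeseries()] at the first
#'   and second geometry wavelength, sharing rate and length.
#' @param geom A [nirs_geometry()].
#' @return A tibble of class `hp_hemoglobin` with columns `time`, `hbo`,
#'   `hb`, `hbt` (uM); attribute `fs` carries the sampling rate.
#' @export
mbll_inverse <- function(delta_od_1, delta_od_2, geom = nirs_geometry()) {
  stopifnot(inherits(delta_od_1, "hp_ts"), inherits(delta_od_2, "hp_ts"),
            inherits(geom, "hp_nirs_geometry"))
  if (delta_od_1$fs != delta_od_2$fs ||
      length(delta_od_1$samples) != length(delta_od_2$samples))
    abort("The two optical-density series must share a time base.",
          class = "hp_param_error")
  M <- geom$extinction * geom$distance * geom$dpf  # row-wise: d * DPF(lambda) * e
  Minv <- solve(M)
  sol <- Minv %*% rbind(delta_od_1$samples, delta_od_2$samples)
  hbo <- sol[1, ] / geom$partial_volume
  hb <- sol[2, ] / geom$partial_volume
  out <- tibble(time = ts_time(delta_od_1), hbo = hbo, hb = hb, hbt = hbo + hb)
  attr(out, "fs") <- delta_od_1$fs
  class(out) <- c("hp_hemoglobin", class(out))
  out
}

#' Full NIRS conversion for a recording
#'
#' Convenience wrapper: optical densities from the two intensity channels,
#' then [mbll_inverse()].
#'
#' @param rec An [recording()] holding the two intensity channels.
#' @param channels Names of the intensity channels, in geometry wavelength
#'   order.
#' @param geom A [nirs_geometry()].
#' @param baseline_window Baseline window passed to [compute_delta_od()].
#' @return An `hp_hemoglobin` tibble.
#' @export
nirs_hemoglobin <- function(rec, channels = c("nirs660", "nirs850"),
                            geom = nirs_geometry(), baseline_window = c(0, 30)) {
  stopifnot(inherits(rec, "hp_recording"))
  missing <- setdiff(channels, names(rec$channels))
  if (length(missing))
    abort(sprintf("Recording lacks channel(s): %s", paste(missing, collapse = ", ")),
          class = "hp_config_error")
  od <- lapply(rec$channels[channels], compute_delta_od, baseline_window = baseline_window)
  mbll_inverse(od[[1]], od[[2]], geom)
}

#' @export
autoplot.hp_hemoglobin <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("hbo", "hb", "hbt"),
                              names_to = "chromophore", values_to = "delta")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$delta,
                                     colour = .data$chromophore)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "concentration (uM)"))
}
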