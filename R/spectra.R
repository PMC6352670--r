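# UV-Vis and IR curve synthesis from transition and harmonic-mode lists.

.kp_fwhm_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

.kp_new_spectrum <- function(axis, intensity, metadata) {
  structure(list(axis = axis, intensity = intensity, metadata = metadata),
            class = "kp_spectrum")
}

#' Synthesize a UV-Vis absorption curve from electronic transitions
#'
#' Transitions below the energy cutoff each contribute a Gaussian in the
#' energy domain, with amplitude proportional to the oscillator strength and
#' the stated full width at half maximum; the summed curve is then evaluated
#' on a wavelength grid via E(lambda) = 1239.842 / lambda (eV, nm). By
#' common quantum-chemistry visualization practice the energy-domain profile
#' is evaluated at E(lambda) without the dE/d(lambda) Jacobian factor;
#' `jacobian = TRUE` switches the factor on. Intensities are in arbitrary
#' units.
#'
#' @param transitions data frame (or 2-column matrix) with columns
#'   `energy_ev` and `strength` (oscillator strength, >= 0).
#' @param cutoff_ev transitions at or above this energy are dropped
#'   (default 5.6 eV).
#' @param width_ev Gaussian full width at half maximum (default 0.25 eV).
#' @param wavelength_nm strictly increasing wavelength grid (default
#'   200..1400 nm, 1 nm step).
#' @param jacobian apply the energy-to-wavelength Jacobian.
#' @return A `kp_spectrum`: list with `axis` (nm), `intensity` and
#'   `metadata` recording the parameters applied.
#' @examples
#' sp <- uv_spectrum(data.frame(energy_ev = 2.95, strength = 0.36))
#' sp$axis[which.max(sp$intensity)]  # 420 nm (= 1239.842 / 2.95)
#' @export
uv_spectrum <- function(transitions, cutoff_ev = 5.6, width_ev = 0.25,
                        wavelength_nm = seq(200, 1400, by = 1),
                        jacobian = FALSE) {
  transitions <- as.data.frame(transitions)
  if (ncol(transitions) >= 2L &&
      !all(c("energy_ev", "strength") %in% names(transitions)))
    names(transitions)[1:2] <- c("energy_ev", "strength")
  if (length(wavelength_nm) == 0L || is.unsorted(wavelength_nm,
                                                 strictly = TRUE))
    stop("wavelength grid must be nonempty and strictly increasing")
  if (nrow(transitions) && any(transitions$strength < 0))
    stop("oscillator strengths must be nonnegative")
  keep <- transitions[transitions$energy_ev < cutoff_ev, , drop = FALSE]
  E <- 1239.842 / wavelength_nm
  y <- numeric(length(wavelength_nm))
  sigma <- .kp_fwhm_sigma(width_ev)
  for (r in seq_len(nrow(keep))) {
    y <- y + keep$strength[r] *
      exp(-(E - keep$energy_ev[r])^2 / (2 * sigma^2))
  }
  if (jacobian) y <- y * E / wavelength_nm
  .kp_new_spectrum(wavelength_nm, y,
                   list(kind = "uv", cutoff_ev = cutoff_ev,
                        width_ev = width_ev, jacobian = jacobian,
                        n_lines = nrow(keep)))
}

#' Synthesize an IR absorption curve from harmonic modes
#'
#' Each harmonic frequency is multiplied by the empirical scaling factor
#' (default 0.9547, correcting systematic overestimation of harmonic
#' frequencies) and broadened by a Gaussian of the stated full width at half
#' maximum.
#'
#' @param modes data frame (or 2-column matrix) with columns `frequency_cm`
#'   (cm^-1) and `intensity` (>= 0).
#' @param scale frequency scaling factor (default 0.9547).
#' @param width_cm Gaussian full width at half maximum (default 20 cm^-1).
#' @param wavenumber_cm strictly increasing wavenumber grid (default
#'   400..2000 cm^-1, 1 cm^-1 step).
#' @return A `kp_spectrum` on the wavenumber axis.
#' @examples
#' sp <- ir_spectrum(data.frame(frequency_cm = 1000, intensity = 1))
#' sp$axis[which.max(sp$intensity)]  # 955 (scaled peak at 954.7)
#' @export
ir_spectrum <- function(modes, scale = 0.9547, width_cm = 20,
                        wavenumber_cm = seq(400, 2000, by = 1)) {
  modes <- as.data.frame(modes)
  if (ncol(modes) >= 2L &&
      !all(c("frequency_cm", "intensity") %in% names(modes)))
    names(modes)[1:2] <- c("frequency_cm", "intensity")
  if (length(wavenumber_cm) == 0L || is.unsorted(wavenumber_cm,
                                                 strictly = TRUE))
    stop("wavenumber grid must be nonempty and strictly increasing")
  if (nrow(modes) && any(modes$intensity < 0))
    stop("mode intensities must be nonnegative")
  y <- numeric(length(wavenumber_cm))
  sigma <- .kp_fwhm_sigma(width_cm)
  for (r in seq_len(nrow(modes))) {
    y <- y + modes$intensity[r] *
      exp(-(wavenumber_cm - scale * modes$frequency_cm[r])^2 / (2 * sigma^2))
  }
  .kp_new_spectrum(wavenumber_cm, y,
                   list(kind = "ir", scale = scale, width_cm = width_cm,
                        n_lines = nrow(modes)))
}

#' @export
print.kp_spectrum <- function(x, ...) {
  md <- x$metadata
  cat("<kp_spectrum> ", toupper(md$kind), " curve, ", length(x$axis),
      " grid points, ", md$n_lines, " line(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.kp_spectrum <- function(x, ...) {
  xlab <- if (x$metadata$kind == "uv") "wavelength (nm)" else
    expression(wavenumber ~ (cm^-1))
  graphics::plot(x$axis, x$intensity, type = "l", xlab = xlab,
                 ylab = "intensity (arb. units)", ...)
  invisible(x)
}
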