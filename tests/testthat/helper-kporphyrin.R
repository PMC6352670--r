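# shared helpers for the test suite

# all 4096 per-unit state assignments as kp_name objects
all_state_assignments <- function() {
  states <- kporphyrin:::.kp_state_sets()
  out <- vector("list", 8L^4L)
  n <- 0L
  for (ia in 1:8) for (ib in 1:8) for (ic in 1:8) for (id in 1:8) {
    n <- n + 1L
    out[[n]] <- kporphyrin:::.kp_new_name(
      list(states[[ia]], states[[ib]], states[[ic]], states[[id]]))
  }
  out
}

# a minimal species record with only energy fields
energy_record <- function(name, level, vac_kcal, wat_kcal = vac_kcal,
                          thermal = 0.4) {
  hk <- kp_constants()$hartree_kcal
  list(name = name, level = level,
       electronic_energy_vacuum = -1900 + vac_kcal / hk,
       electronic_energy_solution = -1900.408 + wat_kcal / hk,
       nonelectrostatic_solvation = 0.008,
       thermal_free_energy_correction = thermal)
}

# the four cyclic rotations of a name
name_rotations <- function(name) {
  masks <- as.integer(kporphyrin:::.kp_masks(parse_name(name)))
  lapply(0:3, function(k) {
    m <- c(masks, masks)[(1:4) + k]
    format_name(kporphyrin:::.kp_name_from_masks(as.list(m)))
  })
}

# trapezoidal integral of a UV curve over the energy axis
uv_energy_integral <- function(transitions, width_ev = 0.25) {
  E <- seq(0.4, 5.5, by = 0.002)
  lambda <- rev(1239.842 / E)
  sp <- uv_spectrum(transitions, wavelength_nm = lambda,
                    width_ev = width_ev)
  y <- rev(sp$intensity)  # back onto the increasing-energy grid
  sum((y[-1] + y[-length(y)]) / 2 * diff(E))
}
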