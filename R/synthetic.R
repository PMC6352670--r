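# Synthetic species records: honest fakes with the qualitative structure of
# quantum-chemistry summaries, so the thermo and spectra stages are testable
# without any electronic-structure computation.

# evaluate expr with a private RNG stream, restoring the caller's state
.kp_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# energies: offsets are kcal/mol relative to the fully reduced species.
# The thermal correction is the same for every species, so it cancels in any
# balanced (mass- and redox-conserving) reaction; solution-phase fields are
# arranged so the smd_rrho composite carries the water offsets.
.kp_record_energies <- function(vac_off_kcal, wat_off_kcal) {
  hk <- kp_constants()$hartree_kcal
  base <- -1900
  list(
    electronic_energy_vacuum = base + vac_off_kcal / hk,
    electronic_energy_solution = base - 0.408 + wat_off_kcal / hk,
    nonelectrostatic_solvation = 0.008,
    thermal_free_energy_correction = 0.400
  )
}

#' Generate one synthetic species record
#'
#' Produces a fully populated quantum-chemistry summary record for a
#' tautomer: composite free-energy components (hartree), occupied/virtual
#' orbital energies, electronic transitions (eV, oscillator strength) and
#' harmonic modes (cm^-1, intensity). All records are marked
#' `provenance = "synthetic"`; they never claim to be computed values.
#' Unspecified fields are drawn reproducibly from documented default
#' distributions (energies near -1900 hartree; HOMO near -5.7 eV; the lowest
#' transition pinned at the HOMO-LUMO gap; transition energies uniform on
#' 1.2..5.5 eV plus one line above the 5.6 eV cutoff; mode frequencies
#' uniform on 420..1800 cm^-1). Overrides win verbatim; the special override
#' `homo_lumo_gap_ev` rebuilds the orbital block so [homo_lumo_gap()]
#' returns exactly that value.
#'
#' @param name tautomer name (string or `kp_name`).
#' @param level oxidation level; must equal `oxidation_level(name)`.
#' @param overrides named list of field overrides.
#' @param seed integer seed; the same seed always yields the same record.
#' @return A `kp_species_record` (a named list).
#' @examples
#' r <- make_species_record("a16_b6_c16_d6", 6,
#'                          overrides = list(homo_lumo_gap_ev = 2),
#'                          seed = 1)
#' homo_lumo_gap(r)  # 2
#' @export
make_species_record <- function(name, level, overrides = list(), seed = 1L) {
  name_str <- format_name(parse_name(name))
  if (oxidation_level(name_str) != level)
    stop("name '", name_str, "' has oxidation level ",
         oxidation_level(name_str), ", not ", level)
  .kp_with_seed(seed, {
    hev <- kp_constants()$hartree_ev
    gap_ev <- if (!is.null(overrides$homo_lumo_gap_ev))
      overrides$homo_lumo_gap_ev else stats::runif(1, 1.2, 3.6)
    homo_ev <- -5.7 + stats::rnorm(1, 0, 0.15)
    orbital_energies <- list(
      occupied = (homo_ev - c(3, 2.2, 1.6, 1.1, 0.7, 0.4, 0.15, 0)) / hev,
      virtual = (homo_ev + gap_ev + c(0, 0.2, 0.5, 0.9, 1.4, 2.0)) / hev
    )
    n_tr <- if (!is.null(overrides$n_transitions)) overrides$n_transitions
            else 8L
    # the HOMO-LUMO line is the absorption onset; all other lines sit above
    tr_e <- sort(c(gap_ev,
                   stats::runif(max(n_tr - 1L, 0L), min(gap_ev, 5.4), 5.5)))
    transitions <- data.frame(
      energy_ev = c(tr_e, stats::runif(1, 5.7, 6.5)),
      strength = stats::runif(length(tr_e) + 1L, 0, 0.6)
    )
    modes <- data.frame(
      frequency_cm = sort(stats::runif(24, 420, 1800)),
      intensity = stats::runif(24, 0, 1)
    )
    rec <- c(
      list(name = name_str, level = level, charge = 0L,
           provenance = "synthetic"),
      .kp_record_energies(stats::rnorm(1, 10, 3), stats::rnorm(1, 10, 3)),
      list(orbital_energies = orbital_energies, transitions = transitions,
           modes = modes)
    )
    for (f in setdiff(names(overrides), c("homo_lumo_gap_ev",
                                          "n_transitions")))
      rec[[f]] <- overrides[[f]]
    structure(rec, class = "kp_species_record")
  })
}

#' @export
print.kp_species_record <- function(x, ...) {
  cat("<kp_species_record> ", x$name, " (level ", x$level, ", charge ",
      x$charge, ", ", x$provenance, ")\n", sep = "")
  invisible(x)
}

# preset stability table: offsets in kcal/mol relative to KP-Red, chosen so
# that in vacuo every intermediate level disproportionates spontaneously
# toward KP-Red + KP-6e while KP-6e -> KP-Red + KP-8e is strongly uphill,
# and in water the KP-1e disproportionations turn slightly endoergonic and
# KP-2e -> KP-Red + KP-4e turns unfavorable while the overall conversion of
# KP-2e to KP-Red + KP-6e stays spontaneous.
.kp_paper_like_minima <- function() {
  data.frame(
    level = c(0, 1, 2, 4, 6, 8),
    name = c("a0_b0_c0_d0", "a6_b0_c0_d0", "a6_b6_c0_d0", "a16_b6_c6_d0",
             "a16_b6_c16_d6", "a16_b56_c16_d56"),
    vac_off = c(0, 2, 3, 5, 6, 60),
    wat_off = c(0, 2, 4.5, 10, 12.6, 66),
    gap_ev = c(3.6, 3.0, 1.7, 1.4, 1.6, 1.7),
    stringsAsFactors = FALSE
  )
}

.kp_paper_like_extras <- function() {
  data.frame(
    level = c(2, 4, 4, 4, 6, 8),
    name = c("a16_b0_c0_d0", "a6_b6_c16_d0", "a6_b16_c6_d0", "a6_b6_c6_d6",
             "a16_b16_c6_d6", "a16_b16_c16_d16"),
    off = c(4, 1, 2, 3.8, 8.5, 36),
    gap_ev = c(1.8, 1.5, 1.4, 1.1, 1.6, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic scenario
#'
#' The `"paper_like"` preset emits species records for the per-level minima
#' of KP-Red through KP-8e plus several higher-lying tautomers per level.
#' The minima carry exact free-energy offsets engineered to reproduce the
#' qualitative redox landscape of the tetramer: in vacuo (scheme
#' `"vacuum"`) every disproportionation of levels 1, 2 and 4 toward
#' KP-Red + KP-6e is exoergonic and KP-6e -> KP-Red + KP-8e is strongly
#' endoergonic; in water (scheme `"smd_rrho"`) the KP-1e disproportionations
#' are slightly endoergonic and KP-2e -> KP-Red + KP-4e is unfavorable,
#' while KP-2e -> KP-Red + KP-6e remains spontaneous. Non-minimum records
#' receive truncated Gaussian energy noise (sd 0.25 kcal/mol, clipped at
#' +-0.45) that cannot reorder them below their level minimum; a
#' generation-time guard re-verifies the full sign structure and stops on
#' any violation.
#'
#' @param preset scenario label; only `"paper_like"` is defined.
#' @param seed integer seed; output is fully determined by it.
#' @return A `kp_scenario`: list with `preset`, `seed`, `records` (flat list
#'   of `kp_species_record`, per-level minima first) and `minima` (the
#'   offset table used).
#' @examples
#' sc <- make_scenario("paper_like", seed = 1)
#' length(sc$records)
#' @export
make_scenario <- function(preset = "paper_like", seed = 1L) {
  if (!identical(preset, "paper_like"))
    stop("unknown preset '", preset, "'")
  minima <- .kp_paper_like_minima()
  extras <- .kp_paper_like_extras()
  records <- list()
  for (r in seq_len(nrow(minima))) {
    rec <- make_species_record(minima$name[r], minima$level[r],
                               overrides = c(
                                 list(homo_lumo_gap_ev = minima$gap_ev[r],
                                      role = "minimum"),
                                 .kp_record_energies(minima$vac_off[r],
                                                     minima$wat_off[r])),
                               seed = seed + 101L * r)
    records[[length(records) + 1L]] <- rec
  }
  noise <- .kp_with_seed(seed,
    pmin(pmax(stats::rnorm(nrow(extras), 0, 0.25), -0.45), 0.45))
  for (r in seq_len(nrow(extras))) {
    lv <- extras$level[r]
    base_vac <- minima$vac_off[minima$level == lv]
    base_wat <- minima$wat_off[minima$level == lv]
    rec <- make_species_record(extras$name[r], lv,
                               overrides = c(
                                 list(homo_lumo_gap_ev = extras$gap_ev[r],
                                      role = "alternative"),
                                 .kp_record_energies(
                                   base_vac + extras$off[r] + noise[r],
                                   base_wat + extras$off[r] + noise[r])),
                               seed = seed + 977L * r)
    records[[length(records) + 1L]] <- rec
  }
  sc <- structure(list(preset = preset, seed = seed, records = records,
                       minima = minima),
                  class = "kp_scenario")
  .kp_check_scenario(sc)
  sc
}

# generation-time guard: the qualitative disproportionation sign structure
# must hold exactly; any violation is a construction bug, not a data issue.
.kp_check_scenario <- function(sc) {
  mins <- Filter(function(r) identical(r$role, "minimum"), sc$records)
  dG <- function(n, p, q, scheme)
    disproportionation_dG(mins, balance_disproportionation(n, p, q),
                          scheme)["per_mole"]
  ok <- c(
    dG(1, 0, 2, "vacuum") < 0, dG(1, 0, 6, "vacuum") < 0,
    dG(2, 0, 4, "vacuum") < 0, dG(2, 0, 6, "vacuum") < 0,
    dG(4, 0, 6, "vacuum") < 0, dG(6, 0, 8, "vacuum") > 20,
    dG(1, 0, 2, "smd_rrho") > 0, dG(1, 0, 6, "smd_rrho") > 0,
    dG(2, 0, 4, "smd_rrho") > 0, dG(2, 0, 6, "smd_rrho") < 0,
    dG(4, 0, 6, "smd_rrho") < 0, dG(6, 0, 8, "smd_rrho") > 20
  )
  if (!all(ok))
    stop("scenario guard: disproportionation sign structure violated")
  for (r in sc$records) {
    if (identical(r$role, "minimum")) next
    m <- Filter(function(x) identical(x$role, "minimum") &&
                  x$level == r$level, sc$records)[[1]]
    if (composite_free_energy(r, "vacuum") <=
          composite_free_energy(m, "vacuum") ||
        composite_free_energy(r, "smd_rrho") <=
          composite_free_energy(m, "smd_rrho"))
      stop("scenario guard: record '", r$name,
           "' fell below its level minimum")
  }
  invisible(sc)
}

#' @export
print.kp_scenario <- function(x, ...) {
  cat("<kp_scenario> preset '", x$preset, "', seed ", x$seed, ", ",
      length(x$records), " synthetic species records\n", sep = "")
  invisible(x)
}

#' Extract records from a scenario
#'
#' @param scenario a `kp_scenario`.
#' @param level optional oxidation level filter.
#' @param minima_only keep only the per-level minimum records.
#' @return List of `kp_species_record`.
#' @export
scenario_records <- function(scenario, level = NULL, minima_only = FALSE) {
  recs <- scenario$records
  if (minima_only)
    recs <- Filter(function(r) identical(r$role, "minimum"), recs)
  if (!is.null(level))
    recs <- Filter(function(r) r$level == level, recs)
  recs
}
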