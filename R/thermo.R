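# Free-energy post-processing: relative stabilities, Boltzmann weights, pKa
# by reference comparison, disproportionation thermodynamics, HOMO-LUMO gaps.

#' Physical constants used by the thermochemistry routines
#'
#' @return Named list: `hartree_kcal` (627.5095 kcal/mol per hartree),
#'   `hartree_ev` (27.2114 eV per hartree), `R_kcal` (gas constant,
#'   kcal/(mol K)) and `default_temperature` (298.15 K). At the default
#'   temperature RT ln(10) = 1.3644 kcal/mol, the free-energy cost of one
#'   pKa unit.
#' @export
kp_constants <- function() {
  list(hartree_kcal = 627.5095,
       hartree_ev = 27.2114,
       R_kcal = 1.98720425864083e-3,
       default_temperature = 298.15)
}

#' Composite free energy of a species record
#'
#' Combines the stored energy components according to the selected scheme:
#' `"vacuum"` is the in-vacuo electronic energy alone; `"vacuum_rrho"` adds
#' the rigid-rotor/harmonic-oscillator thermal free-energy correction;
#' `"smd_rrho"` sums the solution-phase electronic energy, the
#' nonelectrostatic solvation term and the thermal correction (the
#' Delta-G(SMD,RRHO) composite).
#'
#' @param record a species record (see [make_species_record()]).
#' @param scheme one of `"vacuum"`, `"vacuum_rrho"`, `"smd_rrho"`.
#' @return Energy in hartree.
#' @export
composite_free_energy <- function(record,
                                  scheme = c("vacuum", "vacuum_rrho",
                                             "smd_rrho")) {
  scheme <- match.arg(scheme)
  need <- switch(scheme,
    vacuum = "electronic_energy_vacuum",
    vacuum_rrho = c("electronic_energy_vacuum",
                    "thermal_free_energy_correction"),
    smd_rrho = c("electronic_energy_solution", "nonelectrostatic_solvation",
                 "thermal_free_energy_correction"))
  for (f in need) {
    if (is.null(record[[f]]) || !is.finite(record[[f]]))
      stop("scheme '", scheme, "' requires field '", f,
           "', absent from record '", record$name, "'")
  }
  sum(vapply(need, function(f) record[[f]], numeric(1)))
}

#' Relative energies and Boltzmann weights within one oxidation level
#'
#' @param records list of species records at a common oxidation level.
#' @param temperature kelvin.
#' @param scheme energy scheme passed to [composite_free_energy()].
#' @return Data frame with columns `name`, `rel_kcal` (free energy above the
#'   minimum, kcal/mol) and `weight` (Boltzmann population, summing to 1),
#'   sorted ascending by `rel_kcal` with ties broken by canonical name order.
#' @examples
#' recs <- list(
#'   list(name = "a6_b6_c0_d0", level = 2, electronic_energy_vacuum = 0),
#'   list(name = "a16_b0_c0_d0", level = 2,
#'        electronic_energy_vacuum = 2 / 627.5095))
#' relative_energies_and_weights(recs)
#' @export
relative_energies_and_weights <- function(records,
                                          temperature = 298.15,
                                          scheme = "vacuum") {
  if (length(records) == 0L) stop("empty record set")
  lv <- unique(vapply(records, function(r) as.numeric(r$level), numeric(1)))
  if (length(lv) > 1L)
    stop("records span several oxidation levels: ", paste(lv, collapse = ", "))
  cst <- kp_constants()
  G <- vapply(records, composite_free_energy, numeric(1), scheme = scheme)
  rel <- (G - min(G)) * cst$hartree_kcal
  w <- exp(-rel / (cst$R_kcal * temperature))
  w <- w / sum(w)
  nm <- vapply(records, function(r) as.character(r$name), character(1))
  out <- data.frame(name = nm, rel_kcal = rel, weight = w,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rel_kcal, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate a pKa by comparison with reference acid/base pairs
#'
#' In the linear free-energy form, the pKa of the target acid follows from
#' each reference AH/A- pair as
#' `pKa_i = pKa_ref_i + (dG_target - dG_ref_i) / (RT ln 10)`,
#' with deprotonation free energies in kcal/mol. The proton's solvation free
#' energy cancels in the comparison and never enters as an absolute value.
#'
#' @param dG_target deprotonation free energy of the target (kcal/mol).
#' @param references data frame with columns `dG` (kcal/mol) and `pKa`.
#' @param temperature kelvin.
#' @return List with `estimate` (arithmetic mean over references), `spread`
#'   (max minus min of the per-reference values) and `per_reference`
#'   (numeric vector).
#' @examples
#' refs <- data.frame(dG = c(300, 301.3644), pKa = c(7, 8))
#' estimate_pka(300, refs)$estimate  # 7
#' @export
estimate_pka <- function(dG_target, references, temperature = 298.15) {
  if (is.null(references) || nrow(references) == 0L)
    stop("at least one reference acid/base pair is required")
  cst <- kp_constants()
  rtln10 <- cst$R_kcal * temperature * log(10)
  per <- references$pKa + (dG_target - references$dG) / rtln10
  list(estimate = mean(per), spread = max(per) - min(per),
       per_reference = per)
}

#' Balance a disproportionation reaction
#'
#' Finds the smallest positive integer coefficients (m, x, y) for
#' `m KP-n -> x KP-p + y KP-q` with mass balance `m = x + y` and redox
#' balance `m n = x p + y q`.
#'
#' @param n reactant oxidation level, with `p < n < q`.
#' @param p,q product oxidation levels.
#' @return A `kp_reaction`: list with `reactant_level`, `product_levels`
#'   and `coefficients` (named m, x, y).
#' @examples
#' balance_disproportionation(2, 0, 6)$coefficients  # m=3, x=2, y=1
#' @export
balance_disproportionation <- function(n, p, q) {
  if (!(p < n && n < q))
    stop("stoichiometry error: need p < n < q, got (", n, ", ", p, ", ", q, ")")
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(q - n, n - p)
  x <- (q - n) / d
  y <- (n - p) / d
  structure(list(reactant_level = n, product_levels = c(p, q),
                 coefficients = c(m = x + y, x = x, y = y)),
            class = "kp_reaction")
}

#' @export
print.kp_reaction <- function(x, ...) {
  co <- x$coefficients
  cat("<kp_reaction> ", co["m"], " KP-", x$reactant_level, "e -> ",
      co["x"], " KP-", x$product_levels[1], "e + ",
      co["y"], " KP-", x$product_levels[2], "e\n", sep = "")
  invisible(x)
}

#' Disproportionation reaction free energy
#'
#' Computes `dG = x G(p) + y G(q) - m G(n)` in kcal/mol for a balanced
#' disproportionation, together with the value per mole of reactant
#' (`dG / m`, the fractional-coefficient normalization). The reverse
#' comproportionation free energy is the negative.
#'
#' @param records_by_level list of species records; each level is
#'   represented by the record whose `level` field matches (the chosen
#'   representative, typically the Boltzmann minimum of its level).
#' @param reaction a `kp_reaction` from [balance_disproportionation()].
#' @param scheme energy scheme (see [composite_free_energy()]).
#' @return Named numeric vector `c(total = ..., per_mole = ...)` in kcal/mol.
#' @export
disproportionation_dG <- function(records_by_level, reaction,
                                  scheme = "vacuum") {
  stopifnot(inherits(reaction, "kp_reaction"))
  cst <- kp_constants()
  levels_all <- vapply(records_by_level, function(r) as.numeric(r$level),
                       numeric(1))
  pick <- function(lv) {
    hit <- which(levels_all == lv)
    if (length(hit) == 0L)
      stop("no species record at oxidation level ", lv)
    records_by_level[[hit[1L]]]
  }
  n <- reaction$reactant_level
  p <- reaction$product_levels[1]; q <- reaction$product_levels[2]
  co <- reaction$coefficients
  dG <- (co["x"] * composite_free_energy(pick(p), scheme) +
         co["y"] * composite_free_energy(pick(q), scheme) -
         co["m"] * composite_free_energy(pick(n), scheme)) * cst$hartree_kcal
  c(total = unname(dG), per_mole = unname(dG / co["m"]))
}

#' HOMO-LUMO gap of a species record
#'
#' @param record a species record with an `orbital_energies` block (lists
#'   `occupied` and `virtual`, hartree).
#' @return Gap in eV: lowest virtual minus highest occupied orbital energy.
#' @examples
#' r <- list(name = "x", orbital_energies = list(
#'   occupied = -5 / 27.2114, virtual = -3 / 27.2114))
#' homo_lumo_gap(r)  # 2
#' @export
homo_lumo_gap <- function(record) {
  orb <- record$orbital_energies
  if (is.null(orb) || length(orb$occupied) == 0L || length(orb$virtual) == 0L)
    stop("record '", record$name,
         "' lacks occupied and/or virtual orbital energies")
  (min(orb$virtual) - max(orb$occupied)) * kp_constants()$hartree_ev
}
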