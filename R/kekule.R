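# Closed-shell valence structures as perfect matchings, macrocyclic
# conjugation circuits and the Hueckel rule.

# Double-bond demand per atom: valence - sigma-degree - attached hydrogens.
# Every carbon of the tetramer has three heavy/sigma partners counted with its
# single ring hydrogen (C3, C4) or its third heavy neighbour, so carbons
# always demand exactly one double bond; N1 and the oxygens demand one iff
# their mobile hydrogen has been removed.
.kp_demands <- function(name) {
  name <- parse_name(name)
  skel <- build_skeleton()
  demand <- ifelse(skel$atoms$element == "C", 1L, 0L)
  for (k in seq_len(4L)) {
    for (site in name$removed[[k]]) {
      id <- skel$atoms$id[skel$atoms$unit == .kp_units[k] &
                          skel$atoms$label == site]
      demand[id] <- 1L
    }
  }
  demand
}

# Backtracking search over perfect matchings of the demand-1 atom set, using
# only bonds with both endpoints in the set. `first_only` turns the search
# into an existence test with early exit. Pivot on the alive atom with the
# fewest alive neighbours; a stranded atom prunes the branch immediately.
.kp_match_search <- function(required, first_only = FALSE) {
  adj <- .kp_adjacency()
  nbrs <- adj$nbrs
  bond_of <- adj$bond_of
  results <- list()
  nres <- 0L
  recurse <- function(alive, chosen) {
    ids <- which(alive)
    if (length(ids) == 0L) {
      nres <<- nres + 1L
      results[[nres]] <<- sort(chosen)
      return(first_only)
    }
    best <- 0L; best_nb <- NULL; best_k <- Inf
    for (a in ids) {
      nb <- nbrs[[a]]
      nb <- nb[alive[nb]]
      k <- length(nb)
      if (k == 0L) return(FALSE)
      if (k < best_k) {
        best_k <- k; best <- a; best_nb <- nb
        if (k == 1L) break
      }
    }
    for (b in best_nb) {
      alive2 <- alive
      alive2[c(best, b)] <- FALSE
      if (recurse(alive2, c(chosen, bond_of[best, b]))) return(TRUE)
    }
    FALSE
  }
  alive <- logical(nrow(build_skeleton()$atoms))
  alive[required] <- TRUE
  if (sum(alive) %% 2L == 1L) return(list())
  recurse(alive, integer(0))
  results
}

#' Enumerate the Kekulé structures of a tautomer
#'
#' A Kekulé structure is an assignment of localized double bonds in which
#' every atom demanding exactly one double bond (all carbons; N1 and O atoms
#' whose mobile hydrogen is removed) is covered exactly once, and protonated
#' heteroatoms are covered by none -- formally a perfect matching on the
#' demand-1 atom set. A tautomer is closed-shell iff at least one such
#' structure exists.
#'
#' @param name a tautomer name (string or `kp_name`).
#' @return A list of `kp_kekule` objects (empty when the species is
#'   open-shell), sorted so the lexicographically smallest double-bond set
#'   comes first. Each has fields `name`, `bond_ids` (row indices into
#'   `build_skeleton()$bonds`) and `double_bonds` (the corresponding bond
#'   data frame rows).
#' @examples
#' length(kekule_structures("a0_b0_c0_d0"))      # 16
#' length(kekule_structures("a16_b56_c16_d56"))  # 1
#' length(kekule_structures("a1_b0_c0_d0"))      # 0 (open-shell)
#' @export
kekule_structures <- function(name) {
  name <- parse_name(name)
  required <- which(.kp_demands(name) == 1L)
  matchings <- .kp_match_search(required, first_only = FALSE)
  if (length(matchings) > 1L) {
    ord <- order(vapply(matchings, function(m)
      paste(sprintf("%02d", m), collapse = ""), character(1)))
    matchings <- matchings[ord]
  }
  skel <- build_skeleton()
  lapply(matchings, function(m) {
    structure(list(name = name, bond_ids = m,
                   double_bonds = skel$bonds[m, c("i", "j", "type")]),
              class = "kp_kekule")
  })
}

#' @export
print.kp_kekule <- function(x, ...) {
  cat("<kp_kekule> ", format_name(x$name), ": ", length(x$bond_ids),
      " double bonds\n", sep = "")
  invisible(x)
}

# The simple C7 -> C2 paths within one unit (the oxygens are pendant and can
# never be path-interior). Computed once from the skeleton by DFS; there are
# exactly four, of lengths 4, 5, 7 and 8 atoms.
.kp_unit_paths <- function() {
  if (!is.null(.kp_cache$unit_paths)) return(.kp_cache$unit_paths)
  nbr <- list()
  for (b in seq_len(nrow(.kp_intra_bonds))) {
    x <- .kp_intra_bonds[b, 1L]; y <- .kp_intra_bonds[b, 2L]
    nbr[[x]] <- c(nbr[[x]], y)
    nbr[[y]] <- c(nbr[[y]], x)
  }
  paths <- list()
  dfs <- function(path) {
    last <- path[length(path)]
    if (last == "C2") {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nx in nbr[[last]]) {
      if (!(nx %in% path)) dfs(c(path, nx))
    }
  }
  dfs("C7")
  paths <- paths[order(lengths(paths))]
  .kp_cache$unit_paths <- paths
  paths
}

# All candidate macrocyclic circuits: a cyclic edge-id sequence built from
# one C7->C2 path per unit plus the four inter-ring bonds, in traversal order.
.kp_circuit_candidates <- function() {
  if (!is.null(.kp_cache$circuits)) return(.kp_cache$circuits)
  skel <- build_skeleton()
  adj <- .kp_adjacency()
  idx <- function(unit, label)
    skel$atoms$id[skel$atoms$unit == unit & skel$atoms$label == label]
  paths <- .kp_unit_paths()
  inter_bond <- vapply(seq_len(4L), function(k) {
    u <- .kp_units[k]; v <- .kp_units[k %% 4L + 1L]
    adj$bond_of[idx(u, "C2"), idx(v, "C7")]
  }, integer(1))
  combos <- expand.grid(a = seq_along(paths), b = seq_along(paths),
                        c = seq_along(paths), d = seq_along(paths))
  out <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    edge_seq <- integer(0)
    atom_seq <- integer(0)
    for (k in seq_len(4L)) {
      u <- .kp_units[k]
      p <- paths[[combos[r, k]]]
      ids <- vapply(p, idx, integer(1), unit = u)
      atom_seq <- c(atom_seq, ids)
      if (length(ids) > 1L)
        edge_seq <- c(edge_seq, adj$bond_of[cbind(ids[-length(ids)], ids[-1L])])
      edge_seq <- c(edge_seq, inter_bond[k])
    }
    out[[r]] <- list(atoms = atom_seq, edges = edge_seq)
  }
  .kp_cache$circuits <- out
  out
}

#' Macrocyclic conjugation circuits of a tautomer
#'
#' Searches, over every Kekulé structure and every cycle passing through all
#' four inter-ring bonds (one simple C7->C2 path per unit), for circuits
#' whose edges alternate strictly between double and single bonds. The
#' pi-electron count of such a circuit equals its atom count (one p
#' electron per sp2 atom on the circuit), which equals twice the number of
#' on-circuit double bonds.
#'
#' @param name a closed-shell tautomer name.
#' @return A list of circuits, each a list with `atoms` (atom ids in cyclic
#'   order), `pi_electrons`, `n_double` (on-circuit double bonds) and
#'   `kekule` (index of the witnessing Kekulé structure in
#'   [kekule_structures()] order). Duplicate (atom set, Kekulé) pairs are
#'   collapsed. Empty list when no macrocyclic conjugated circuit exists.
#' @seealso [macrocyclic_pi_counts()] for just the distinct pi counts.
#' @export
macrocyclic_circuits <- function(name) {
  name <- parse_name(name)
  ks <- kekule_structures(name)
  if (length(ks) == 0L)
    stop("open-shell tautomer '", format_name(name),
         "': no Kekulé structure exists")
  cands <- .kp_circuit_candidates()
  nb <- nrow(build_skeleton()$bonds)
  out <- list()
  for (ki in seq_along(ks)) {
    dbl <- logical(nb)
    dbl[ks[[ki]]$bond_ids] <- TRUE
    for (cand in cands) {
      d <- dbl[cand$edges]
      if (all(d != c(d[-1L], d[1L]))) {
        out[[length(out) + 1L]] <- list(
          atoms = cand$atoms,
          pi_electrons = length(cand$atoms),
          n_double = sum(d),
          kekule = ki
        )
      }
    }
  }
  out
}

#' Macrocyclic pi-electron counts
#'
#' The set of pi-electron counts of the alternating conjugation circuits that
#' run through all four inter-ring bonds (see [macrocyclic_circuits()]).
#' Circuits of this kind only exist when every unit is in one of the states
#' \{N1\}, \{O6\} or \{N1,O6\}; the count is then the sum of the per-unit
#' path contributions (7, 5 and 4 atoms respectively) and is unique.
#'
#' @param name a closed-shell tautomer name.
#' @return Sorted integer vector of distinct pi-electron counts; `integer(0)`
#'   when no macrocyclic conjugated circuit exists.
#' @examples
#' macrocyclic_pi_counts("a16_b6_c16_d6")   # 18
#' macrocyclic_pi_counts("a1_b1_c1_d1")     # 28
#' macrocyclic_pi_counts("a16_b56_c16_d56") # integer(0)
#' @export
macrocyclic_pi_counts <- function(name) {
  circuits <- macrocyclic_circuits(name)
  sort(unique(vapply(circuits, `[[`, integer(1), "pi_electrons")))
}

#' Hueckel 4n+2 classification
#'
#' A cyclic conjugated system with 4n+2 pi electrons is aromatic; with 4n it
#' is antiaromatic.
#'
#' @param pi_electrons positive even integer count(s).
#' @return Character vector, `"aromatic"` or `"antiaromatic"`.
#' @examples
#' huckel_class(18)  # "aromatic"
#' huckel_class(16)  # "antiaromatic"
#' @export
huckel_class <- function(pi_electrons) {
  if (any(pi_electrons <= 0) || any(pi_electrons %% 2 != 0))
    stop("pi-electron count must be a positive even integer")
  ifelse(pi_electrons %% 4 == 2, "aromatic", "antiaromatic")
}
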