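# Exhaustive tautomer generation at each oxidation level, building-block
# derivation and structural motif classification.

# the eight per-unit removed-H states, ordered by bitmask (N1=1, O5=2, O6=4)
.kp_state_sets <- function() {
  if (!is.null(.kp_cache$states)) return(.kp_cache$states)
  states <- list(character(0), "N1", "O5", c("N1", "O5"), "O6",
                 c("N1", "O6"), c("O5", "O6"), c("N1", "O5", "O6"))
  .kp_cache$states <- states
  states
}

.kp_state_string <- function(state) {
  if (length(state) == 0L) "0" else
    paste(sort(unname(.kp_site_digit[state])), collapse = "")
}

#' Is a tautomer closed-shell?
#'
#' A tautomer is closed-shell iff the 44-atom graph admits at least one
#' Kekulé structure, i.e. a perfect matching on the atoms demanding one
#' double bond. An odd number of removed hydrogens makes this impossible by
#' parity (radical species).
#'
#' @param name a tautomer name (string or `kp_name`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_closed_shell("a6_b6_c0_d0")  # TRUE
#' is_closed_shell("a6_b0_c6_d0")  # FALSE: no pairing across opposite rings
#' @export
is_closed_shell <- function(name) {
  name <- parse_name(name)
  required <- which(.kp_demands(name) == 1L)
  if (length(required) %% 2L == 1L) return(FALSE)
  length(.kp_match_search(required, first_only = TRUE)) > 0L
}

#' Enumerate closed-shell tautomers at an oxidation level
#'
#' Iterates over all 8^4 = 4096 assignments of per-unit removed-H states,
#' keeps those with the requested total oxidation level, per-unit cap and
#' whole-graph Kekulé feasibility, and deduplicates under the four cyclic
#' rotations of the unit labels. Odd levels are rejected: removing an odd
#' number of hydrogens leaves an unpaired electron.
#'
#' The default per-unit cap of 2 mirrors the generation procedure for the
#' paper censuses; the single three-electron unit state \{N1,O5,O6\} is a
#' high-energy site admitted only via `include_three_electron_blocks`, and
#' even then no valid tautomer exists at levels 10 or 12.
#'
#' @param level even integer in 0..12.
#' @param max_unit_oxidation maximum removed hydrogens per unit (default 2).
#' @param include_three_electron_blocks also admit the three-electron unit
#'   state \{N1,O5,O6\}.
#' @param motifs compute per-name motif tags (see [classify_motifs()]).
#' @return A `kp_census` object: list with `level`, `names` (sorted
#'   character vector of canonical names), `motifs` (named list of tag
#'   vectors, when requested) and `counts_by_motif` (table).
#' @examples
#' enumerate_closed_shell(2)$names   # 7 tautomers
#' length(enumerate_closed_shell(4)$names)  # 49
#' @export
enumerate_closed_shell <- function(level, max_unit_oxidation = 2L,
                                   include_three_electron_blocks = FALSE,
                                   motifs = TRUE) {
  if (length(level) != 1L || level < 0L || level > 12L)
    stop("oxidation level must be in 0..12")
  if (level %% 2L == 1L)
    stop("parity error: odd oxidation level ", level,
         " admits no closed-shell species")
  key <- paste("cs", level, max_unit_oxidation,
               include_three_electron_blocks, sep = "_")
  if (is.null(.kp_cache[[key]])) {
    states <- .kp_state_sets()
    sizes <- lengths(states)
    ok_size <- sizes <= max_unit_oxidation |
      (include_three_electron_blocks & sizes == 3L)
    candidates <- character(0)
    for (ia in which(ok_size)) for (ib in which(ok_size)) {
      if (sizes[ia] + sizes[ib] > level) next
      for (ic in which(ok_size)) {
        if (sizes[ia] + sizes[ib] + sizes[ic] > level) next
        for (id in which(ok_size)) {
          if (sizes[ia] + sizes[ib] + sizes[ic] + sizes[id] != level) next
          nm <- .kp_new_name(list(states[[ia]], states[[ib]],
                                  states[[ic]], states[[id]]))
          candidates <- c(candidates, format_name(canonical_form(nm)))
        }
      }
    }
    candidates <- unique(candidates)
    .kp_cache[[key]] <- sort(candidates[vapply(candidates, is_closed_shell,
                                               logical(1))])
  }
  nms <- .kp_cache[[key]]
  tags <- NULL
  counts <- NULL
  if (motifs) {
    tags <- lapply(nms, classify_motifs)
    names(tags) <- nms
    counts <- table(unlist(tags))
  }
  structure(list(level = level, names = nms, motifs = tags,
                 counts_by_motif = counts),
            class = "kp_census")
}

#' @export
print.kp_census <- function(x, ...) {
  cat("<kp_census> level ", x$level, ": ", length(x$names),
      " closed-shell tautomer(s)\n", sep = "")
  if (!is.null(x$counts_by_motif) && length(x$counts_by_motif)) {
    cat("motifs:\n")
    print(x$counts_by_motif)
  }
  invisible(x)
}

#' @export
as.data.frame.kp_census <- function(x, ...) {
  data.frame(
    name = x$names,
    level = rep(x$level, length(x$names)),
    closed_shell = rep(TRUE, length(x$names)),
    motifs = if (is.null(x$motifs)) NA_character_ else
      vapply(x$motifs, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Enumerate all tautomer orbits at an oxidation level
#'
#' Counts every distinct placement of removed hydrogens at the level, with no
#' closed-shell (valence feasibility) constraint -- the state space that also
#' contains the open-shell radicals. Useful for radical/anion site
#' exploration and for Burnside-style orbit accounting.
#'
#' @param level integer in 0..12 (odd levels allowed).
#' @return Sorted character vector of canonical names.
#' @examples
#' enumerate_open_shell(1)  # 3 orbits: H removed at N1, O5 or O6
#' @export
enumerate_open_shell <- function(level) {
  if (length(level) != 1L || level < 0L || level > 12L)
    stop("oxidation level must be in 0..12")
  states <- .kp_state_sets()
  sizes <- lengths(states)
  canon <- character(0)
  for (ia in seq_along(states)) for (ib in seq_along(states))
    for (ic in seq_along(states)) for (id in seq_along(states)) {
      if (sizes[ia] + sizes[ib] + sizes[ic] + sizes[id] != level) next
      nm <- .kp_new_name(list(states[[ia]], states[[ib]],
                              states[[ic]], states[[id]]))
      cf <- format_name(canonical_form(nm))
      if (!(cf %in% canon)) canon <- c(canon, cf)
    }
  sort(canon)
}

# single-unit admissibility: does unit "a" with the given removed-H state
# admit a perfect matching when its 2-/7-position dangling bonds have the
# stated orders? A dangling double satisfies C2/C7 externally, removing it
# from the internal demand set.
.kp_block_admissible <- function(state, dangling_2, dangling_7) {
  skel <- build_skeleton()
  a <- skel$atoms
  req <- a$id[a$unit == "a" &
              (a$element == "C" | a$label %in% state)]
  if (dangling_2 == "double")
    req <- setdiff(req, a$id[a$unit == "a" & a$label == "C2"])
  if (dangling_7 == "double")
    req <- setdiff(req, a$id[a$unit == "a" & a$label == "C7"])
  if (length(req) %% 2L == 1L) return(FALSE)
  # only unit-a atoms are alive, so inter-ring bonds are excluded implicitly
  length(.kp_match_search(req, first_only = TRUE)) > 0L
}

#' Derive the DHI building-block library
#'
#' A building block is a single DHI unit in a given removed-H state together
#' with the bond orders of its dangling 2- and 7-position bonds. A block is
#' admissible iff the single-unit subgraph admits a perfect matching on its
#' demand-1 atoms once dangling doubles are credited externally; the library
#' is derived from this feasibility test, not hard-coded. The standard
#' library has 9 blocks: the fully reduced unit (single, single); four
#' one-electron blocks (\{N1\} or \{O6\}, dangling double at 2 or at 7);
#' three two-electron (single, single) blocks -- the o-quinone \{O5,O6\},
#' quinone methide \{N1,O6\} and quinone imine \{N1,O5\} forms -- and one
#' two-electron (double, double) block, \{N1,O6\}. With
#' `include_three_electron_blocks` there is exactly one more, \{N1,O5,O6\}
#' with its dangling double at the 7-position.
#'
#' @param include_three_electron_blocks admit per-unit states of size 3.
#' @return Data frame with columns `state` (digit string), `n_removed`,
#'   `dangling_2`, `dangling_7` (`"single"`/`"double"`).
#' @examples
#' nrow(derive_block_library())  # 9
#' @export
derive_block_library <- function(include_three_electron_blocks = FALSE) {
  key <- paste0("blocks_", include_three_electron_blocks)
  if (!is.null(.kp_cache[[key]])) return(.kp_cache[[key]])
  states <- .kp_state_sets()
  rows <- list()
  for (s in states) {
    if (!include_three_electron_blocks && length(s) == 3L) next
    for (d2 in c("single", "double")) for (d7 in c("single", "double")) {
      if (.kp_block_admissible(s, d2, d7)) {
        rows[[length(rows) + 1L]] <- data.frame(
          state = .kp_state_string(s), n_removed = length(s),
          dangling_2 = d2, dangling_7 = d7, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_removed, out$state, out$dangling_2, out$dangling_7),
             , drop = FALSE]
  rownames(out) <- NULL
  .kp_cache[[key]] <- out
  out
}

#' Closed-shell feasibility by building-block composition
#'
#' Independent route to [is_closed_shell()]: assign each of the four
#' inter-ring bonds an order (single or double) and require every unit's
#' (state, dangling-2, dangling-7) triple to be an admissible building block
#' from [derive_block_library()]. Unit k's 2-position bond links to unit
#' k+1's 7-position around the directed cycle.
#'
#' @param name a tautomer name.
#' @param include_three_electron_blocks use the extended block library.
#' @return `TRUE` iff some consistent assignment of inter-ring bond orders
#'   exists.
#' @export
composable_from_blocks <- function(name,
                                   include_three_electron_blocks = FALSE) {
  name <- parse_name(name)
  lib <- derive_block_library(include_three_electron_blocks)
  key <- paste(lib$state, lib$dangling_2, lib$dangling_7)
  st <- vapply(name$removed, .kp_state_string, character(1))
  orders <- c("single", "double")
  for (o1 in orders) for (o2 in orders) for (o3 in orders) for (o4 in orders) {
    o <- c(o1, o2, o3, o4)  # o[k]: order of the bond C2(unit k)-C7(unit k+1)
    ok <- TRUE
    for (k in seq_len(4L)) {
      d2 <- o[k]
      d7 <- o[(k - 2L) %% 4L + 1L]
      if (!(paste(st[k], d2, d7) %in% key)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Classify the conjugation motif of a closed-shell tautomer
#'
#' Infers structural motif tags from which inter-ring bonds can carry a
#' double bond in some Kekulé structure:
#' \describe{
#'   \item{macrocyclic-conjugated}{an alternating conjugation circuit runs
#'     through all four inter-ring bonds.}
#'   \item{three-ring-chain}{some Kekulé structure has double bonds on two
#'     adjacent inter-ring bonds: a conjugated system formally delocalized
#'     over three units.}
#'   \item{interring-pair}{some Kekulé structure has an inter-ring double
#'     bond (e.g. a quinone methide extended over two adjacent units).}
#'   \item{alternating-localized-quinonoid}{all inter-ring bonds are single
#'     in every Kekulé structure and the unit states alternate between two
#'     distinct localized oxidized forms (pattern x,y,x,y).}
#'   \item{single-ring-localized}{all inter-ring bonds single; oxidation
#'     confined to individual units.}
#' }
#'
#' @param name a closed-shell tautomer name.
#' @return Character vector of motif tags (possibly several).
#' @examples
#' classify_motifs("a6_b6_c0_d0")       # interring-pair
#' classify_motifs("a16_b56_c16_d56")   # alternating-localized-quinonoid
#' @export
classify_motifs <- function(name) {
  name <- parse_name(name)
  ks <- kekule_structures(name)
  if (length(ks) == 0L)
    stop("open-shell tautomer '", format_name(name),
         "' has no conjugation motif")
  skel <- build_skeleton()
  inter_ids <- which(skel$bonds$type == "inter")
  # adjacency of inter-ring bonds around the 4-cycle, in unit order a..d
  adj_ids <- .kp_adjacency()
  idx <- function(unit, label)
    skel$atoms$id[skel$atoms$unit == unit & skel$atoms$label == label]
  ring_order <- vapply(seq_len(4L), function(k)
    adj_ids$bond_of[idx(.kp_units[k], "C2"),
                    idx(.kp_units[k %% 4L + 1L], "C7")], integer(1))
  tags <- character(0)
  if (length(macrocyclic_pi_counts(name)) > 0L)
    tags <- c(tags, "macrocyclic-conjugated")
  any_double <- FALSE
  any_adjacent <- FALSE
  any_single_inter <- FALSE
  for (k in ks) {
    dbl <- ring_order %in% k$bond_ids
    nd <- sum(dbl)
    if (nd > 0L) any_double <- TRUE
    if (nd == 1L) any_single_inter <- TRUE
    if (any(dbl & c(dbl[-1L], dbl[1L]))) any_adjacent <- TRUE
  }
  if (any_adjacent && !("macrocyclic-conjugated" %in% tags))
    tags <- c(tags, "three-ring-chain")
  if (any_single_inter) tags <- c(tags, "interring-pair")
  if (!any_double) {
    st <- vapply(name$removed, .kp_state_string, character(1))
    alternating <- st[1] == st[3] && st[2] == st[4] && st[1] != st[2] &&
      all(st != "0")
    tags <- c(tags, if (alternating) "alternating-localized-quinonoid"
                    else "single-ring-localized")
  }
  unique(tags)
}
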