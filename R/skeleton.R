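# Molecular graph of the 2,7'-cyclotetramer and the mobile-hydrogen naming scheme.

.kp_units <- c("a", "b", "c", "d")
.kp_sites <- c("N1", "O5", "O6")
.kp_ring_atoms <- c("N1", "C2", "C3", "C3a", "C4", "C5", "C6", "C7", "C7a",
                    "O5", "O6")

# intra-unit bonds of one DHI unit: the fused 5-6 ring system plus the two
# catechol-derived oxygens
.kp_intra_bonds <- matrix(c(
  "N1",  "C2",
  "C2",  "C3",
  "C3",  "C3a",
  "C3a", "C4",
  "C4",  "C5",
  "C5",  "C6",
  "C6",  "C7",
  "C7",  "C7a",
  "C7a", "N1",
  "C3a", "C7a",
  "C5",  "O5",
  "C6",  "O6"
), ncol = 2, byrow = TRUE)

# digit encoding of mobile sites used in tautomer names
.kp_site_digit <- c(N1 = "1", O5 = "5", O6 = "6")
.kp_digit_site <- c(`1` = "N1", `5` = "O5", `6` = "O6")
# bitmask used to order rotations when picking a canonical representative
.kp_site_bit <- c(N1 = 1L, O5 = 2L, O6 = 4L)

# package-level cache for the skeleton, adjacency and derived tables
.kp_cache <- new.env(parent = emptyenv())

#' Build the molecular graph of the DHI cyclotetramer
#'
#' Constructs the 44-heavy-atom graph of the porphyrin-type tetramer obtained
#' by oxidative cyclization of four 5,6-dihydroxyindole (DHI) units joined by
#' 2,7' bonds. Units are labelled `a`, `b`, `c`, `d` in the sequence of the
#' 2,7' connectivities, so the four inter-ring bonds form a directed cycle
#' a->b->c->d->a (C2 of one unit bonded to C7 of the next). Each unit carries
#' three mobile-hydrogen sites (N1, O5, O6), twelve in total.
#'
#' @return An object of class `kp_skeleton`: a list with
#'   \describe{
#'     \item{atoms}{data frame with columns `id`, `unit`, `label`, `element`
#'       (44 rows, deterministic order: unit a..d, atom labels N1, C2, C3,
#'       C3a, C4, C5, C6, C7, C7a, O5, O6).}
#'     \item{bonds}{data frame with columns `i`, `j` (atom ids, `i < j`) and
#'       `type` (`"intra"` or `"inter"`); 52 rows.}
#'     \item{mobile_sites}{data frame with columns `unit`, `site`, `atom_id`
#'       (12 rows).}
#'   }
#' @examples
#' skel <- build_skeleton()
#' nrow(skel$atoms)         # 44
#' nrow(skel$bonds)         # 52
#' nrow(skel$mobile_sites)  # 12
#' @export
build_skeleton <- function() {
  if (!is.null(.kp_cache$skeleton)) return(.kp_cache$skeleton)
  atoms <- data.frame(
    id      = seq_len(4L * length(.kp_ring_atoms)),
    unit    = rep(.kp_units, each = length(.kp_ring_atoms)),
    label   = rep(.kp_ring_atoms, times = 4L),
    element = rep(substr(.kp_ring_atoms, 1L, 1L), times = 4L),
    stringsAsFactors = FALSE
  )
  idx <- function(unit, label) {
    atoms$id[atoms$unit == unit & atoms$label == label]
  }
  bonds <- do.call(rbind, lapply(.kp_units, function(u) {
    data.frame(
      i = vapply(.kp_intra_bonds[, 1L], idx, integer(1), unit = u),
      j = vapply(.kp_intra_bonds[, 2L], idx, integer(1), unit = u),
      type = "intra", stringsAsFactors = FALSE
    )
  }))
  inter <- do.call(rbind, lapply(seq_along(.kp_units), function(k) {
    u <- .kp_units[k]
    v <- .kp_units[k %% 4L + 1L]
    data.frame(i = idx(u, "C2"), j = idx(v, "C7"), type = "inter",
               stringsAsFactors = FALSE)
  }))
  bonds <- rbind(bonds, inter)
  swap <- bonds$i > bonds$j
  tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
  rownames(bonds) <- NULL
  mobile <- expand.grid(site = .kp_sites, unit = .kp_units,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mobile <- mobile[, c("unit", "site")]
  mobile <- mobile[order(match(mobile$unit, .kp_units),
                         match(mobile$site, .kp_sites)), ]
  mobile$atom_id <- mapply(idx, mobile$unit, mobile$site)
  rownames(mobile) <- NULL
  skel <- structure(list(atoms = atoms, bonds = bonds, mobile_sites = mobile),
                    class = "kp_skeleton")
  .kp_cache$skeleton <- skel
  skel
}

#' @export
print.kp_skeleton <- function(x, ...) {
  cat("DHI cyclotetramer skeleton: ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, ", nrow(x$mobile_sites),
      " mobile H sites\n", sep = "")
  invisible(x)
}

# adjacency list (atom id -> neighbouring atom ids) and bond id lookup
.kp_adjacency <- function() {
  if (!is.null(.kp_cache$adj)) return(.kp_cache$adj)
  skel <- build_skeleton()
  n <- nrow(skel$atoms)
  nbrs <- vector("list", n)
  bond_of <- matrix(0L, n, n)
  for (b in seq_len(nrow(skel$bonds))) {
    i <- skel$bonds$i[b]; j <- skel$bonds$j[b]
    nbrs[[i]] <- c(nbrs[[i]], j)
    nbrs[[j]] <- c(nbrs[[j]], i)
    bond_of[i, j] <- b; bond_of[j, i] <- b
  }
  .kp_cache$adj <- list(nbrs = nbrs, bond_of = bond_of)
  .kp_cache$adj
}

.kp_new_name <- function(removed) {
  removed <- lapply(removed, function(s) .kp_sites[.kp_sites %in% s])
  names(removed) <- .kp_units
  structure(list(removed = removed), class = "kp_name")
}

#' Parse a tautomer name string
#'
#' Tautomer names follow the `aXX_bXX_cXX_dXX` scheme: for each unit the
#' digits of the mobile hydrogens that have been *removed* relative to the
#' fully reduced form are listed in ascending order (`1` = N1, `5` = O5,
#' `6` = O6), with `0` standing for none. For example `"a56_b16_c0_d0"`
#' denotes an o-quinone unit (O5 and O6 hydrogens removed on unit a) next to
#' a quinone-methide/imine unit (N1 and O6 removed on unit b).
#'
#' @param text a single name string.
#' @return A `kp_name` object: list with element `removed`, a named list
#'   mapping each unit to the character vector of removed sites.
#' @examples
#' parse_name("a56_b16_c0_d0")$removed$a  # "O5" "O6"
#' @export
parse_name <- function(text) {
  if (inherits(text, "kp_name")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(toks) != 4L)
    stop("malformed tautomer name '", text, "': expected 4 unit tokens")
  removed <- vector("list", 4L)
  for (k in seq_len(4L)) {
    tok <- toks[k]
    if (substr(tok, 1L, 1L) != .kp_units[k])
      stop("malformed unit token '", tok, "': expected unit '",
           .kp_units[k], "' at position ", k)
    digits <- substring(tok, 2L)
    if (digits == "0") {
      removed[[k]] <- character(0)
      next
    }
    ch <- strsplit(digits, "")[[1]]
    if (length(ch) == 0L || anyDuplicated(ch) ||
        !all(ch %in% names(.kp_digit_site)) ||
        is.unsorted(as.integer(ch), strictly = TRUE))
      stop("malformed unit token '", tok,
           "': digits must be an ascending subset of {1,5,6}, or '0'")
    removed[[k]] <- unname(.kp_digit_site[ch])
  }
  .kp_new_name(removed)
}

#' Format a tautomer name as a string
#'
#' Inverse of [parse_name()]: digits ascending within each unit, `0` for an
#' empty set.
#'
#' @param name a `kp_name` object (or a name string, returned normalized).
#' @return The normalized name string.
#' @examples
#' format_name(parse_name("a56_b16_c0_d0"))  # "a56_b16_c0_d0"
#' @export
format_name <- function(name) {
  name <- parse_name(name)
  toks <- vapply(seq_len(4L), function(k) {
    s <- name$removed[[k]]
    digits <- if (length(s) == 0L) "0" else
      paste(sort(unname(.kp_site_digit[s])), collapse = "")
    paste0(.kp_units[k], digits)
  }, character(1))
  paste(toks, collapse = "_")
}

#' @export
print.kp_name <- function(x, ...) {
  cat("<kp_name> ", format_name(x), " (oxidation level ",
      oxidation_level(x), ")\n", sep = "")
  invisible(x)
}

#' @export
format.kp_name <- function(x, ...) format_name(x)

# per-unit bitmask tuple (N1=1, O5=2, O6=4)
.kp_masks <- function(name) {
  vapply(name$removed, function(s) sum(.kp_site_bit[s]), numeric(1))
}

.kp_name_from_masks <- function(masks) {
  .kp_new_name(lapply(masks, function(m) {
    .kp_sites[bitwAnd(m, .kp_site_bit[.kp_sites]) > 0L]
  }))
}

#' Canonical representative under cyclic rotation
#'
#' Two tautomer names describe the same species when one is obtained from the
#' other by cyclically rotating the unit labels (a->b->c->d->a); the 2,7'
#' connectivity is directional, so only the four rotations -- no reflections
#' -- are graph automorphisms. The canonical representative is the rotation
#' whose per-unit bitmask tuple (N1=1, O5=2, O6=4) is lexicographically
#' smallest.
#'
#' @param name a `kp_name` or name string.
#' @return The canonical `kp_name`.
#' @examples
#' format_name(canonical_form("a0_b56_c0_d0"))  # "a0_b0_c0_d56"
#' @export
canonical_form <- function(name) {
  name <- parse_name(name)
  masks <- as.integer(.kp_masks(name))
  best <- masks
  for (k in 1:3) {
    rot <- c(masks[(k + 1):4], masks[1:k])
    for (p in 1:4) {
      if (rot[p] < best[p]) { best <- rot; break }
      if (rot[p] > best[p]) break
    }
  }
  .kp_name_from_masks(as.list(best))
}

#' Oxidation level of a tautomer
#'
#' The oxidation level is the total number of mobile (heteroatom-bound)
#' hydrogens removed relative to the fully reduced form: removing n hydrogens
#' and n electrons gives the n-electron oxidized species KP-ne.
#'
#' @param name a `kp_name` or name string.
#' @return Integer count of removed hydrogens, in 0..12.
#' @examples
#' oxidation_level("a56_b16_c0_d0")  # 4
#' @export
oxidation_level <- function(name) {
  name <- parse_name(name)
  sum(lengths(name$removed))
}

#' Test equivalence of two tautomer names under cyclic rotation
#'
#' @param x,y names (strings or `kp_name` objects).
#' @return `TRUE` iff the names lie in the same rotation orbit.
#' @export
same_orbit <- function(x, y) {
  identical(format_name(canonical_form(x)), format_name(canonical_form(y)))
}
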