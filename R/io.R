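# Record file I/O (versioned JSON) and SDF V2000 structure export.

.kp_record_format_version <- "1.0"

.kp_validate_record <- function(rec, index) {
  fail <- function(field, msg)
    stop("record ", index, ", field '", field, "': ", msg)
  if (is.null(rec$name) || !nzchar(rec$name)) fail("name", "missing")
  if (is.null(rec$level)) fail("level", "missing")
  if (!is.numeric(rec$level) || rec$level < 0 || rec$level > 12)
    fail("level", "must be a number in 0..12")
  if (!is.null(rec$orbital_energies)) {
    if (length(rec$orbital_energies$occupied) == 0L)
      fail("orbital_energies.occupied",
           "must be nonempty when the orbital block is present")
  }
  if (!is.null(rec$transitions) && nrow(as.data.frame(rec$transitions))) {
    tr <- as.data.frame(rec$transitions)
    if (any(tr$strength < 0))
      fail("transitions.strength", "oscillator strengths must be >= 0")
  }
  if (!is.null(rec$modes) && nrow(as.data.frame(rec$modes))) {
    md <- as.data.frame(rec$modes)
    if (any(md$intensity < 0))
      fail("modes.intensity", "intensities must be >= 0")
    if (any(md$frequency_cm <= 0))
      fail("modes.frequency_cm", "frequencies must be positive for minima")
  }
  invisible(rec)
}

#' Write species records to a versioned JSON file
#'
#' The file is a single JSON document with a `format_version` string and a
#' `records` array; all energies are in hartree, transition energies in eV,
#' frequencies in cm^-1 (units are fixed by the format, version "1.0").
#' Fields unknown to the schema are
#' preserved verbatim, and writing is normalized so that write-read-write
#' round-trips are byte-identical.
#'
#' @param records a list of species records, or a `kp_scenario`, or a
#'   record-file list as returned by [read_records()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  if (inherits(records, "kp_scenario")) records <- records$records
  if (!is.null(records$records)) records <- records$records
  records <- lapply(records, unclass)
  for (i in seq_along(records)) .kp_validate_record(records[[i]], i)
  doc <- list(format_version = .kp_record_format_version, records = records)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read species records from a JSON file
#'
#' @param path file written by [write_records()].
#' @return A `kp_record_file`: list with `format_version` and `records`
#'   (each a `kp_species_record`). Schema violations are reported with the
#'   offending record index and field.
#' @export
read_records <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$format_version) ||
      !identical(as.character(doc$format_version),
                 .kp_record_format_version))
    stop("unrecognized record file version: ",
         if (is.null(doc$format_version)) "<missing>" else doc$format_version)
  recs <- doc$records
  recs <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (!is.null(r$transitions)) r$transitions <- as.data.frame(r$transitions)
    if (!is.null(r$modes)) r$modes <- as.data.frame(r$modes)
    .kp_validate_record(r, i)
    structure(r, class = "kp_species_record")
  })
  structure(list(format_version = .kp_record_format_version, records = recs),
            class = "kp_record_file")
}

#' @export
print.kp_record_file <- function(x, ...) {
  cat("<kp_record_file> version ", x$format_version, ", ",
      length(x$records), " record(s)\n", sep = "")
  invisible(x)
}

# schematic unit-local 2D template for the 11 atoms of one DHI unit,
# in .kp_ring_atoms order
.kp_unit_template <- function() {
  rbind(
    N1  = c(-0.292, 2.768),
    C2  = c(-1.683, 2.915),
    C3  = c(-2.252, 1.637),
    C3a = c(-1.212, 0.700),
    C4  = c(-1.212, -0.700),
    C5  = c(0.000, -1.400),
    C6  = c(1.212, -0.700),
    C7  = c(1.212, 0.700),
    C7a = c(0.000, 1.400),
    O5  = c(0.000, -2.700),
    O6  = c(2.338, -1.350)
  )
}

#' Export a tautomer as an SDF V2000 structure file
#'
#' Writes the 44-atom, 52-bond connection table with bond orders taken from
#' the lexicographically first Kekulé structure of the tautomer. Coordinates
#' are a deterministic schematic 2D layout (the four units on a circle,
#' rotated by 90 degrees each), flagged as schematic in the comment line;
#' they carry no geometric meaning. Hydrogen counts on the heteroatoms are
#' implied by the removed-H sets of the name.
#'
#' @param name a closed-shell tautomer name.
#' @param path output file path.
#' @return The path, invisibly.
#' @examples
#' \dontrun{export_sdf("a0_b0_c0_d0", "kp_red.sdf")}
#' @export
export_sdf <- function(name, path) {
  name <- parse_name(name)
  ks <- kekule_structures(name)
  if (length(ks) == 0L)
    stop("open-shell tautomer '", format_name(name),
         "' has no Kekulé structure to export")
  skel <- build_skeleton()
  dbl <- ks[[1L]]$bond_ids
  tmpl <- .kp_unit_template()
  coords <- matrix(0, nrow(skel$atoms), 2L)
  for (k in seq_len(4L)) {
    th <- -(k - 1L) * pi / 2
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    centre <- 5.2 * c(cos(pi / 2 + (k - 1L) * pi / 2),
                      sin(pi / 2 + (k - 1L) * pi / 2))
    rows <- which(skel$atoms$unit == .kp_units[k])
    local <- tmpl[skel$atoms$label[rows], , drop = FALSE]
    coords[rows, ] <- sweep(local %*% t(rot), 2L, centre, `+`)
  }
  lines <- c(
    format_name(name),
    "  kporphyrin",
    "schematic 2D layout (units on a circle); bond orders from one Kekule structure",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            nrow(skel$atoms), nrow(skel$bonds)),
    vapply(seq_len(nrow(skel$atoms)), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              coords[i, 1], coords[i, 2], 0, skel$atoms$element[i])
    }, character(1)),
    vapply(seq_len(nrow(skel$bonds)), function(b) {
      sprintf("%3d%3d%3d  0", skel$bonds$i[b], skel$bonds$j[b],
              if (b %in% dbl) 2L else 1L)
    }, character(1)),
    "M  END",
    "$$$$"
  )
  writeLines(lines, path)
  invisible(path)
}
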