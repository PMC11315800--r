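#' Write a molecule to an XYZ file
#'
#' Standard XYZ output in angstrom. The comment line records the torsion
#' angles in degrees. Lone-pair vertices are omitted by default; with
#' `include_lone_pairs = TRUE` they are written with the dummy symbol `X`.
#'
#' @param graph A `chemion_molecule`.
#' @param path Output file path.
#' @param include_lone_pairs Emit lone-pair vertices as symbol `"X"`?
#' @return `path`, invisibly.
#' @export
write_xyz <- function(graph, path, include_lone_pairs = FALSE) {
  v <- graph$vertices
  if (!include_lone_pairs) v <- v[v$kind != "lone-pair", ]
  sym <- ifelse(v$kind == "lone-pair", "X", v$element)
  b <- chemion_constants$bohr_angstrom
  tors <- if (nrow(graph$torsions)) {
    paste(sprintf("%.4f", graph$torsions$value * 180 / pi), collapse = " ")
  } else {
    "none"
  }
  lines <- c(
    as.character(nrow(v)),
    paste0("torsions_deg: ", tors),
    sprintf("%-2s %16.10f %16.10f %16.10f", sym, v$x * b, v$y * b, v$z * b)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path XYZ file path (angstrom).
#' @return A tibble with columns `element`, `x`, `y`, `z` (positions in bohr).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  nat <- as.integer(lines[1])
  rows <- strsplit(trimws(lines[3:(2 + nat)]), "\\s+")
  b <- chemion_constants$bohr_angstrom
  tibble(
    element = vapply(rows, `[[`, "", 1),
    x = vapply(rows, function(r) as.numeric(r[2]), 0) / b,
    y = vapply(rows, function(r) as.numeric(r[3]), 0) / b,
    z = vapply(rows, function(r) as.numeric(r[4]), 0) / b
  )
}

#' Build a molecule from a structured text config
#'
#' Reads a YAML molecule specification with keys `terminal`, `n`,
#' `torsions_deg` (optional), `bond_lengths` (optional named overrides in
#' angstrom), and `exponents` (optional named orbital-exponent overrides),
#' and returns the corresponding chain molecule.
#'
#' @param spec Path to a YAML file, or an equivalent named list.
#' @return A `chemion_molecule`.
#' @export
#' @examples
#' mol <- read_molecule_spec(list(terminal = "CH3", n = 1, torsions_deg = 60))
read_molecule_spec <- function(spec) {
  if (is.character(spec)) {
    spec <- yaml::read_yaml(spec)
    # YAML 1.1 parses a bare key `n` as the boolean FALSE; restore it
    names(spec)[names(spec) %in% c("FALSE", "n")] <- "n"
  }
  if (is.null(spec$terminal) || is.null(spec$n)) {
    abort("molecule spec needs 'terminal' and 'n'", class = "chemion_bad_spec")
  }
  tors <- spec$torsions_deg
  if (is.null(tors)) tors <- rep(0, spec$n)
  build_chain(
    n = spec$n, terminal = spec$terminal,
    torsions = unlist(tors) * pi / 180,
    bond_lengths = if (!is.null(spec$bond_lengths)) unlist(spec$bond_lengths),
    exponents = if (!is.null(spec$exponents)) unlist(spec$exponents)
  )
}
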