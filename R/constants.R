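#' Physical and geometric constants of the vertex picture
#'
#' The model geometry is deliberately idealised: every centre is a perfect
#' tetrahedron, every lone pair sits one Bohr radius from its parent atom,
#' and all internal arithmetic is done in atomic units (bohr, hartree).
#' Input/output lengths are in angstrom.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_angstrom}{1 bohr in angstrom, 0.529177249.}
#'   \item{theta}{Tetrahedron bond angle, `acos(-1/3)` rad (about 109.471 deg).}
#'   \item{delta}{Tetrahedral dihedral spacing, `2*pi/3` rad (120 deg exactly).}
#' }
#' @export
#' @examples
#' chemion_constants$theta * 180 / pi
chemion_constants <- list(
  bohr_angstrom = 0.529177249,
  theta = acos(-1 / 3),
  delta = 2 * pi / 3
)

# valence charge (main-group column) and valence shell (row) per element
.element_data <- data.frame(
  element = c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl"),
  z_val   = c(1L, 4L, 5L, 6L, 7L, 4L, 5L, 6L, 7L),
  n_val   = c(1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L),
  n_lone  = c(0L, 0L, 1L, 2L, 3L, 0L, 1L, 2L, 3L),
  stringsAsFactors = FALSE
)

.element_row <- function(element) {
  i <- match(element, .element_data$element)
  if (is.na(i)) {
    abort(paste0("unknown element '", element, "'"), class = "chemion_unknown_element")
  }
  .element_data[i, ]
}

#' Default covalent bond lengths
#'
#' Idealised single-bond lengths in angstrom, used by the geometry builders.
#' Any entry can be overridden by passing a named vector; names are
#' order-independent ("C-H" and "H-C" are the same key).
#'
#' @return Named numeric vector of bond lengths in angstrom.
#' @export
#' @examples
#' default_bond_lengths()[["C-C"]]
default_bond_lengths <- function() {
  c(
    "C-C" = 1.54, "C-H" = 1.09, "N-H" = 1.01, "O-H" = 0.96,
    "C-N" = 1.47, "C-O" = 1.43, "C-F" = 1.38, "Si-H" = 1.48,
    "P-H" = 1.42, "S-H" = 1.34, "H-Cl" = 1.27, "C-Cl" = 1.77,
    "C-Si" = 1.87, "C-P" = 1.84, "C-S" = 1.82, "H-F" = 0.92,
    "Si-Si" = 2.33
  )
}

# bond length in bohr between two elements, with overrides in angstrom
.bond_length <- function(el1, el2, table = NULL) {
  tab <- default_bond_lengths()
  if (!is.null(table)) tab[names(table)] <- table
  key1 <- paste0(el1, "-", el2)
  key2 <- paste0(el2, "-", el1)
  val <- if (key1 %in% names(tab)) tab[[key1]] else tab[[key2]]
  if (is.null(val) || is.na(val)) {
    abort(paste0("no bond length for ", key1), class = "chemion_unknown_bond")
  }
  val / chemion_constants$bohr_angstrom
}
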