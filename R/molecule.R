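#' Molecular vertex graphs
#'
#' A `chemion_molecule` represents a singly bound molecule as a tree of
#' *vertices* (bonding sites): central atoms, hydrogen ligands, and lone-pair
#' positions. Every vertex carries exactly one spherical Slater basis orbital;
#' lone-pair vertices carry no nuclear charge and sit one Bohr radius from
#' their parent atom. The Euler topology rule `#vtx = #chp + 1` (vertices =
#' chemion pairs + 1) holds for every graph built here, because the graph is a
#' tree and every edge carries one shared pair.
#'
#' @name chemion_molecule
#' @keywords internal
NULL

.vertex_row <- function(label, kind, element, pos, parent = NA_integer_,
                        exponents = NULL) {
  ed <- .element_row(element)
  zeta <- if (!is.null(exponents) && element %in% names(exponents)) {
    unname(exponents[[element]])
  } else {
    ed$z_val / ed$n_val
  }
  tibble(
    label = label, kind = kind, element = element,
    x = pos[1], y = pos[2], z = pos[3],
    z_val = ed$z_val, n_val = ed$n_val, zeta = zeta,
    nucleus = kind != "lone-pair", parent = parent
  )
}

.new_molecule <- function(vertices, bonds, torsions, meta) {
  g <- structure(
    list(vertices = vertices, bonds = bonds, torsions = torsions, meta = meta),
    class = "chemion_molecule"
  )
  euler_counts(g) # structural validation
  g
}

#' Build a monofocal hydride
#'
#' Constructs the five-vertex graph of one of the eight anchor hydrides
#' (CH4, NH3, OH2, FH, SiH4, PH3, SH2, ClH): a central atom plus four
#' peripheral tetrahedral positions, filled left-to-right with hydrogen
#' ligands and then lone pairs. Hydrogens sit at the element-H bond length;
#' lone pairs at one Bohr radius.
#'
#' @param element Central atom, one of `"C"`, `"N"`, `"O"`, `"F"`, `"Si"`,
#'   `"P"`, `"S"`, `"Cl"`.
#' @param bond_lengths Optional named vector of bond-length overrides in
#'   angstrom (e.g. `c("O-H" = 0.97)`).
#' @param exponents Optional named vector of orbital exponents per element
#'   (1/bohr), overriding the default ratio rule `zeta = z_val / n_val`.
#' @return A `chemion_molecule`.
#' @export
#' @examples
#' ch4 <- build_monofocal("C")
#' euler_counts(ch4)
build_monofocal <- function(element, bond_lengths = NULL, exponents = NULL) {
  ed <- .element_row(element)
  if (element == "H") {
    abort("monofocals need a tetravalent-frame central atom, not H",
      class = "chemion_unknown_element"
    )
  }
  dirs <- .tetra_dirs()
  n_h <- 4L - ed$n_lone
  verts <- .vertex_row(element, "central-atom", element, c(0, 0, 0),
    exponents = exponents
  )
  bonds <- matrix(integer(0), ncol = 2)
  lam_h <- if (n_h > 0) .bond_length(element, "H", bond_lengths) else NA_real_
  for (i in seq_len(4)) {
    if (i <= n_h) {
      verts <- bind_rows(verts, .vertex_row(
        paste0("H", i), "hydrogen-ligand", "H", dirs[i, ] * lam_h,
        parent = 1L, exponents = exponents
      ))
    } else {
      lp <- .vertex_row(paste0("lp", i - n_h), "lone-pair", element,
        dirs[i, ] * 1.0,
        parent = 1L, exponents = exponents
      )
      lp$nucleus <- FALSE
      verts <- bind_rows(verts, lp)
    }
    bonds <- rbind(bonds, c(1L, i + 1L))
  }
  .new_molecule(
    verts, bonds,
    torsions = tibble(
      index = integer(0), from = integer(0),
      to = integer(0), value = numeric(0)
    ),
    meta = list(
      family = "monofocal", element = element,
      bond_lengths = bond_lengths, exponents = exponents
    )
  )
}

.terminal_table <- c(
  CH3 = "C", NH2 = "N", OH = "O", F = "F",
  SiH3 = "Si", PH2 = "P", SH = "S", Cl = "Cl"
)

#' Build a chain molecule H-(CH2)n-X
#'
#' Constructs the explicit vertex graph of a chain `H-(CH2)n-X` with all
#' tetrahedral centres ideal and backbone torsions set to the supplied
#' values. `n` counts methylene units: `build_chain(1, "CH3")` is ethane,
#' `build_chain(0, "OH")` is water. The total vertex count is `3n + 5`
#' for every terminal (hydrogens missing from the terminal are replaced by
#' lone-pair vertices), so the Euler rule `#vtx = #chp + 1` always holds.
#'
#' Vertices are listed from the terminal group outward (X group first, then
#' methylenes, then the leading hydrogen), and coordinates are anchored at X:
#' growing the chain by one unit leaves every previously placed vertex
#' bit-identical, which is what makes fragment reuse across chain-growth
#' steps exact.
#'
#' @param n Number of CH2 units, `>= 0`.
#' @param terminal Terminal group, one of `"CH3"`, `"NH2"`, `"OH"`, `"F"`,
#'   `"SiH3"`, `"PH2"`, `"SH"`, `"Cl"`.
#' @param torsions Backbone torsion angles in radians, length `n`. Torsion
#'   `i` belongs to the backbone bond `i` steps away from the terminal group
#'   (torsion 1 is the X-adjacent bond, torsion `n` the bond of the leading
#'   methyl).
#' @inheritParams build_monofocal
#' @return A `chemion_molecule` with `n` torsional degrees of freedom.
#' @export
#' @examples
#' ethane <- build_chain(1, "CH3")
#' euler_counts(ethane)
build_chain <- function(n, terminal, torsions = rep(0, n),
                        bond_lengths = NULL, exponents = NULL) {
  if (n < 0) abort("chain length n must be >= 0", class = "chemion_bad_chain")
  if (!terminal %in% names(.terminal_table)) {
    abort(paste0("unsupported terminal group '", terminal, "'"),
      class = "chemion_bad_chain"
    )
  }
  if (length(torsions) != n) {
    abort("torsions must have length n", class = "chemion_bad_chain")
  }
  x_el <- .terminal_table[[terminal]]
  ed <- .element_row(x_el)
  n_h <- 3L - ed$n_lone # peripheral hydrogens on the terminal centre
  dirs <- .tetra_dirs()
  theta <- chemion_constants$theta

  # backbone centre positions: cent[1] = X, cent[2] = C_n, ..., cent[n+1] = C_1,
  # cent[n+2] = leading hydrogen
  cent <- vector("list", n + 2L)
  cent[[1]] <- c(0, 0, 0)
  lam_xc <- if (n > 0) .bond_length(x_el, "C", bond_lengths) else NULL
  lam_cc <- if (n > 1) .bond_length("C", "C", bond_lengths) else NULL
  lam_ch <- .bond_length("C", "H", bond_lengths)
  if (n == 0) {
    cent[[2]] <- dirs[1, ] * .bond_length(x_el, "H", bond_lengths)
  } else {
    cent[[2]] <- dirs[1, ] * lam_xc
    for (j in seq(3, n + 2)) {
      is_h <- j == n + 2L
      bond <- if (is_h) lam_ch else lam_cc
      A <- if (j == 3) cent[[1]] + dirs[2, ] else cent[[j - 3]]
      cent[[j]] <- .place_internal(A, cent[[j - 2]], cent[[j - 1]],
        bond = bond, angle = theta, dihedral = pi
      )
    }
  }

  # vertex list: X group, methylenes from the X end, leading hydrogen
  verts <- .vertex_row(x_el, "central-atom", x_el, cent[[1]],
    exponents = exponents
  )
  bonds <- matrix(integer(0), ncol = 2)
  u_back <- dirs[1, ]
  lam_xh <- if (n_h > 0) .bond_length(x_el, "H", bond_lengths) else NA_real_
  for (i in seq_len(3)) {
    d <- dirs[i + 1, ]
    if (i <= n_h) {
      verts <- bind_rows(verts, .vertex_row(
        paste0(x_el, "H", i), "hydrogen-ligand", "H", d * lam_xh,
        parent = 1L, exponents = exponents
      ))
    } else {
      lp <- .vertex_row(paste0("lp", i - n_h), "lone-pair", x_el, d * 1.0,
        parent = 1L, exponents = exponents
      )
      lp$nucleus <- FALSE
      verts <- bind_rows(verts, lp)
    }
    bonds <- rbind(bonds, c(1L, i + 1L))
  }
  centre_idx <- c(1L) # vertex index of backbone centre j
  for (j in seq_len(n)) {
    ci <- nrow(verts) + 1L
    verts <- bind_rows(verts, .vertex_row(
      paste0("C", n - j + 1L), "central-atom", "C", cent[[j + 1]],
      exponents = exponents
    ))
    centre_idx <- c(centre_idx, ci)
    bonds <- rbind(bonds, c(centre_idx[j], ci))
    u1 <- .unit3(cent[[j]] - cent[[j + 1]])
    u2 <- .unit3(cent[[j + 2]] - cent[[j + 1]])
    hdirs <- .tetra_complete2(u1, u2)
    for (k in 1:2) {
      verts <- bind_rows(verts, .vertex_row(
        paste0("C", n - j + 1L, "H", k), "hydrogen-ligand", "H",
        cent[[j + 1]] + hdirs[[k]] * lam_ch,
        parent = ci, exponents = exponents
      ))
      bonds <- rbind(bonds, c(ci, nrow(verts)))
    }
  }
  # leading hydrogen
  verts <- bind_rows(verts, .vertex_row(
    "H", "hydrogen-ligand", "H", cent[[n + 2]],
    parent = centre_idx[n + 1L], exponents = exponents
  ))
  bonds <- rbind(bonds, c(centre_idx[n + 1L], nrow(verts)))

  tors <- tibble(
    index = seq_len(n),
    from = centre_idx[seq_len(n)],
    to = centre_idx[seq_len(n) + 1L],
    value = 0
  )
  g <- .new_molecule(verts, bonds, tors, meta = list(
    family = "chain", terminal = terminal, n = n,
    bond_lengths = bond_lengths, exponents = exponents
  ))
  for (i in seq_len(n)) {
    g$torsions$value[i] <- .measure_torsion(g, i)
  }
  for (i in seq_len(n)) {
    g <- set_torsion(g, i, torsions[i])
  }
  g
}

# first-listed peripheral neighbour of vertex v, excluding `not`
.reference_ligand <- function(graph, v, not) {
  nb <- c(
    graph$bonds[graph$bonds[, 1] == v, 2],
    graph$bonds[graph$bonds[, 2] == v, 1]
  )
  nb <- sort(nb[nb != not])
  kinds <- graph$vertices$kind[nb]
  periph <- nb[kinds != "central-atom"]
  if (length(periph) == 0) {
    abort("no reference ligand for torsion measurement",
      class = "chemion_geometry_error"
    )
  }
  periph[1]
}

.vertex_pos <- function(graph, i) {
  unlist(graph$vertices[i, c("x", "y", "z")], use.names = FALSE)
}

.measure_torsion <- function(graph, torsion_index) {
  tr <- graph$torsions[torsion_index, ]
  rp <- .reference_ligand(graph, tr$from, tr$to)
  rd <- .reference_ligand(graph, tr$to, tr$from)
  .dihedral(
    .vertex_pos(graph, rp), .vertex_pos(graph, tr$from),
    .vertex_pos(graph, tr$to), .vertex_pos(graph, rd)
  )
}

# vertices on the `to` side of the bond (from, to): everything reachable from
# `to` without crossing the bond
.distal_set <- function(graph, from, to) {
  nv <- nrow(graph$vertices)
  adj <- vector("list", nv)
  for (r in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds[r, 1]
    b <- graph$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, nv)
  seen[from] <- TRUE
  seen[to] <- TRUE
  queue <- to
  out <- to
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
        out <- c(out, w)
      }
    }
  }
  sort(out)
}

#' Set a backbone torsion angle
#'
#' Rigidly rotates the fragment on the leading-hydrogen side of backbone bond
#' `torsion_index` about the bond axis so that the torsion (measured between
#' the first-listed ligand on each side of the bond, right-hand rule looking
#' from the terminal-group side) equals `tau`. All bond lengths and angles,
#' and all other torsions, are preserved exactly.
#'
#' @param graph A `chemion_molecule` with torsions.
#' @param torsion_index Torsion number (1 = terminal-adjacent bond).
#' @param tau Target angle in radians; reduced modulo `2*pi`.
#' @return The modified `chemion_molecule`.
#' @export
#' @examples
#' e0 <- build_chain(1, "CH3")
#' e1 <- set_torsion(e0, 1, pi / 3)
set_torsion <- function(graph, torsion_index, tau) {
  if (!is.numeric(torsion_index) || torsion_index < 1 ||
    torsion_index > nrow(graph$torsions)) {
    abort("invalid torsion index", class = "chemion_bad_torsion")
  }
  tau <- tau %% (2 * pi)
  tr <- graph$torsions[torsion_index, ]
  current <- .measure_torsion(graph, torsion_index)
  delta <- tau - current
  pa <- .vertex_pos(graph, tr$from)
  pb <- .vertex_pos(graph, tr$to)
  # rotation that *increases* the measured dihedral by delta: the distal side
  # rotates about the from->to axis by -delta (right-hand rule)
  rot <- .rotation_matrix(pb - pa, -delta)
  distal <- .distal_set(graph, tr$from, tr$to)
  xyz <- as.matrix(graph$vertices[distal, c("x", "y", "z")])
  xyz <- t(rot %*% (t(xyz) - pb) + pb)
  graph$vertices[distal, c("x", "y", "z")] <- as.data.frame(xyz)
  graph$torsions$value[torsion_index] <- tau
  graph
}

#' Euler topology counts
#'
#' Returns the vertex, chemion-pair, and nucleus counts of a molecule graph
#' and validates the Euler rule `#vtx = #chp + 1` (an error of class
#' `chemion_euler_violation` is raised if it fails).
#'
#' @param graph A `chemion_molecule`.
#' @return Named integer vector `c(vtx = , chp = , nuc = )`.
#' @export
#' @examples
#' euler_counts(build_monofocal("O")) # c(vtx = 5, chp = 4, nuc = 3)
euler_counts <- function(graph) {
  vtx <- nrow(graph$vertices)
  chp <- nrow(graph$bonds)
  nuc <- sum(graph$vertices$nucleus)
  if (vtx != chp + 1L) {
    abort(paste0("Euler rule violated: #vtx=", vtx, ", #chp=", chp),
      class = "chemion_euler_violation"
    )
  }
  c(vtx = vtx, chp = chp, nuc = nuc)
}

#' @export
print.chemion_molecule <- function(x, ...) {
  cts <- euler_counts(x)
  cat(
    "<chemion_molecule> ", cts["vtx"], " vertices, ", cts["chp"],
    " chemion pairs, ", cts["nuc"], " nuclei, ",
    nrow(x$torsions), " torsion(s)\n",
    sep = ""
  )
  print(as_tibble(x$vertices))
  invisible(x)
}

#' Vertex table of a molecule
#'
#' @param x A `chemion_molecule`.
#' @param ... Unused.
#' @return A tibble with one row per vertex (positions in bohr).
#' @method tidy chemion_molecule
#' @export
tidy.chemion_molecule <- function(x, ...) {
  as_tibble(x$vertices)
}
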