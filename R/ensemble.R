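#' Chemionic ensembles
#'
#' A chemionic ensemble is a subset of the molecule's shared electron pairs
#' ("chemions") treated as its own closed-shell system: it carries
#' `chp` chemion pairs and a set of *proportional nuclear charges* -- the
#' valence charges of all nuclei rescaled so that their sum equals the
#' ensemble's total chemion charge `2 * chp`. The two ensembles used
#' throughout are the full molecule (all pairs) and a single chain bond
#' (one pair, `chp = 1`, basis condensed to the two fragments it joins).
#'
#' @param graph A `chemion_molecule`.
#' @return A `chemion_ensemble` with fields `kind`, `chp`, `members`
#'   (named list of vertex index groups), and `z_prop`.
#' @name chemion_ensemble
NULL

.new_ensemble <- function(kind, chp, members, graph) {
  ens <- structure(
    list(kind = kind, chp = chp, members = members),
    class = "chemion_ensemble"
  )
  ens$z_prop <- proportional_charges(ens, graph)
  ens
}

#' @rdname chemion_ensemble
#' @export
full_molecule_ensemble <- function(graph) {
  cts <- euler_counts(graph)
  .new_ensemble(
    "full-molecule", unname(cts["chp"]),
    list(all = seq_len(cts["vtx"])), graph
  )
}

#' @rdname chemion_ensemble
#' @param torsion_index Backbone bond whose chemion pair forms the ensemble.
#' @param kind For chain-bond ensembles, one of `"off-diagonal-ab"` (the
#'   bond pair itself; default), `"diagonal-aa"` or `"diagonal-bb"` (the
#'   fragment-diagonal contributions of a condensation step).
#' @export
chain_bond_ensemble <- function(graph, torsion_index,
                                kind = c(
                                  "off-diagonal-ab", "diagonal-aa",
                                  "diagonal-bb"
                                )) {
  kind <- match.arg(kind)
  if (torsion_index < 1 || torsion_index > nrow(graph$torsions)) {
    abort("invalid torsion index", class = "chemion_bad_torsion")
  }
  tr <- graph$torsions[torsion_index, ]
  distal <- .distal_set(graph, tr$from, tr$to) # leading-hydrogen side (alpha)
  proximal <- setdiff(seq_len(nrow(graph$vertices)), distal)
  .new_ensemble(kind, 1L, list(alpha = distal, beta = sort(proximal)), graph)
}

#' Proportional nuclear charges of an ensemble
#'
#' Each nucleus C receives the charge
#' `z_prop(C) = z_val(C) * 2 * chp / sum(z_val)`, so that the charges sum to
#' the ensemble's total chemion charge `2 * chp`.
#'
#' @param ensemble A `chemion_ensemble` (or any list with a `chp` field).
#' @param graph The `chemion_molecule` the ensemble lives on.
#' @return Numeric vector of length `#nuc`, named by vertex label, in units
#'   of elementary charge.
#' @export
#' @examples
#' eth <- build_chain(1, "CH3")
#' proportional_charges(chain_bond_ensemble(eth, 1), eth)
proportional_charges <- function(ensemble, graph) {
  nuc <- which(graph$vertices$nucleus)
  if (length(nuc) < 1) abort("graph has no nuclei", class = "chemion_no_nuclei")
  z <- graph$vertices$z_val[nuc]
  tot <- sum(z)
  if (tot <= 0) abort("zero total valence charge", class = "chemion_zero_charge")
  setNames(z * 2 * ensemble$chp / tot, graph$vertices$label[nuc])
}

#' Nuclear repulsion energy of an ensemble
#'
#' Pairwise Coulomb repulsion of the proportional point charges,
#' `sum_{A<B} z_prop(A) z_prop(B) / |R_A - R_B|`, in hartree.
#'
#' @inheritParams proportional_charges
#' @return Scalar energy in hartree (0 for a single nucleus).
#' @export
nuclear_repulsion <- function(ensemble, graph) {
  nuc <- which(graph$vertices$nucleus)
  zp <- proportional_charges(ensemble, graph)
  if (length(nuc) < 2) {
    return(0)
  }
  xyz <- as.matrix(graph$vertices[nuc, c("x", "y", "z")])
  e <- 0
  for (a in seq_len(length(nuc) - 1)) {
    for (b in seq(a + 1, length(nuc))) {
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      if (d < 1e-8) {
        abort("coincident nuclei", class = "chemion_coincident_nuclei")
      }
      e <- e + zp[a] * zp[b] / d
    }
  }
  unname(e)
}

#' @export
print.chemion_ensemble <- function(x, ...) {
  cat(
    "<chemion_ensemble> kind=", x$kind, ", chp=", x$chp,
    ", sum(z_prop)=", format(sum(x$z_prop)), "\n",
    sep = ""
  )
  invisible(x)
}
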