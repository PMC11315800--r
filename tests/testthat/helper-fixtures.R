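# Shared fixtures, computed once per test run. Low expansion order keeps the
# suite fast; the order-dependent accuracy contracts are tested explicitly in
# test-sto.R.

.fix <- new.env(parent = emptyenv())

fix_methane <- function() {
  if (is.null(.fix$methane)) .fix$methane <- build_monofocal("C")
  .fix$methane
}

fix_methane_ints <- function() {
  if (is.null(.fix$methane_ints)) {
    .fix$methane_ints <- build_anchor_integrals(fix_methane(), order = 3)
  }
  .fix$methane_ints
}

fix_methane_scf <- function() {
  if (is.null(.fix$methane_scf)) {
    .fix$methane_scf <- scf(fix_methane_ints(),
      full_molecule_ensemble(fix_methane()),
      tol = 1e-10, max_iter = 300
    )
  }
  .fix$methane_scf
}

fix_ethane <- function() {
  if (is.null(.fix$ethane)) .fix$ethane <- build_chain(1, "CH3")
  .fix$ethane
}

fix_ethane_ints <- function() {
  if (is.null(.fix$ethane_ints)) {
    .fix$ethane_ints <- build_anchor_integrals(fix_ethane(), order = 3)
  }
  .fix$ethane_ints
}

coords_of <- function(graph) as.matrix(graph$vertices[, c("x", "y", "z")])

# rigid rotation + translation of every vertex
transform_graph <- function(graph, axis = c(1, 2, 3), angle = 0.7,
                            shift = c(0.5, -1.2, 2.0)) {
  rot <- chemion:::.rotation_matrix(axis, angle)
  xyz <- coords_of(graph) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  graph$vertices[, c("x", "y", "z")] <- as.data.frame(xyz)
  graph
}
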