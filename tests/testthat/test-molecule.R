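test_that("monofocal hydrides have the expected vertex composition", {
  cases <- list(
    C = c(vtx = 5, chp = 4, nuc = 5, lp = 0),
    N = c(vtx = 5, chp = 4, nuc = 4, lp = 1),
    O = c(vtx = 5, chp = 4, nuc = 3, lp = 2),
    F = c(vtx = 5, chp = 4, nuc = 2, lp = 3),
    Si = c(vtx = 5, chp = 4, nuc = 5, lp = 0),
    P = c(vtx = 5, chp = 4, nuc = 4, lp = 1),
    S = c(vtx = 5, chp = 4, nuc = 3, lp = 2),
    Cl = c(vtx = 5, chp = 4, nuc = 2, lp = 3)
  )
  for (el in names(cases)) {
    mol <- build_monofocal(el)
    cts <- euler_counts(mol)
    expect_equal(unname(cts), unname(cases[[el]][1:3]))
    expect_equal(sum(mol$vertices$kind == "lone-pair"), unname(cases[[el]]["lp"]))
  }
  expect_error(build_monofocal("Xx"), class = "chemion_unknown_element")
})

test_that("lone pairs sit one Bohr radius from their parent and carry no nucleus", {
  w <- build_monofocal("O")
  lp <- which(w$vertices$kind == "lone-pair")
  expect_length(lp, 2)
  expect_false(any(w$vertices$nucleus[lp]))
  for (i in lp) {
    d <- sqrt(sum(coords_of(w)[i, ]^2)) # parent O is at the origin
    expect_equal(d, 1.0, tolerance = 1e-12)
    expect_equal(d * chemion_constants$bohr_angstrom, 0.529177249,
      tolerance = 1e-12
    )
  }
  # lone pairs inherit the parent's valence shell and exponent
  expect_equal(w$vertices$n_val[lp], c(2L, 2L))
  expect_equal(w$vertices$zeta[lp], c(3, 3))
})

test_that("the Euler rule #vtx = #chp + 1 holds for all chains and terminals", {
  for (terminal in c("CH3", "NH2", "OH", "F", "SiH3", "PH2", "SH", "Cl")) {
    for (n in 0:6) {
      g <- build_chain(n, terminal, torsions = rep(0.4, n))
      cts <- euler_counts(g)
      expect_equal(unname(cts["vtx"]), unname(cts["chp"]) + 1)
      expect_equal(unname(cts["vtx"]), 3 * n + 5) # lone pairs replace missing H
      expect_equal(nrow(g$torsions), n)
    }
  }
  expect_error(build_chain(-1, "CH3"), class = "chemion_bad_chain")
  expect_error(build_chain(1, "XH9"), class = "chemion_bad_chain")
})

test_that("chain geometry respects the ideal tetrahedral constants", {
  th <- chemion_constants$theta
  g <- build_chain(2, "CH3")
  xyz <- coords_of(g)
  ctr <- which(g$vertices$kind == "central-atom")
  for (c0 in ctr) {
    nb <- c(g$bonds[g$bonds[, 1] == c0, 2], g$bonds[g$bonds[, 2] == c0, 1])
    for (i in seq_along(nb)) {
      for (j in seq_len(i - 1)) {
        u <- xyz[nb[i], ] - xyz[c0, ]
        v <- xyz[nb[j], ] - xyz[c0, ]
        ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
        expect_equal(ang, th, tolerance = 1e-10)
      }
    }
  }
})

test_that("set_torsion is a 2*pi-periodic rigid rotation and a group action", {
  eth <- fix_ethane()
  same <- set_torsion(set_torsion(eth, 1, 1.1), 1, 1.1 + 2 * pi)
  expect_equal(coords_of(same), coords_of(set_torsion(eth, 1, 1.1)),
    tolerance = 1e-12
  )
  # rigid: every interatomic distance within each fragment is preserved
  d0 <- as.matrix(dist(coords_of(eth)))
  d1 <- as.matrix(dist(coords_of(set_torsion(eth, 1, 2.2))))
  tr <- eth$torsions[1, ]
  distal <- chemion:::.distal_set(eth, tr$from, tr$to)
  prox <- setdiff(seq_len(8), distal)
  expect_equal(d1[distal, distal], d0[distal, distal], tolerance = 1e-12)
  expect_equal(d1[prox, prox], d0[prox, prox], tolerance = 1e-12)
  # group action: composing increments equals the summed rotation
  g1 <- set_torsion(set_torsion(eth, 1, 0.7), 1, 0.7 + 0.9)
  g2 <- set_torsion(eth, 1, 1.6)
  expect_equal(coords_of(g1), coords_of(g2), tolerance = 1e-10)
  expect_error(set_torsion(eth, 5, 1), class = "chemion_bad_torsion")
})

test_that("rotating ethane by the dihedral spacing gives a congruent geometry", {
  # brute-force relabeling oracle: minimum RMSD over permutations of the
  # three equivalent hydrogens on each methyl carbon
  eth <- set_torsion(fix_ethane(), 1, 0.3)
  rot <- set_torsion(fix_ethane(), 1, 0.3 + 2 * pi / 3)
  h_x <- 2:4 # hydrogens on the terminal carbon
  h_c1 <- 6:7 # hydrogens on the leading methyl (plus the lead H, vertex 8)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- Inf
  x0 <- coords_of(eth)
  x1 <- coords_of(rot)
  lead <- c(6, 7, 8)
  for (p in perms3) {
    for (q in perms3) {
      map <- seq_len(8)
      map[h_x] <- h_x[p]
      map[lead] <- lead[q]
      best <- min(best, sqrt(mean((x1 - x0[map, ])^2)))
    }
  }
  expect_lt(best, 1e-10)
})

test_that("proportional charges follow the valence-charge rescaling", {
  eth <- fix_ethane()
  ens <- chain_bond_ensemble(eth, 1)
  zp <- proportional_charges(ens, eth)
  expect_length(zp, 8)
  cvals <- zp[eth$vertices$element[eth$vertices$nucleus] == "C"]
  hvals <- zp[eth$vertices$element[eth$vertices$nucleus] == "H"]
  expect_equal(unname(cvals), rep(4 / 7, 2), tolerance = 1e-14)
  expect_equal(unname(hvals), rep(1 / 7, 6), tolerance = 1e-14)
  expect_equal(sum(zp), 2, tolerance = 1e-12)
  # full methane ensemble: scale factor 1, charges equal valence charges
  mol <- fix_methane()
  zp2 <- proportional_charges(full_molecule_ensemble(mol), mol)
  expect_equal(unname(zp2), c(4, 1, 1, 1, 1), tolerance = 1e-14)
  # normalization identity across ensembles and molecules
  for (terminal in c("OH", "Cl")) {
    g <- build_chain(1, terminal)
    e <- chain_bond_ensemble(g, 1)
    expect_equal(sum(e$z_prop), 2 * e$chp, tolerance = 1e-12)
  }
})

test_that("nuclear repulsion matches a brute-force pairwise loop and is rigid-motion invariant", {
  mol <- fix_methane()
  ens <- full_molecule_ensemble(mol)
  zp <- proportional_charges(ens, mol)
  xyz <- coords_of(mol)[mol$vertices$nucleus, ]
  e_ref <- 0
  for (a in 1:4) {
    for (b in (a + 1):5) {
      e_ref <- e_ref + zp[a] * zp[b] / sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    }
  }
  expect_equal(nuclear_repulsion(ens, mol), unname(e_ref), tolerance = 1e-12)
  moved <- transform_graph(mol)
  expect_equal(nuclear_repulsion(ens, moved), unname(e_ref), tolerance = 1e-12)
  # two unit charges 2 bohr apart -> 0.5 hartree
  fake <- mol
  fake$vertices <- fake$vertices[1:2, ]
  fake$vertices$z_val <- c(1L, 1L)
  fake$vertices[, c("x", "y", "z")] <- data.frame(x = c(0, 2), y = 0, z = 0)
  fake$bonds <- matrix(c(1L, 2L), 1)
  e2 <- list(chp = 1)
  expect_equal(nuclear_repulsion(e2, fake), 0.5, tolerance = 1e-14)
})

test_that("euler_counts raises a structural error on a corrupted graph", {
  mol <- fix_methane()
  broken <- mol
  broken$bonds <- broken$bonds[-1, , drop = FALSE]
  expect_error(euler_counts(broken), class = "chemion_euler_violation")
})

test_that("the condensed chain-bond chart is constant along the chain", {
  # the bond ensemble always condenses to 2 vertices with one pair, and the
  # methyl-side fragment always holds 4 nuclei
  for (n in 1:3) {
    g <- build_chain(n, "CH3", torsions = rep(0.2, n))
    ens <- chain_bond_ensemble(g, n) # the leading methyl bond
    expect_equal(ens$chp, 1L)
    expect_length(ens$members, 2)
    expect_length(ens$members$alpha, 4) # H3C: one carbon + three hydrogens
    expect_equal(sum(g$vertices$nucleus[ens$members$alpha]), 4)
  }
})

test_that("geometry constants match their closed forms", {
  expect_equal(chemion_constants$theta, acos(-1 / 3), tolerance = 0)
  expect_equal(chemion_constants$theta * 180 / pi, 109.4712206, tolerance = 1e-6)
  expect_equal(chemion_constants$delta * 180 / pi, 120)
  expect_equal(chemion_constants$bohr_angstrom, 0.529177249)
})
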