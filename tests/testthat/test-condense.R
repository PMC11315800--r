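test_that("condensation normalization follows the overlap-sum rule", {
  expect_equal(condense_normalization(1, matrix(1)), 1)
  expect_equal(condense_normalization(1:2, diag(2)), 1 / sqrt(2))
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(condense_normalization(1:2, S), 1 / sqrt(3), tolerance = 1e-12)
  expect_error(
    condense_normalization(1:2, matrix(c(1, -1, -1, 1), 2)),
    class = "chemion_bad_condensation"
  )
})

test_that("singleton condensation reproduces the raw integrals exactly", {
  ints <- fix_methane_ints()
  cond <- condense_integrals(ints, as.list(1:5))
  expect_equal(cond$S, ints$S, tolerance = 1e-14)
  expect_equal(cond$K, ints$K, tolerance = 1e-14)
  expect_equal(cond$U, ints$U, tolerance = 1e-14)
  expect_equal(cond$R, ints$R, tolerance = 1e-14)
  expect_equal(cond$norms, rep(1, 5), tolerance = 1e-14)
  expect_error(
    condense_integrals(ints, list(1:2, 4:5)),
    class = "chemion_bad_condensation"
  )
})

test_that("condensed integrals equal direct integrals over the summed orbitals", {
  # linearity oracle: build each recursion orbital explicitly as the
  # normalized sum of its members (concatenated Gaussian primitives) and
  # evaluate the integral families with the primitive-level evaluators
  w <- build_monofocal("O")
  ints <- build_anchor_integrals(w, order = 3)
  groups <- list(c(1, 2, 4), c(3, 5))
  cond <- condense_integrals(ints, groups)
  v <- w$vertices
  orbs <- lapply(seq_len(5), function(i) {
    sto_orbital(v$n_val[i], v$zeta[i], c(v$x[i], v$y[i], v$z[i]), order = 3)
  })
  summed <- lapply(groups, function(g) {
    N <- condense_normalization(g, ints$S)
    # a summed s-orbital is not itself an STO; represent it directly by the
    # union of its members' primitives (centres kept per primitive)
    prim <- do.call(rbind, lapply(g, function(i) {
      cbind(
        alpha = orbs[[i]]$alpha, coef = N * orbs[[i]]$coef,
        cx = orbs[[i]]$center[1], cy = orbs[[i]]$center[2],
        cz = orbs[[i]]$center[3]
      )
    }))
    prim
  })
  # pairwise evaluation over primitive unions via single-primitive orbitals
  prim_orb <- function(row) {
    structure(
      list(
        n = 1, zeta = 1, center = row[c("cx", "cy", "cz")],
        alpha = row[["alpha"]], coef = row[["coef"]], order = 1
      ),
      class = "chemion_orbital"
    )
  }
  pair_sum <- function(p1, p2, fun, ...) {
    tot <- 0
    for (i in seq_len(nrow(p1))) {
      for (j in seq_len(nrow(p2))) {
        tot <- tot + fun(prim_orb(p1[i, ]), prim_orb(p2[j, ]), ...)
      }
    }
    tot
  }
  for (a in 1:2) {
    for (b in 1:2) {
      expect_equal(pair_sum(summed[[a]], summed[[b]], overlap),
        cond$S[a, b],
        tolerance = 1e-10
      )
      expect_equal(pair_sum(summed[[a]], summed[[b]], kinetic),
        cond$K[a, b],
        tolerance = 1e-10
      )
      nuc1 <- which(w$vertices$nucleus)[1]
      pos1 <- unlist(w$vertices[nuc1, c("x", "y", "z")])
      expect_equal(pair_sum(summed[[a]], summed[[b]], attraction, pos1),
        cond$U[a, b, 1],
        tolerance = 1e-10
      )
    }
  }
  # repulsion: quadruple sum over primitive unions
  quad_sum <- function(p1, p2, p3, p4) {
    tot <- 0
    for (i in seq_len(nrow(p1))) {
      for (j in seq_len(nrow(p2))) {
        for (k in seq_len(nrow(p3))) {
          for (l in seq_len(nrow(p4))) {
            tot <- tot + repulsion(
              prim_orb(p1[i, ]), prim_orb(p2[j, ]),
              prim_orb(p3[k, ]), prim_orb(p4[l, ])
            )
          }
        }
      }
    }
    tot
  }
  expect_equal(quad_sum(summed[[1]], summed[[2]], summed[[2]], summed[[1]]),
    cond$R[1, 2, 2, 1],
    tolerance = 1e-10
  )
  expect_equal(diag(cond$S), rep(1, 2), tolerance = 1e-10)
})

test_that("condensation is associative across levels", {
  eth <- fix_ethane()
  ints <- fix_ethane_ints()
  # two-step: first condense into four sub-fragments, then into two
  lvl1 <- condense_integrals(ints, list(1:4, 5:7, 8))
  lvl2 <- condense_integrals(lvl1, list(1, 2:3))
  # one-shot: same partition of the anchors
  once <- condense_integrals(ints, list(1:4, 5:8))
  expect_equal(lvl2$S, once$S, tolerance = 1e-10)
  expect_equal(lvl2$K, once$K, tolerance = 1e-10)
  expect_equal(lvl2$U, once$U, tolerance = 1e-10)
  expect_equal(lvl2$R, once$R, tolerance = 1e-10)
})

test_that("one-chemion matrix contracts charges correctly", {
  ints <- fix_methane_ints()
  zp <- proportional_charges(full_molecule_ensemble(fix_methane()), fix_methane())
  vh <- one_chemion_matrix(ints, zp)
  expect_equal(vh$H, ints$K - vh$V, tolerance = 1e-14)
  expect_equal(vh$V, t(vh$V), tolerance = 1e-10)
  # brute-force elementwise loop
  for (m in 1:5) {
    for (n in 1:5) {
      ref <- 0
      for (ci in 1:5) ref <- ref + zp[ci] * ints$U[m, n, ci]
      expect_equal(vh$V[m, n], unname(ref), tolerance = 1e-12)
    }
  }
  # zero charges and linearity
  expect_equal(one_chemion_matrix(ints, rep(0, 5))$H, ints$K, tolerance = 1e-14)
  expect_equal(one_chemion_matrix(ints, 2 * zp)$V, 2 * vh$V, tolerance = 1e-12)
  expect_error(one_chemion_matrix(ints, zp[1:3]), class = "chemion_bad_charges")
})

test_that("the fragment bank round-trips and persists blocks unchanged", {
  bank <- fragment_bank()
  blocks <- list(S = matrix(rnorm(4), 2), note = "x")
  bank_store(bank, "k1", blocks)
  expect_identical(bank_fetch(bank, "k1"), blocks)
  expect_null(bank_fetch(bank, "missing"))
  expect_equal(unname(bank_counters(bank)), c(1L, 1L))
  path <- tempfile(fileext = ".rds")
  bank2 <- fragment_bank(path)
  bank_store(bank2, "k1", blocks)
  bank_save(bank2)
  bank3 <- fragment_bank(path)
  expect_identical(bank_fetch(bank3, "k1"), blocks)
  # store -> load -> store is idempotent
  bank_save(bank3)
  bank4 <- fragment_bank(path)
  expect_identical(bank4$store, bank3$store)
  unlink(path)
})

test_that("fragment keys reflect everything that changes an integral", {
  eth <- fix_ethane()
  k0 <- fragment_key(eth, level = 1L, mode = "exact", order = 6)
  expect_identical(k0, fragment_key(eth, level = 1L, mode = "exact", order = 6))
  expect_false(identical(k0, fragment_key(set_torsion(eth, 1, 0.1), level = 1L)))
  expect_false(identical(k0, fragment_key(eth, level = 1L, order = 3)))
  expect_false(identical(k0, fragment_key(eth, level = 1L, mode = "two-center")))
  expect_false(identical(
    k0,
    fragment_key(eth, level = 1L, extra = list(kind = "diagonal-aa"))
  ))
})

test_that("condense_fock reuses only stored matching blocks", {
  ints <- fix_ethane_ints()
  eth <- fix_ethane()
  ens <- chain_bond_ensemble(eth, 1)
  H <- one_chemion_matrix(ints, ens$z_prop)$H
  fit <- scf(ints, ens, tol = 1e-10, max_iter = 300)
  bank <- fragment_bank()
  key <- fragment_key(eth, level = 0L, extra = list(kind = ens$kind))
  # missing key -> "not available"
  expect_null(condense_fock(bank, key))
  groups <- list(ens$members$alpha, ens$members$beta)
  bank_store(bank, key, list(F_prev = fit$F, S_prev = ints$S, groups = groups))
  Fc <- condense_fock(bank, key)
  expect_false(is.null(Fc))
  # recompute oracle: condensed F from condensed H, R and the frozen density
  cond <- condense_integrals(ints, groups)
  N <- vapply(groups, condense_normalization, 0, S_prev = ints$S)
  ref <- matrix(0, 2, 2)
  for (a in 1:2) {
    for (b in 1:2) {
      ref[a, b] <- N[a] * N[b] * sum(fit$F[groups[[a]], groups[[b]]])
    }
  }
  expect_equal(unclass(Fc)[1:2, 1:2], ref, tolerance = 1e-12)
  # singleton condensation of a stored block reproduces it exactly
  bank_store(bank, "single", list(F_prev = fit$F, S_prev = ints$S, groups = as.list(1:8)))
  expect_equal(unclass(condense_fock(bank, "single"))[1:8, 1:8], fit$F,
    tolerance = 1e-14
  )
})

test_that("integral budgets follow the difference-of-powers factorizations", {
  anchor <- integral_budget(NULL)
  expect_equal(anchor$n_S, 25L)
  expect_equal(anchor$n_R, 625L)
  b0 <- integral_budget(0)
  expect_identical(c(b0$a, b0$b), c(8L, 4L))
  expect_identical(b0$n_S, 48L) # 8^2 - 4^2
  expect_identical(b0$n_R, 3840L) # 8^4 - 4^4
  b2 <- integral_budget(2)
  expect_identical(b2$n_S, 96L) # 14^2 - 10^2
  for (n in 0:5) {
    b <- integral_budget(n)
    a <- b$a
    bb <- b$b
    expect_identical(a - bb, 4L)
    expect_identical(b$n_S, (a - bb) * (a + bb))
    expect_identical(b$n_U_bound, (a - bb) * (a * a + a * bb + bb * bb))
    expect_identical(b$n_R, (a - bb) * (a * a * a + a * a * bb + a * bb * bb + bb * bb * bb))
  }
})
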