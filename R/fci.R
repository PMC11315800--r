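#' Transform integrals to the molecular-orbital basis
#'
#' Congruence transform of the one-chemion matrix and full four-index
#' transform of the repulsion tensor with the converged SCF coefficients.
#' Because the vertex basis has exactly one orbital per bonding site
#' (`#vtx = #chp + 1`), the transformed set always has exactly one virtual
#' orbital, indexed `r = chp + 1`.
#'
#' @param fit A converged `chemion_scf`.
#' @return A `chemion_mo` with `h` (MO one-chemion matrix), `eri` (MO
#'   repulsion tensor, chemists' notation `(ab|cd)`), `chp`, and `r`.
#' @export
transform_integrals <- function(fit) {
  C <- fit$C
  vtx <- nrow(C)
  h <- t(C) %*% fit$H %*% C
  eri <- fit$ints$R
  for (m in 1:4) {
    eri <- array(t(C) %*% matrix(eri, vtx, vtx^3), rep(vtx, 4))
    eri <- aperm(eri, c(2, 3, 4, 1))
  }
  structure(
    list(h = h, eri = eri, chp = fit$chp, r = fit$chp + 1L, vtx = vtx),
    class = "chemion_mo"
  )
}

# generalized MO Fock-like matrix element F^m_kl = h_kl +
# sum over all orbitals n != m of [2(kl|nn) - (kn|nl)]
.fmat <- function(mo, k, l, m) {
  ns <- setdiff(seq_len(mo$vtx), m)
  val <- mo$h[k, l]
  for (n in ns) {
    val <- val + 2 * mo$eri[k, l, n, n] - mo$eri[k, n, n, l]
  }
  val
}

.e0_rhf <- function(mo) {
  occ <- seq_len(mo$chp)
  e <- 0
  for (m in occ) {
    e <- e + 2 * mo$h[m, m]
    for (n in occ) {
      e <- e + 2 * mo$eri[m, m, n, n] - mo$eri[m, n, n, m]
    }
  }
  e
}

# <S_c | H | D_{ab}> with c a member of {a, b}; `b` is the other member
.single_double_shared <- function(mo, b, a) {
  r <- mo$r
  ns_a <- setdiff(seq_len(mo$vtx), a)
  ns_r <- setdiff(seq_len(mo$vtx), r)
  val <- mo$h[b, r]
  for (n in ns_a) val <- val + mo$eri[b, r, n, n]
  for (n in ns_r) val <- val + mo$eri[b, r, n, n] - mo$eri[b, n, n, r]
  val - mo$eri[a, b, a, r]
}

# <D_{ab} | H | D_{bc}> sharing member s; u, v are the unshared members.
# One-chemion-plus-mean-field form of the effective u -> v single excitation
# between the two open-shell doubles (verified against determinant-space
# Slater-Condon evaluation to machine precision).
.double_double_shared <- function(mo, u, s, v) {
  r <- mo$r
  rest <- setdiff(seq_len(mo$chp), c(u, s, v))
  val <- mo$h[u, v]
  for (n in rest) val <- val + 2 * mo$eri[u, v, n, n] - mo$eri[u, n, n, v]
  val <- val + mo$eri[u, v, u, u] + mo$eri[u, v, v, v] + mo$eri[u, v, s, s] +
    2 * mo$eri[u, v, r, r] - mo$eri[u, r, r, v]
  -val + 2 * mo$eri[u, s, s, v]
}

#' Singlet configuration-interaction matrix
#'
#' Builds the full singlet block over the configuration-state-function basis
#' `[Psi0, single excitations a->r, pair doubles aa->rr, open-shell doubles
#' ab->rr (a<b)]` from closed-form matrix elements (the basis set has exactly
#' one virtual orbital, so this is the complete singlet space). The
#' dimension is `(chp+1)(chp+2)/2`.
#'
#' @param mo A `chemion_mo` from [transform_integrals()].
#' @return Symmetric matrix with attribute `"basis"` describing the CSF of
#'   each row.
#' @export
build_singlet <- function(mo) {
  chp <- mo$chp
  r <- mo$r
  if (mo$vtx != chp + 1L) {
    abort("CI formulas require exactly one virtual orbital (#vtx = #chp + 1)",
      class = "chemion_bad_ci"
    )
  }
  occ <- seq_len(chp)
  J <- function(a, b) mo$eri[a, a, b, b]
  K <- function(a, b) mo$eri[a, b, b, a]
  e0 <- .e0_rhf(mo)
  eps <- vapply(seq_len(mo$vtx), function(k) .fmat(mo, k, k, r), 0)

  basis <- c(
    list(list(type = "ref")),
    lapply(occ, function(a) list(type = "single", a = a)),
    lapply(occ, function(a) list(type = "pair", a = a)),
    if (chp >= 2) {
      unlist(lapply(seq_len(chp - 1), function(a) {
        lapply(seq(a + 1, chp), function(b) list(type = "open", a = a, b = b))
      }), recursive = FALSE)
    }
  )
  nb <- length(basis)
  M <- matrix(0, nb, nb)

  elem <- function(x, y) {
    tx <- x$type
    ty <- y$type
    if (tx == "ref" && ty == "ref") {
      return(e0)
    }
    if (tx == "ref" && ty == "single") {
      return(sqrt(2) * .fmat(mo, y$a, r, r))
    }
    if (tx == "ref" && ty == "pair") {
      return(K(y$a, r))
    }
    if (tx == "ref" && ty == "open") {
      return(sqrt(2) * mo$eri[y$a, r, y$b, r])
    }
    if (tx == "single" && ty == "single") {
      a <- x$a
      b <- y$a
      if (a == b) {
        return(e0 + eps[r] - eps[a] - J(a, r) + 2 * K(a, r))
      }
      return(-.fmat(mo, a, b, r) - mo$eri[a, b, r, r] + 2 * mo$eri[a, r, r, b])
    }
    if (tx == "single" && ty == "pair") {
      a <- y$a
      b <- x$a
      if (a == b) {
        return(sqrt(2) * .fmat(mo, a, r, a))
      }
      return(-sqrt(2) * mo$eri[a, b, a, r])
    }
    if (tx == "single" && ty == "open") {
      cc <- x$a
      if (cc == y$a) {
        return(.single_double_shared(mo, y$b, y$a))
      }
      if (cc == y$b) {
        return(.single_double_shared(mo, y$a, y$b))
      }
      return(-mo$eri[cc, y$a, y$b, r] - mo$eri[cc, y$b, y$a, r])
    }
    if (tx == "pair" && ty == "pair") {
      a <- x$a
      b <- y$a
      if (a == b) {
        return(e0 + 2 * (eps[r] - eps[a]) + J(r, r) + J(a, a) -
          4 * J(a, r) + 2 * K(a, r))
      }
      return(K(a, b))
    }
    if (tx == "pair" && ty == "open") {
      a <- x$a
      if (a == y$a) {
        return(-sqrt(2) * .fmat(mo, a, y$b, a))
      }
      if (a == y$b) {
        return(-sqrt(2) * .fmat(mo, a, y$a, a))
      }
      return(sqrt(2) * mo$eri[a, y$a, a, y$b])
    }
    if (tx == "open" && ty == "open") {
      p1 <- c(x$a, x$b)
      p2 <- c(y$a, y$b)
      shared <- intersect(p1, p2)
      if (length(shared) == 2) {
        a <- x$a
        b <- x$b
        return(e0 + 2 * eps[r] - eps[a] - eps[b] + J(r, r) + J(a, b) -
          2 * J(a, r) - 2 * J(b, r) + K(a, b) + K(a, r) + K(b, r))
      }
      if (length(shared) == 1) {
        s <- shared
        u <- setdiff(p1, s)
        v <- setdiff(p2, s)
        return(.double_double_shared(mo, u, s, v))
      }
      return(mo$eri[x$a, y$a, x$b, y$b] + mo$eri[x$a, y$b, x$b, y$a])
    }
    NA_real_
  }

  for (i in seq_len(nb)) {
    for (j in i:nb) {
      M[i, j] <- M[j, i] <- elem(basis[[i]], basis[[j]])
    }
  }
  attr(M, "basis") <- basis
  M
}

#' Triplet configuration-interaction matrix
#'
#' Builds the full M_S = 0 triplet block over `[singles a->r, open-shell
#' doubles ab->rr (a<b)]` as the singlet elements plus closed-form
#' singlet-to-triplet exchange corrections; every correction has been
#' verified element-by-element against a determinant-space Slater-Condon
#' evaluation. The open-shell triplet CSF is antisymmetric under exchange of
#' its two members (`T_ba = -T_ab`), which introduces the explicit sign
#' factors in the mixed elements. The dimension is `(chp+1)chp/2`. The
#' M_S = +1 and -1 blocks are identical by spin symmetry, so only this one
#' is constructed.
#'
#' @inheritParams build_singlet
#' @return Symmetric matrix with attribute `"basis"`.
#' @export
build_triplet <- function(mo) {
  chp <- mo$chp
  r <- mo$r
  if (mo$vtx != chp + 1L) {
    abort("CI formulas require exactly one virtual orbital (#vtx = #chp + 1)",
      class = "chemion_bad_ci"
    )
  }
  occ <- seq_len(chp)
  sing <- build_singlet(mo)
  sbasis <- attr(sing, "basis")
  stype <- vapply(sbasis, `[[`, "", "type")
  # index of a singlet basis element
  sidx <- function(type, a = NULL, b = NULL) {
    which(vapply(sbasis, function(e) {
      e$type == type &&
        (is.null(a) || (!is.null(e$a) && e$a == a)) &&
        (is.null(b) || (!is.null(e$b) && e$b == b))
    }, TRUE))
  }
  basis <- c(
    lapply(occ, function(a) list(type = "single", a = a)),
    if (chp >= 2) {
      unlist(lapply(seq_len(chp - 1), function(a) {
        lapply(seq(a + 1, chp), function(b) list(type = "open", a = a, b = b))
      }), recursive = FALSE)
    }
  )
  nb <- length(basis)
  M <- matrix(0, nb, nb)
  K <- function(a, b) mo$eri[a, b, b, a]

  elem <- function(x, y) {
    tx <- x$type
    ty <- y$type
    if (tx == "single" && ty == "single") {
      a <- x$a
      b <- y$a
      base <- sing[sidx("single", a), sidx("single", b)]
      if (a == b) {
        return(base - 2 * K(a, r))
      }
      return(base - 2 * mo$eri[a, r, r, b])
    }
    if (tx == "single" && ty == "open") {
      cc <- x$a
      base <- sing[sidx("single", cc), sidx("open", y$a, y$b)]
      other <- setdiff(c(y$a, y$b), cc)
      if (cc == y$a) {
        return(base + 2 * mo$eri[cc, other, cc, r])
      }
      if (cc == y$b) {
        # T_ab = -T_ba: the shared member is the pair's second slot
        return(-(base + 2 * mo$eri[cc, other, cc, r]))
      }
      return(base + 2 * mo$eri[cc, y$b, y$a, r])
    }
    if (tx == "open" && ty == "open") {
      shared <- intersect(c(x$a, x$b), c(y$a, y$b))
      if (length(shared) == 2) {
        base <- sing[sidx("open", x$a, x$b), sidx("open", y$a, y$b)]
        return(base - 2 * K(x$a, x$b))
      }
      if (length(shared) == 1) {
        s <- shared
        u <- setdiff(c(x$a, x$b), s)
        v <- setdiff(c(y$a, y$b), s)
        sgn <- (if (u < s) 1 else -1) * (if (v < s) 1 else -1)
        return(sgn * (.double_double_shared(mo, u, s, v) -
          2 * mo$eri[u, s, s, v]))
      }
      base <- sing[sidx("open", x$a, x$b), sidx("open", y$a, y$b)]
      return(base - 2 * (mo$eri[x$a, y$b, x$b, y$a]))
    }
    NA_real_
  }
  for (i in seq_len(nb)) {
    for (j in i:nb) {
      val_ij <- elem(basis[[i]], basis[[j]])
      M[i, j] <- M[j, i] <- val_ij
    }
  }
  attr(M, "basis") <- basis
  M
}

#' Chemionic ground energy from the two spin blocks
#'
#' The chemionic energy is the lower of the lowest singlet and lowest
#' triplet eigenvalue; the singlet wins ties. When the two are degenerate
#' within 1e-9 the multiplicity is reported as `"degenerate"`.
#'
#' @param singlet_spectrum,triplet_spectrum Numeric eigenvalue vectors
#'   (ascending). An empty triplet spectrum (chp = 0) selects the singlet.
#' @return List with `energy` (hartree) and `multiplicity` (`"singlet"`,
#'   `"triplet"` or `"degenerate"`).
#' @export
chemionic_energy <- function(singlet_spectrum, triplet_spectrum) {
  e1 <- min(singlet_spectrum)
  e3 <- if (length(triplet_spectrum)) min(triplet_spectrum) else Inf
  if (abs(e1 - e3) < 1e-9) {
    return(list(energy = e1, multiplicity = "degenerate"))
  }
  if (e1 <= e3) {
    list(energy = e1, multiplicity = "singlet")
  } else {
    list(energy = e3, multiplicity = "triplet")
  }
}

#' Total ensemble energy
#'
#' `E_0 = E_nucl + E_chem`: nuclear repulsion of the ensemble's proportional
#' charges plus the chemionic (lowest CI) energy.
#'
#' @inheritParams proportional_charges
#' @param e_chem Chemionic energy in hartree.
#' @return Scalar total energy in hartree.
#' @export
total_energy <- function(ensemble, graph, e_chem) {
  nuclear_repulsion(ensemble, graph) + e_chem
}

#' Full configuration interaction for a converged SCF state
#'
#' Transforms the integrals, builds and diagonalizes the singlet and triplet
#' blocks, and selects the chemionic ground energy.
#'
#' @param fit A converged `chemion_scf`.
#' @return A `chemion_fci` with the two matrices, their full spectra, the
#'   chemionic energy and multiplicity.
#' @export
#' @examples
#' mol <- build_monofocal("C")
#' ints <- build_anchor_integrals(mol, order = 3)
#' fit <- scf(ints, full_molecule_ensemble(mol), tol = 1e-8)
#' ci <- run_fci(fit)
#' glance(ci)
run_fci <- function(fit) {
  mo <- transform_integrals(fit)
  sing <- build_singlet(mo)
  trip <- build_triplet(mo)
  ev_s <- sort(eigen((sing + t(sing)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  ev_t <- if (nrow(trip)) {
    sort(eigen((trip + t(trip)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    numeric(0)
  }
  sel <- chemionic_energy(ev_s, ev_t)
  structure(
    list(
      mo = mo, singlet = sing, triplet = trip,
      singlet_values = ev_s, triplet_values = ev_t,
      e_chem = sel$energy, multiplicity = sel$multiplicity,
      e_rhf = .e0_rhf(mo), chp = mo$chp
    ),
    class = "chemion_fci"
  )
}

#' @export
print.chemion_fci <- function(x, ...) {
  cat(
    "<chemion_fci> #sing=", nrow(x$singlet), ", #trip=", nrow(x$triplet),
    ", E_chem=", format(x$e_chem), " (", x$multiplicity, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Eigenvalue table of a CI solution
#'
#' @param x A `chemion_fci`.
#' @param ... Unused.
#' @return A tibble with columns `block`, `state`, `energy`.
#' @method tidy chemion_fci
#' @export
tidy.chemion_fci <- function(x, ...) {
  bind_rows(
    tibble(
      block = "singlet", state = seq_along(x$singlet_values),
      energy = x$singlet_values
    ),
    tibble(
      block = "triplet", state = seq_along(x$triplet_values),
      energy = x$triplet_values
    )
  )
}

#' @rdname tidy.chemion_fci
#' @method glance chemion_fci
#' @export
glance.chemion_fci <- function(x, ...) {
  tibble(
    n_singlet = nrow(x$singlet),
    n_triplet = nrow(x$triplet),
    e_singlet = min(x$singlet_values),
    e_triplet = if (length(x$triplet_values)) min(x$triplet_values) else NA_real_,
    e_rhf = x$e_rhf,
    e_chem = x$e_chem,
    multiplicity = x$multiplicity
  )
}
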