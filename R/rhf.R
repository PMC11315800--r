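#' Closed-shell density matrix
#'
#' `D = 2 * C_occ %*% t(C_occ)` over the `chp` lowest molecular orbitals
#' (aufbau filling; each chemion pair doubly occupies one orbital).
#'
#' @param C Coefficient matrix, columns = molecular orbitals in ascending
#'   energy order.
#' @param chp Number of occupied orbitals (chemion pairs).
#' @return Symmetric density matrix.
#' @export
density_matrix <- function(C, chp) {
  if (ncol(C) < chp) abort("C has fewer columns than chp", class = "chemion_bad_density")
  occ <- C[, seq_len(chp), drop = FALSE]
  2 * occ %*% t(occ)
}

#' Fock matrix from one-chemion and repulsion blocks
#'
#' `F = H + W_cou - W_exc/2` with the Coulomb term
#' `W_cou[a,b] = sum_gd R[a,b,g,d] D[g,d]` and the symmetrized exchange term
#' `W_exc[a,b] = sum_gd (R[a,g,b,d] + R[a,d,g,b])/2 * D[g,d]`.
#'
#' @param H One-chemion matrix (kinetic minus charge-weighted attraction).
#' @param R_tensor Repulsion tensor with full 8-fold symmetry.
#' @param D Density matrix.
#' @return Symmetric Fock matrix.
#' @export
build_fock <- function(H, R_tensor, D) {
  vtx <- nrow(H)
  dvec <- as.vector(D)
  w_cou <- matrix(matrix(R_tensor, vtx^2) %*% dvec, vtx, vtx)
  b1 <- matrix(aperm(R_tensor, c(1, 3, 2, 4)), vtx^2)
  b2 <- matrix(aperm(R_tensor, c(1, 4, 3, 2)), vtx^2)
  w_exc <- matrix(0.5 * (b1 + b2) %*% dvec, vtx, vtx)
  F_ <- H + w_cou - 0.5 * w_exc
  (F_ + t(F_)) / 2
}

#' Solve the Roothaan generalized eigenproblem
#'
#' `F C = S C E` by symmetric (Loewdin) orthogonalization. Eigenvalues are
#' returned in ascending order; each column's phase is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param F Fock matrix.
#' @param S Overlap matrix (positive definite).
#' @return List with `C` (coefficients) and `E_orb` (orbital energies).
#' @export
solve_roothaan <- function(F, S) {
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(es$values) < 1e-8) {
    abort(
      paste0(
        "overlap matrix is near-singular (smallest eigenvalue ",
        format(min(es$values)), ")"
      ),
      class = "chemion_linear_dependence"
    )
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values)) %*% t(es$vectors)
  Fp <- t(X) %*% F %*% X
  ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(ef$values)
  C <- X %*% ef$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(C))) {
    imax <- which.max(abs(C[, k]))
    if (C[imax, k] < 0) C[, k] <- -C[, k]
  }
  list(C = C, E_orb = ef$values[ord])
}

#' Self-consistent restricted Hartree-Fock for a chemionic ensemble
#'
#' Iterates Fock build, Roothaan solve and density update from a
#' core-Hamiltonian start (`D = 0`) until the density root-mean-square
#' change `sigma(i) = sqrt(mean((D_i - D_{i-1})^2))` falls below `tol`.
#' On non-convergence the state is returned with `converged = FALSE`
#' rather than raising an error.
#'
#' @param ints A `chemion_integrals` (anchor or condensed).
#' @param ensemble A `chemion_ensemble` (supplies `chp` and the proportional
#'   charges), or `NULL` if `z_prop` and `chp` are given directly.
#' @param z_prop,chp Proportional charges and pair count (overridden by
#'   `ensemble`).
#' @param tol Density convergence threshold; 1e-4 is the documented default
#'   for a standalone solve, tighter values (1e-8) are used when the result
#'   feeds configuration interaction.
#' @param max_iter Iteration cap (default 200).
#' @param damping Fraction of the previous density mixed into the update
#'   (0 = plain iteration).
#' @param guess Optional starting density matrix.
#' @return A `chemion_scf` with coefficients `C`, orbital energies `E_orb`,
#'   density `D`, Fock `F`, one-chemion matrix `H`, the convergence history,
#'   and the electronic energy `0.5 * sum(D * (H + F))`.
#' @export
#' @examples
#' mol <- build_monofocal("C", )
#' ints <- build_anchor_integrals(mol, order = 3)
#' ens <- full_molecule_ensemble(mol)
#' fit <- scf(ints, ens, tol = 1e-8)
#' glance(fit)
scf <- function(ints, ensemble = NULL, z_prop = NULL, chp = NULL,
                tol = 1e-4, max_iter = 200, damping = 0, guess = NULL) {
  if (!is.null(ensemble)) {
    z_prop <- ensemble$z_prop
    chp <- ensemble$chp
  }
  if (is.null(z_prop) || is.null(chp)) {
    abort("need an ensemble or z_prop + chp", class = "chemion_bad_scf")
  }
  H <- one_chemion_matrix(ints, z_prop)$H
  vtx <- ints$vtx
  if (chp >= vtx) {
    abort("chp must be smaller than the basis size", class = "chemion_bad_scf")
  }
  D <- if (is.null(guess)) matrix(0, vtx, vtx) else guess
  sigma_history <- numeric(0)
  energy_history <- numeric(0)
  converged <- FALSE
  C <- NULL
  E_orb <- NULL
  for (i in seq_len(max_iter)) {
    F_ <- build_fock(H, ints$R, D)
    sol <- solve_roothaan(F_, ints$S)
    C <- sol$C
    E_orb <- sol$E_orb
    D_new <- density_matrix(C, chp)
    if (damping > 0) D_new <- (1 - damping) * D_new + damping * D
    sigma <- sqrt(sum((D_new - D)^2) / vtx^2)
    D <- D_new
    F_cur <- build_fock(H, ints$R, D)
    sigma_history <- c(sigma_history, sigma)
    energy_history <- c(energy_history, 0.5 * sum(D * (H + F_cur)))
    if (sigma < tol) {
      converged <- TRUE
      break
    }
  }
  F_final <- build_fock(H, ints$R, D)
  structure(
    list(
      C = C, E_orb = E_orb, D = D, F = F_final, H = H, S = ints$S,
      ints = ints, chp = chp, z_prop = z_prop,
      iterations = length(sigma_history),
      sigma_history = sigma_history, energy_history = energy_history,
      converged = converged,
      electronic_energy = 0.5 * sum(D * (H + F_final))
    ),
    class = "chemion_scf"
  )
}

#' @export
print.chemion_scf <- function(x, ...) {
  cat(
    "<chemion_scf> ", nrow(x$C), " orbitals, chp=", x$chp,
    ", E_elec=", format(x$electronic_energy),
    if (x$converged) " (converged in " else " (NOT converged after ",
    x$iterations, " iterations)\n",
    sep = ""
  )
  invisible(x)
}

#' Orbital-level summary of an SCF fit
#'
#' @param x A `chemion_scf`.
#' @param ... Unused.
#' @return A tibble with one row per molecular orbital.
#' @method tidy chemion_scf
#' @export
tidy.chemion_scf <- function(x, ...) {
  tibble(
    orbital = seq_along(x$E_orb),
    energy = x$E_orb,
    occupied = seq_along(x$E_orb) <= x$chp
  )
}

#' @rdname tidy.chemion_scf
#' @return For `glance()`: a one-row tibble with the fit summary.
#' @method glance chemion_scf
#' @export
glance.chemion_scf <- function(x, ...) {
  tibble(
    converged = x$converged,
    iterations = x$iterations,
    sigma = tail(x$sigma_history, 1),
    electronic_energy = x$electronic_energy,
    chp = x$chp,
    n_basis = nrow(x$C)
  )
}
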