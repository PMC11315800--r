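#' Torsion potential curves and recursive chain growth
#'
#' The n-dimensional torsion space of a chain is reduced to one-dimensional
#' potential curves: at each chain length exactly one torsion is varied over
#' a uniform grid while all previously optimized torsions stay frozen. The
#' potential is the total energy of the varied bond's chain-bond ensemble
#' (one chemion pair in the two-fragment condensed basis, plus the nuclear
#' repulsion of that ensemble's proportional charges).
#'
#' @name torsion_scan
#' @keywords internal
NULL

# principal sub-block of an anchor integral set (raw vertex indices `idx`)
.subset_integrals <- function(ints, idx) {
  keep_nuc <- which(ints$nuclei %in% idx)
  structure(
    list(
      S = ints$S[idx, idx, drop = FALSE],
      K = ints$K[idx, idx, drop = FALSE],
      U = ints$U[idx, idx, keep_nuc, drop = FALSE],
      R = ints$R[idx, idx, idx, idx, drop = FALSE],
      nuclei = match(ints$nuclei[keep_nuc], idx),
      vtx = length(idx), mode = ints$mode, order = ints$order,
      level = ints$level, norms = NULL,
      fresh_counts = c(S = 0, K = 0, U = 0, R = 0)
    ),
    class = "chemion_integrals"
  )
}

# key of an anchor-level sub-block over a fixed-geometry fragment
.anchor_subblock_key <- function(vertices, inner_torsions, bond_lengths,
                                 mode, order) {
  hash(list(
    elements = vertices$element, kinds = vertices$kind,
    zeta = round(vertices$zeta, 12),
    torsions = round(inner_torsions, 9),
    bond_lengths = bond_lengths,
    mode = mode, order = order, what = "anchor-subblock"
  ))
}

# reuse key of the torsion-invariant proximal (terminal-side) fragment of
# the bond `torsion_index`
.proximal_key <- function(graph, torsion_index, mode, order) {
  tr <- graph$torsions[torsion_index, ]
  distal <- .distal_set(graph, tr$from, tr$to)
  prox <- sort(setdiff(seq_len(nrow(graph$vertices)), distal))
  inner <- graph$torsions$index[graph$torsions$index < torsion_index]
  list(
    prox = prox,
    key = .anchor_subblock_key(
      graph$vertices[prox, ], graph$torsions$value[inner],
      graph$meta$bond_lengths, mode, order
    )
  )
}

# single-point energy of the chain-bond ensemble at the current geometry
.bond_point <- function(graph, torsion_index, ints, scf_tol, max_iter) {
  ens <- chain_bond_ensemble(graph, torsion_index)
  cond <- condense_integrals(ints, list(
    alpha = ens$members$alpha,
    beta = ens$members$beta
  ))
  fit <- scf(cond, ens, tol = scf_tol, max_iter = max_iter)
  ci <- run_fci(fit)
  e_nucl <- nuclear_repulsion(ens, graph)
  list(
    e_nucl = e_nucl, e_chem = ci$e_chem,
    e_total = e_nucl + ci$e_chem,
    multiplicity = ci$multiplicity, converged = fit$converged,
    cond = cond, fit = fit, ci = ci
  )
}

#' Scan one torsion angle
#'
#' Computes the potential curve of one backbone torsion on a uniform,
#' half-open grid over `[0, 2*pi)`: for every grid point the torsion is set,
#' the chain-bond ensemble of the varied bond is built (one chemion pair,
#' basis condensed to the two fragments), RHF and full CI are solved, and
#' the total energy `E_total = E_nucl + E_chem` is recorded. The
#' terminal-side fragment's anchor integrals do not depend on the varied
#' torsion and are reused from the bank (or computed once), so each grid
#' point evaluates only the index tuples that touch the rotating fragment.
#'
#' @param spec A `chemion_molecule`, or a molecule spec (list or YAML path,
#'   see [read_molecule_spec()]).
#' @param torsion_index Torsion to vary; defaults to the last (leading
#'   methyl) bond.
#' @param grid_size Number of grid points (`>= 3`), default 24.
#' @param bank Optional [fragment_bank()] for block reuse across calls and
#'   chain-growth steps.
#' @param mode,order Integral evaluation settings.
#' @param scf_tol,max_iter SCF settings (tight default because the result
#'   feeds CI).
#' @return A `chemion_curve`: a tibble with columns `tau`, `tau_deg`,
#'   `e_total`, `e_nucl`, `e_chem`, `multiplicity`, `converged`, carrying
#'   the grid argmin, a parabolic refinement, and the per-point counts of
#'   freshly evaluated integrals as attributes.
#' @export
#' @examples
#' \donttest{
#' curve <- scan_torsion(build_chain(1, "CH3"), grid_size = 6, order = 3)
#' attr(curve, "argmin")
#' }
scan_torsion <- function(spec, torsion_index = NULL, grid_size = 24,
                         bank = NULL, mode = "exact", order = 6,
                         scf_tol = 1e-8, max_iter = 200) {
  graph <- if (inherits(spec, "chemion_molecule")) spec else read_molecule_spec(spec)
  if (nrow(graph$torsions) == 0) {
    abort("molecule has no torsional degree of freedom", class = "chemion_bad_torsion")
  }
  if (is.null(torsion_index)) torsion_index <- nrow(graph$torsions)
  if (grid_size < 3) abort("grid_size must be >= 3", class = "chemion_bad_grid")

  pk <- .proximal_key(graph, torsion_index, mode, order)
  sub <- if (!is.null(bank)) bank_fetch(bank, pk$key) else NULL
  grid <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  rows <- vector("list", grid_size)
  fresh <- matrix(0, grid_size, 4, dimnames = list(NULL, c("S", "K", "U", "R")))
  for (gi in seq_along(grid)) {
    g <- set_torsion(graph, torsion_index, grid[gi])
    ints <- build_anchor_integrals(g,
      mode = mode, order = order,
      reuse = if (!is.null(sub)) list(ints = sub, map = pk$prox)
    )
    fresh[gi, ] <- ints$fresh_counts
    if (is.null(sub)) {
      sub <- .subset_integrals(ints, pk$prox)
      if (!is.null(bank)) bank_store(bank, pk$key, sub)
    }
    pt <- .bond_point(g, torsion_index, ints, scf_tol, max_iter)
    if (!is.null(bank)) {
      bank_store(
        bank,
        paste0(fragment_key(g, level = 1L, mode = mode, order = order,
          extra = list(grid = gi, kind = "off-diagonal-ab")
        )),
        list(
          S = pt$cond$S, K = pt$cond$K, U = pt$cond$U, R = pt$cond$R,
          F_cond = pt$fit$F, H_cond = pt$fit$H
        )
      )
    }
    rows[[gi]] <- tibble(
      tau = grid[gi], tau_deg = grid[gi] * 180 / pi,
      e_total = pt$e_total, e_nucl = pt$e_nucl, e_chem = pt$e_chem,
      multiplicity = pt$multiplicity, converged = pt$converged
    )
  }
  curve <- bind_rows(rows)
  imin <- which(curve$e_total == min(curve$e_total))[1] # ties: smallest tau
  structure(
    curve,
    class = c("chemion_curve", class(curve)),
    torsion_index = torsion_index,
    argmin = curve$tau[imin],
    argmin_refined = .parabolic_argmin(curve$tau, curve$e_total, imin),
    fresh_counts = fresh,
    mode = mode, order = order,
    spec_hash = fragment_key(graph, mode = mode, order = order)
  )
}

# local 3-point parabolic refinement on the periodic grid
.parabolic_argmin <- function(tau, e, imin) {
  n <- length(tau)
  il <- if (imin == 1) n else imin - 1
  ir <- if (imin == n) 1 else imin + 1
  h <- tau[2] - tau[1]
  el <- e[il]
  e0 <- e[imin]
  er <- e[ir]
  denom <- el - 2 * e0 + er
  if (abs(denom) < 1e-14) {
    return(tau[imin])
  }
  (tau[imin] + h * 0.5 * (el - er) / denom) %% (2 * pi)
}

#' @export
print.chemion_curve <- function(x, ...) {
  cat(
    "<chemion_curve> torsion ", attr(x, "torsion_index"), ", ",
    nrow(x), " points, argmin tau = ",
    format(attr(x, "argmin") * 180 / pi), " deg\n",
    sep = ""
  )
  NextMethod()
}

#' Plot a torsion potential curve
#'
#' @param object A `chemion_curve`.
#' @param ... Unused.
#' @return A ggplot: total energy (hartree) against torsion angle (deg).
#' @export
autoplot.chemion_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$tau_deg, y = .data$e_total)) +
    geom_line() +
    geom_point(aes(colour = .data$multiplicity)) +
    labs(
      x = "torsion angle (deg)", y = "total energy (hartree)",
      colour = "multiplicity"
    )
}

#' Recursive chain growth with sequential torsion optimization
#'
#' Grows the chain `H3C-(CH2)n-X` step by step: at step `n` all previously
#' optimized torsions are frozen, the newly created bond's torsion is
#' scanned, and its grid argmin becomes the frozen value for the next step.
#' Condensed and anchor blocks are stored in (and reused from) the fragment
#' bank, so each step only evaluates the integral entries that involve the
#' new methyl unit.
#'
#' @param terminal Terminal group X.
#' @param max_n Last step index (step `n` treats the chain with `n + 1`
#'   methylene units, i.e. `H3C-(CH2)n-X`).
#' @param grid_size Grid points per torsion scan.
#' @param bank A [fragment_bank()]; created fresh if `NULL`.
#' @inheritParams scan_torsion
#' @param bond_lengths Optional bond-length overrides (angstrom).
#' @return A `chemion_aufbau`: list with `curves` (one `chemion_curve` per
#'   step), `torsions` (optimized values, terminal-adjacent first),
#'   `final` (the final `chemion_molecule`), `minima` (per-step minimum
#'   energies) and the `bank`.
#' @export
aufbau_polymerize <- function(terminal, max_n, grid_size = 24, bank = NULL,
                              mode = "exact", order = 6, scf_tol = 1e-8,
                              bond_lengths = NULL) {
  if (max_n < 0) abort("max_n must be >= 0", class = "chemion_bad_chain")
  if (is.null(bank)) bank <- fragment_bank()
  tors_opt <- numeric(0)
  curves <- list()
  minima <- numeric(0)
  graph <- NULL
  for (step in 0:max_n) {
    m <- step + 1L
    graph <- build_chain(m, terminal,
      torsions = c(tors_opt, 0),
      bond_lengths = bond_lengths
    )
    curve <- scan_torsion(graph,
      torsion_index = m, grid_size = grid_size,
      bank = bank, mode = mode, order = order, scf_tol = scf_tol
    )
    tau_star <- attr(curve, "argmin")
    tors_opt <- c(tors_opt, tau_star)
    graph <- set_torsion(graph, m, tau_star)
    curves[[length(curves) + 1L]] <- curve
    minima <- c(minima, min(curve$e_total))
    # seed the next step: the molecule minus its leading hydrogen is the
    # torsion-invariant proximal fragment of the bond created by the next
    # prolongation, so its anchor block is banked under that key now
    if (step < max_n) {
      pk <- .proximal_key(graph, m, mode, order)
      sub <- bank_fetch(bank, pk$key)
      ints_opt <- build_anchor_integrals(graph,
        mode = mode, order = order,
        reuse = if (!is.null(sub)) list(ints = sub, map = pk$prox)
      )
      keep <- seq_len(nrow(graph$vertices) - 1L) # all but the leading H
      bank_store(
        bank,
        .anchor_subblock_key(
          graph$vertices[keep, ], graph$torsions$value,
          graph$meta$bond_lengths, mode, order
        ),
        .subset_integrals(ints_opt, keep)
      )
    }
  }
  structure(
    list(
      curves = curves, torsions = tors_opt, final = graph,
      minima = minima, bank = bank, terminal = terminal, max_n = max_n
    ),
    class = "chemion_aufbau"
  )
}

#' @export
print.chemion_aufbau <- function(x, ...) {
  cat(
    "<chemion_aufbau> H3C-(CH2)n-", x$terminal, " for n = 0..", x$max_n,
    "; optimized torsions (deg): ",
    paste(round(x$torsions * 180 / pi, 2), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a torsion curve to CSV
#'
#' Columns: `tau_deg`, `E_total_hartree`, `E_nucl_hartree`,
#' `E_chem_hartree`, `multiplicity`, `converged`.
#'
#' @param curve A `chemion_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(
    tau_deg = curve$tau_deg,
    E_total_hartree = curve$e_total,
    E_nucl_hartree = curve$e_nucl,
    E_chem_hartree = curve$e_chem,
    multiplicity = curve$multiplicity,
    converged = curve$converged
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
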