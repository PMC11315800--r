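#' Vertex condensation of orbitals and integral blocks
#'
#' A condensation step replaces a group of vertex orbitals by a single
#' normalized "recursion orbital": the plain sum of the members, scaled by
#' `N = (sum of the members' overlap block)^(-1/2)` so the condensed orbital
#' has unit self-overlap. Because integration is linear, every condensed
#' integral is the normalized double (or quadruple) sum of the precursor
#' block -- no new quadrature is ever needed.
#'
#' @name condensation
#' @keywords internal
NULL

#' Normalization constant of a condensed orbital
#'
#' @param members Indices of the member orbitals.
#' @param S_prev Overlap matrix at the previous level.
#' @return The scalar `N = (sum(S_prev[members, members]))^(-1/2)`.
#' @export
#' @examples
#' condense_normalization(1:2, diag(2)) # 1/sqrt(2)
condense_normalization <- function(members, S_prev) {
  tot <- sum(S_prev[members, members])
  if (tot <= 0) {
    abort("non-positive overlap sum in condensation",
      class = "chemion_bad_condensation"
    )
  }
  1 / sqrt(tot)
}

#' Condense an integral set onto orbital groups
#'
#' Replaces the basis of `ints` by one normalized recursion orbital per
#' element of `groups` and condenses all four integral families by the
#' normalized block sums. Condensing each vertex into its own singleton
#' group reproduces the raw integrals exactly; condensation is associative,
#' so condensing condensed blocks equals condensing the anchors in one shot.
#'
#' @param ints A `chemion_integrals` (anchor-level or already condensed).
#' @param groups List of index vectors over the current basis; must
#'   partition it.
#' @return A `chemion_integrals` at `level + 1` with `length(groups)` basis
#'   functions; the `norms` field holds the cumulative (anchor-relative)
#'   group normalizations.
#' @details At the anchor level the condensed values are exactly the
#'   normalized block sums. When the input is itself condensed, its
#'   normalizations are divided out before summing and a fresh one applied
#'   afterwards: a recursion orbital of recursion orbitals is then the
#'   *same function* as the one-shot normalized sum of all its anchors,
#'   which makes condensation associative across levels (and makes banked
#'   fragment blocks exactly reusable inside larger fragments).
#' @export
condense_integrals <- function(ints, groups) {
  if (!setequal(unlist(groups), seq_len(ints$vtx)) ||
    length(unlist(groups)) != ints$vtx) {
    abort("groups must partition the basis", class = "chemion_bad_condensation")
  }
  G <- length(groups)
  w <- if (is.null(ints$norms)) rep(1, ints$vtx) else 1 / ints$norms
  # raw (unnormalized-sum) blocks of the current level
  S_raw <- ints$S * outer(w, w)
  K_raw <- ints$K * outer(w, w)
  N <- vapply(groups, condense_normalization, 0, S_prev = S_raw)
  S <- matrix(0, G, G)
  K <- matrix(0, G, G)
  nnuc <- dim(ints$U)[3]
  U <- array(0, c(G, G, nnuc))
  R <- array(0, rep(G, 4))
  for (a in seq_len(G)) {
    for (b in seq_len(G)) {
      ga <- groups[[a]]
      gb <- groups[[b]]
      S[a, b] <- N[a] * N[b] * sum(S_raw[ga, gb])
      K[a, b] <- N[a] * N[b] * sum(K_raw[ga, gb])
      wab <- as.vector(outer(w[ga], w[gb]))
      for (ci in seq_len(nnuc)) {
        U[a, b, ci] <- N[a] * N[b] *
          sum(as.vector(ints$U[ga, gb, ci, drop = FALSE]) * wab)
      }
    }
  }
  for (a in seq_len(G)) {
    for (b in seq_len(G)) {
      for (cc in seq_len(G)) {
        for (d in seq_len(G)) {
          ga <- groups[[a]]
          gb <- groups[[b]]
          gc <- groups[[cc]]
          gd <- groups[[d]]
          w4 <- as.vector(outer(outer(w[ga], w[gb]), outer(w[gc], w[gd])))
          R[a, b, cc, d] <- N[a] * N[b] * N[cc] * N[d] *
            sum(as.vector(ints$R[ga, gb, gc, gd, drop = FALSE]) * w4)
        }
      }
    }
  }
  structure(
    list(
      S = S, K = K, U = U, R = R, nuclei = ints$nuclei, vtx = G,
      mode = ints$mode, order = ints$order, level = ints$level + 1L,
      norms = N, groups = groups, fresh_counts = c(S = 0, K = 0, U = 0, R = 0)
    ),
    class = "chemion_integrals"
  )
}

#' One-chemion matrix of an ensemble
#'
#' Contracts the attraction tensor with the ensemble's proportional nuclear
#' charges, `V = sum_C z_prop[C] * U[, , C]`, and forms the one-chemion
#' energy matrix `H = K - V`.
#'
#' @param ints A `chemion_integrals`.
#' @param z_prop Proportional charges, one per nucleus of the block.
#' @return List with symmetric matrices `V` and `H`.
#' @export
one_chemion_matrix <- function(ints, z_prop) {
  if (length(z_prop) != dim(ints$U)[3]) {
    abort("z_prop length must match the nucleus dimension of U",
      class = "chemion_bad_charges"
    )
  }
  V <- matrix(0, ints$vtx, ints$vtx)
  for (ci in seq_along(z_prop)) {
    V <- V + z_prop[ci] * ints$U[, , ci]
  }
  list(V = V, H = ints$K - V)
}

# ---- fragment bank -------------------------------------------------------

#' Persistent fragment bank
#'
#' A keyed store of precomputed blocks (anchor or condensed integral sets,
#' Fock blocks) used by the chain-growth drivers. Keys hash everything that
#' can change an integral: element sequence, orbital exponents, bond-length
#' table, torsion values (rounded to 1e-9 rad), evaluation mode and
#' expansion order. A stored block is only ever reused under an identical
#' key, so a geometry or ensemble mismatch silently becomes a miss and a
#' fresh computation.
#'
#' @param path Optional `.rds` path for persistence across sessions.
#' @return A `chemion_bank` (environment-backed).
#' @export
#' @examples
#' bank <- fragment_bank()
#' bank_store(bank, "demo", list(x = 1))
#' bank_fetch(bank, "demo")$x
fragment_bank <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  env$store <- list()
  env$hits <- 0L
  env$misses <- 0L
  env$path <- path
  if (!is.null(path) && file.exists(path)) {
    env$store <- readRDS(path)
  }
  structure(env, class = "chemion_bank")
}

#' @rdname fragment_bank
#' @param bank A `chemion_bank`.
#' @param key Character key, usually from [fragment_key()].
#' @param blocks Arbitrary list of blocks to store.
#' @export
bank_store <- function(bank, key, blocks) {
  bank$store[[key]] <- blocks
  invisible(bank)
}

#' @rdname fragment_bank
#' @export
bank_fetch <- function(bank, key) {
  hit <- bank$store[[key]]
  if (is.null(hit)) {
    bank$misses <- bank$misses + 1L
  } else {
    bank$hits <- bank$hits + 1L
  }
  hit
}

#' @rdname fragment_bank
#' @export
bank_save <- function(bank) {
  if (is.null(bank$path)) abort("bank has no path", class = "chemion_bank_no_path")
  saveRDS(bank$store, bank$path)
  invisible(bank)
}

#' @rdname fragment_bank
#' @export
bank_counters <- function(bank) {
  c(hits = bank$hits, misses = bank$misses)
}

#' Reuse key of a fragment
#'
#' @param graph The `chemion_molecule` the block was computed on.
#' @param level Condensation level of the stored block.
#' @param mode,order Integral evaluation settings.
#' @param extra Optional extra key components (e.g. an ensemble kind or a
#'   torsion-grid index).
#' @return A character hash key.
#' @export
fragment_key <- function(graph, level = 0L, mode = "exact", order = 6,
                         extra = NULL) {
  v <- graph$vertices
  hash(list(
    elements = v$element, kinds = v$kind, zeta = round(v$zeta, 12),
    torsions = round(graph$torsions$value, 9),
    bond_lengths = graph$meta$bond_lengths,
    family = graph$meta$family, terminal = graph$meta$terminal,
    n = graph$meta$n, level = level, mode = mode, order = order,
    extra = extra
  ))
}

#' Condense a stored Fock block
#'
#' Retrieves the precursor Fock block stored under `fragment_key` and
#' returns its normalized double sum over the stored groups. If no block is
#' stored under that key (which includes any geometry or ensemble change,
#' since both are part of the key) the function returns `NULL` -- the
#' "not available" signal that triggers a fresh Fock build.
#'
#' The stored entry must be a list with `F_prev`, `S_prev` and `groups`.
#'
#' @param bank A `chemion_bank`.
#' @param fragment_key Character key of the stored precursor.
#' @return The condensed Fock matrix, or `NULL` if not available.
#' @export
condense_fock <- function(bank, fragment_key) {
  entry <- bank_fetch(bank, fragment_key)
  if (is.null(entry) || is.null(entry$F_prev)) {
    return(NULL)
  }
  groups <- entry$groups
  N <- vapply(groups, condense_normalization, 0, S_prev = entry$S_prev)
  G <- length(groups)
  Fc <- matrix(0, G, G)
  for (a in seq_len(G)) {
    for (b in seq_len(G)) {
      Fc[a, b] <- N[a] * N[b] * sum(entry$F_prev[groups[[a]], groups[[b]]])
    }
  }
  attr(Fc, "condensed") <- TRUE
  Fc
}

#' Anchor-integral budget of a chain-growth step
#'
#' Number of *new* raw integral entries a prolongation step must evaluate
#' when the precursor block is reused: with `a = 3n + 8` total vertices and
#' `b = 3n + 4` reused precursor vertices, the step adds `a^2 - b^2` overlap
#' and kinetic entries, at most `a^3 - b^3` attraction entries, and
#' `a^4 - b^4` repulsion entries; the difference `a - b` is always 4. The
#' anchor step itself (a monofocal `H-XV3` chart) needs the full `5^2`,
#' `5^2`, `<= 5^3`, `5^4`.
#'
#' Lone-pair vertices carry a basis orbital like any other vertex; with
#' `include_lone_pairs = FALSE` the terminal's lone-pair vertices are left
#' out of both `a` and `b` (their difference, hence the scaling, is
#' unchanged).
#'
#' @param n Prolongation step index (`>= 0`), or `NULL` for the anchor step.
#' @param include_lone_pairs Count lone-pair vertices? Default `TRUE`.
#' @param terminal Terminal group (determines the lone-pair count when
#'   `include_lone_pairs = FALSE`).
#' @return A tibble with columns `step`, `a`, `b`, `n_S`, `n_K`,
#'   `n_U_bound`, `n_R` (integer counts of raw index tuples).
#' @export
#' @examples
#' integral_budget(0) # 48 overlaps, 3840 repulsions
integral_budget <- function(n = NULL, include_lone_pairs = TRUE,
                            terminal = "CH3") {
  if (is.null(n)) {
    return(tibble(
      step = "anchor", a = 5L, b = 0L, n_S = 25L, n_K = 25L,
      n_U_bound = 125L, n_R = 625L
    ))
  }
  if (n < 0) abort("n must be >= 0", class = "chemion_bad_budget")
  drop <- if (include_lone_pairs) 0L else .element_row(.terminal_table[[terminal]])$n_lone
  a <- 3L * as.integer(n) + 8L - drop
  b <- 3L * as.integer(n) + 4L - drop
  tibble(
    step = as.character(n), a = a, b = b,
    n_S = a * a - b * b, n_K = a * a - b * b,
    n_U_bound = a * a * a - b * b * b,
    n_R = a * a * a * a - b * b * b * b
  )
}
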