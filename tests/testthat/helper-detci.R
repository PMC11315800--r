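# Independent determinant-space full-CI oracle (Slater-Condon rules over
# alpha/beta occupation strings, spin resolved by S^2 projection). Used to
# arbitrate the closed-form CSF matrices; deliberately shares no code with
# the package implementation.

det_ann <- function(occ, p) {
  i <- match(p, occ)
  if (is.na(i)) {
    return(NULL)
  }
  list(occ = occ[-i], sign = (-1)^(i - 1))
}

det_cre <- function(occ, p) {
  if (p %in% occ) {
    return(NULL)
  }
  list(occ = sort(c(occ, p)), sign = (-1)^sum(occ < p))
}

det_excite <- function(occ, p, q) {
  s1 <- det_ann(occ, p)
  if (is.null(s1)) {
    return(NULL)
  }
  s2 <- det_cre(s1$occ, q)
  if (is.null(s2)) {
    return(NULL)
  }
  list(occ = s2$occ, sign = s1$sign * s2$sign)
}

det_all <- function(vtx, na, nb) {
  as_ <- utils::combn(vtx, na, simplify = FALSE)
  bs_ <- utils::combn(vtx, nb, simplify = FALSE)
  out <- list()
  for (a in as_) for (b in bs_) out[[length(out) + 1]] <- list(a = a, b = b)
  out
}

det_key <- function(d) paste(paste(d$a, collapse = ","), "|", paste(d$b, collapse = ","))

det_sc_single <- function(h, eri, p, q, same_common, other_common) {
  v <- h[p, q]
  for (n in same_common) v <- v + eri[p, q, n, n] - eri[p, n, n, q]
  for (n in other_common) v <- v + eri[p, q, n, n]
  v
}

det_sc_element <- function(d1, d2, h, eri) {
  ra <- setdiff(d1$a, d2$a)
  aa <- setdiff(d2$a, d1$a)
  rb <- setdiff(d1$b, d2$b)
  ab <- setdiff(d2$b, d1$b)
  nex <- length(ra) + length(rb)
  if (nex > 2) {
    return(0)
  }
  if (nex == 0) {
    e <- sum(diag(h)[d1$a]) + sum(diag(h)[d1$b])
    for (p in d1$a) {
      for (q in d1$a) {
        if (p != q) e <- e + 0.5 * (eri[p, p, q, q] - eri[p, q, q, p])
      }
    }
    for (p in d1$b) {
      for (q in d1$b) {
        if (p != q) e <- e + 0.5 * (eri[p, p, q, q] - eri[p, q, q, p])
      }
    }
    for (p in d1$a) for (q in d1$b) e <- e + eri[p, p, q, q]
    return(e)
  }
  if (nex == 1) {
    if (length(ra) == 1) {
      ex <- det_excite(d1$a, ra, aa)
      return(ex$sign * det_sc_single(h, eri, ra, aa, setdiff(d1$a, ra), d1$b))
    }
    ex <- det_excite(d1$b, rb, ab)
    return(ex$sign * det_sc_single(h, eri, rb, ab, setdiff(d1$b, rb), d1$a))
  }
  if (length(ra) == 2) {
    e1 <- det_excite(d1$a, ra[1], aa[1])
    e2 <- det_excite(e1$occ, ra[2], aa[2])
    return(e1$sign * e2$sign * (eri[ra[1], aa[1], ra[2], aa[2]] - eri[ra[1], aa[2], ra[2], aa[1]]))
  }
  if (length(rb) == 2) {
    e1 <- det_excite(d1$b, rb[1], ab[1])
    e2 <- det_excite(e1$occ, rb[2], ab[2])
    return(e1$sign * e2$sign * (eri[rb[1], ab[1], rb[2], ab[2]] - eri[rb[1], ab[2], rb[2], ab[1]]))
  }
  ea <- det_excite(d1$a, ra, aa)
  eb <- det_excite(d1$b, rb, ab)
  ea$sign * eb$sign * eri[ra, aa, rb, ab]
}

det_hamiltonian <- function(dets, h, eri) {
  n <- length(dets)
  H <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) H[i, j] <- det_sc_element(dets[[i]], dets[[j]], h, eri)
  }
  H
}

# lowest singlet / triplet energies from the Sz = 0 sector (S^2 = S+S-)
det_fci <- function(h, eri, chp) {
  vtx <- nrow(h)
  d0 <- det_all(vtx, chp, chp)
  H0 <- det_hamiltonian(d0, h, eri)
  dm <- if (chp >= 1) det_all(vtx, chp - 1, chp + 1) else list()
  if (length(dm)) {
    keys <- vapply(dm, det_key, "")
    M <- matrix(0, length(dm), length(d0))
    na <- chp
    for (j in seq_along(d0)) {
      d <- d0[[j]]
      for (p in d$a) {
        if (p %in% d$b) next
        s1 <- det_ann(d$a, p)
        s2 <- det_cre(d$b, p)
        nd <- list(a = s1$occ, b = s2$occ)
        i <- match(det_key(nd), keys)
        M[i, j] <- M[i, j] + s1$sign * (-1)^(na - 1) * s2$sign
      }
    }
    S2 <- t(M) %*% M
  } else {
    S2 <- matrix(0, length(d0), length(d0))
  }
  es <- eigen((S2 + t(S2)) / 2, symmetric = TRUE)
  pick <- function(val) es$vectors[, abs(es$values - val) < 1e-8, drop = FALSE]
  ev <- function(B) {
    if (!ncol(B)) {
      return(numeric(0))
    }
    sort(eigen(t(B) %*% H0 %*% B, symmetric = TRUE, only.values = TRUE)$values)
  }
  list(singlet = ev(pick(0)), triplet = ev(pick(2)))
}

# random symmetric one-chemion matrix and 8-fold symmetric repulsion tensor,
# packaged like the output of transform_integrals()
random_mo <- function(vtx, chp, seed) {
  set.seed(seed)
  h <- matrix(rnorm(vtx^2), vtx)
  h <- (h + t(h)) / 2
  eri <- array(rnorm(vtx^4), rep(vtx, 4))
  sym <- array(0, rep(vtx, 4))
  for (perm in list(
    c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
    c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1)
  )) {
    sym <- sym + aperm(eri, perm)
  }
  structure(
    list(h = h, eri = sym / 8, chp = chp, r = chp + 1L, vtx = vtx),
    class = "chemion_mo"
  )
}
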