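#' Slater-type vertex orbitals and their integrals
#'
#' Every vertex carries one normalized node-less spherical Slater orbital
#' `N r^(n-1) exp(-zeta r)` with `n` the valence shell (1 for H, 2 for the
#' first-row centres and their lone pairs, 3 for the second-row centres).
#' Integrals are evaluated by expanding each Slater orbital in spherical
#' Gaussian primitives (least-squares fit, default order 6), which makes all
#' two-, three- and four-centre integrals analytic over the primitives.
#'
#' @name sto_integrals
#' @keywords internal
NULL

.sto_cache <- new.env(parent = emptyenv())

# radial value of the normalized node-less Slater function
.sto_radial <- function(n, zeta, r) {
  norm <- (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
  norm * r^(n - 1) * exp(-zeta * r)
}

.erf <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

# Boys function F0
.boys0 <- function(t) {
  out <- numeric(length(t))
  small <- t < 1e-13
  out[small] <- 1 - t[small] / 3
  tb <- t[!small]
  out[!small] <- 0.5 * sqrt(pi / tb) * .erf(sqrt(tb))
  out
}

# overlap matrix of normalized s-Gaussians with exponents a (vector)
.gauss_overlap_matrix <- function(a) {
  outer(a, a, function(x, y) (2 * sqrt(x * y) / (x + y))^1.5)
}

# <STO(n, zeta=1) | normalized gaussian(alpha)> by radial quadrature;
# .sto_radial carries the radial norm, the gaussian the full 3D norm, so the
# angular factor enters as sqrt(4*pi)
.sto_gauss_overlap <- function(n, alpha) {
  vapply(alpha, function(al) {
    f <- function(r) {
      .sto_radial(n, 1, r) * (2 * al / pi)^0.75 * exp(-al * r^2) *
        sqrt(4 * pi) * r^2
    }
    integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, 0)
}

# best-overlap fit of the zeta = 1 Slater function by `order` Gaussians;
# returns list(alpha, coef) with coef on *normalized* primitives,
# normalized so the expansion has unit self-overlap
.fit_expansion <- function(n, order) {
  key <- paste(n, order, sep = ".")
  hit <- .sto_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  span <- list(c(0.05, 25), c(0.02, 8), c(0.01, 3))[[n]]
  a0 <- exp(seq(log(span[1]), log(span[2]), length.out = max(order, 2)))[seq_len(order)]
  par0 <- c(log(a0[1]), if (order > 1) log(diff(log(a0))))
  unpack <- function(par) exp(cumsum(c(par[1], if (order > 1) exp(par[-1]))))
  objective <- function(par) {
    a <- unpack(par)
    sg <- .gauss_overlap_matrix(a)
    s <- .sto_gauss_overlap(n, a)
    t2 <- tryCatch(drop(crossprod(s, solve(sg, s))), error = function(e) NA_real_)
    if (!is.finite(t2)) {
      return(1e6)
    }
    -t2
  }
  fit <- if (order == 1) {
    optim(par0, objective, method = "Brent", lower = -8, upper = 8)
  } else {
    optim(par0, objective,
      method = "Nelder-Mead",
      control = list(maxit = 4000, reltol = 1e-14)
    )
  }
  fit <- optim(fit$par, objective,
    method = "BFGS",
    control = list(maxit = 500, reltol = 1e-14)
  )
  alpha <- unpack(fit$par)
  sg <- .gauss_overlap_matrix(alpha)
  s <- .sto_gauss_overlap(n, alpha)
  coef <- solve(sg, s)
  coef <- coef / sqrt(drop(crossprod(coef, sg %*% coef)))
  res <- list(
    alpha = alpha, coef = coef,
    overlap = sqrt(drop(crossprod(s, solve(sg, s))))
  )
  if (res$overlap < 0.95) {
    abort(
      paste0(
        "Gaussian expansion fit failed for n=", n, ", order=", order,
        " (overlap ", format(res$overlap), ")"
      ),
      class = "chemion_fit_failure"
    )
  }
  .sto_cache[[key]] <- res
  res
}

#' Expand a Slater orbital in Gaussian primitives
#'
#' Least-squares (maximum-overlap) fit of the normalized node-less Slater
#' radial function by `order` spherical Gaussians. The fit is performed once
#' per (`n`, `order`) at `zeta = 1` and transferred to arbitrary exponents by
#' the exact scaling `alpha -> alpha * zeta^2`; the result is re-normalized
#' so its self-overlap is 1 to machine precision.
#'
#' @param n Principal quantum number, 1, 2 or 3.
#' @param zeta Slater exponent (1/bohr).
#' @param order Number of primitives, 1..6.
#' @return List with `alpha` (exponents), `coef` (coefficients of the *raw*
#'   primitives `exp(-alpha r^2)`), and `fit_overlap` (the ζ-independent
#'   quality of fit, `<STO|expansion>`).
#' @export
#' @examples
#' gaussian_expand(1, 1, 3)$fit_overlap
gaussian_expand <- function(n, zeta, order = 6) {
  stopifnot(n %in% 1:3, order %in% 1:6, zeta > 0)
  fit <- .fit_expansion(n, order)
  alpha <- fit$alpha * zeta^2
  d <- fit$coef * (2 * alpha / pi)^0.75
  # exact renormalization of the expansion itself
  self <- drop(crossprod(d, outer(alpha, alpha, function(x, y) (pi / (x + y))^1.5) %*% d))
  d <- d / sqrt(self)
  list(n = n, zeta = zeta, alpha = alpha, coef = d, fit_overlap = fit$overlap)
}

#' Construct a Slater vertex orbital
#'
#' @inheritParams gaussian_expand
#' @param center Position, 3-vector in bohr.
#' @return A `chemion_orbital` carrying its Gaussian expansion.
#' @export
sto_orbital <- function(n, zeta, center = c(0, 0, 0), order = 6) {
  exp_ <- gaussian_expand(n, zeta, order)
  structure(
    list(
      n = n, zeta = zeta, center = as.numeric(center),
      alpha = exp_$alpha, coef = exp_$coef, order = order
    ),
    class = "chemion_orbital"
  )
}

# all primitive-pair quantities of two expanded orbitals:
# composite exponent p, combined centre P, overlap-kernel weight
# c = d_i d_j exp(-mu R^2), reduced exponent mu = a_i a_j / p
.pair_data <- function(a, b) {
  ai <- rep(a$alpha, times = length(b$alpha))
  aj <- rep(b$alpha, each = length(a$alpha))
  di <- rep(a$coef, times = length(b$coef))
  dj <- rep(b$coef, each = length(a$coef))
  p <- ai + aj
  mu <- ai * aj / p
  r2 <- sum((a$center - b$center)^2)
  cc <- di * dj * exp(-mu * r2)
  P <- outer(ai, a$center) + outer(aj, b$center)
  list(p = p, mu = mu, cc = cc, P = P / p, r2 = r2)
}

#' Anchor integrals over vertex orbitals
#'
#' `overlap`, `kinetic`, `attraction` and `repulsion` evaluate the four
#' integral families over Gaussian-expanded Slater orbitals: the overlap
#' `<a|b>`, the kinetic energy `<a|-Laplacian/2|b>`, the (positive)
#' nuclear-attraction moment `<a|1/|r - R_C||b>`, and the two-chemion Coulomb
#' repulsion `(ab|cd)` in chemists' notation.
#'
#' @param a,b,c,d `chemion_orbital` objects.
#' @param nucleus_position 3-vector in bohr.
#' @return Scalar integral value in atomic units.
#' @export
#' @examples
#' s <- sto_orbital(1, 1)
#' kinetic(s, s) # zeta^2 / 2
overlap <- function(a, b) {
  pd <- .pair_data(a, b)
  sum(pd$cc * (pi / pd$p)^1.5)
}

#' @rdname overlap
#' @export
kinetic <- function(a, b) {
  pd <- .pair_data(a, b)
  sum(pd$cc * pd$mu * (3 - 2 * pd$mu * pd$r2) * (pi / pd$p)^1.5)
}

#' @rdname overlap
#' @export
attraction <- function(a, b, nucleus_position) {
  pd <- .pair_data(a, b)
  pc2 <- rowSums((pd$P - matrix(nucleus_position, nrow(pd$P), 3, byrow = TRUE))^2)
  sum(pd$cc * 2 * pi / pd$p * .boys0(pd$p * pc2))
}

#' @rdname overlap
#' @export
repulsion <- function(a, b, c, d) {
  .pair_repulsion(.pair_data(a, b), .pair_data(c, d))
}

.pair_repulsion <- function(p1, p2) {
  pb <- rep(p1$p, times = length(p2$p))
  pk <- rep(p2$p, each = length(p1$p))
  cb <- rep(p1$cc, times = length(p2$cc))
  ck <- rep(p2$cc, each = length(p1$cc))
  d2 <- (rep(p1$P[, 1], times = length(p2$p)) - rep(p2$P[, 1], each = length(p1$p)))^2 +
    (rep(p1$P[, 2], times = length(p2$p)) - rep(p2$P[, 2], each = length(p1$p)))^2 +
    (rep(p1$P[, 3], times = length(p2$p)) - rep(p2$P[, 3], each = length(p1$p)))^2
  sum(cb * ck * 2 * pi^2.5 / (pb * pk * sqrt(pb + pk)) *
    .boys0(pb * pk / (pb + pk) * d2))
}
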