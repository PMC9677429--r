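# Slater-type radial primitives and their analytic electrostatic potentials.
# All functions here work in atomic units (Bohr, e).
#
# A "primitive" is a radial density term  c * r^m * exp(-a r)  (e/Bohr^3).
# Spherical pseudoatom densities (core, kappa-scaled valence) and the radial
# parts of the deformation terms are sums of such primitives, so their
# potentials have closed forms in terms of incomplete gamma functions.

# normalization constant of the Slater orbital N r^(n-1) exp(-zeta r)
.sto_norm <- function(n, zeta) {
  (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
}

# lower incomplete gamma(a, x) (non-regularized), vectorized in x
.gamma_low <- function(a, x) gamma(a) * stats::pgamma(x, a)
# upper incomplete gamma(a, x)
.gamma_up <- function(a, x) gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)

# Potential at radius r (Bohr) of the spherical density c r^m exp(-a r):
#   V(r) = 4 pi [ (1/r) int_0^r s^(m+2) e^(-as) ds + int_r^inf s^(m+1) e^(-as) ds ]
.prim_potential <- function(r, c0, m, a) {
  v <- numeric(length(r))
  small <- r < 1e-12
  rs <- r[!small]
  if (any(!small)) {
    v[!small] <- 4 * pi * c0 *
      (.gamma_low(m + 3, a * rs) / (a^(m + 3) * rs) +
       .gamma_up(m + 2, a * rs) / a^(m + 2))
  }
  if (any(small)) v[small] <- 4 * pi * c0 * gamma(m + 2) / a^(m + 2)
  v
}

# Radial factor of the potential of the density f(r) y_lm(Omega) with
# f(r) = c r^m exp(-a r):
#   V(r, Omega) = y_lm(Omega) * 4 pi/(2l+1) *
#     [ r^-(l+1) int_0^r f s^(l+2) ds + r^l int_r^inf f s^(1-l) ds ]
.prim_potential_l <- function(r, c0, m, a, l) {
  v <- numeric(length(r))
  small <- r < 1e-12
  rs <- r[!small]
  if (any(!small)) {
    v[!small] <- 4 * pi / (2 * l + 1) * c0 *
      (.gamma_low(m + l + 3, a * rs) / (a^(m + l + 3) * rs^(l + 1)) +
       rs^l * .gamma_up(m + 2 - l, a * rs) / a^(m + 2 - l))
  }
  # r -> 0: only the outer integral survives for l = 0; zero for l >= 1
  if (any(small)) {
    v[small] <- if (l == 0) 4 * pi * c0 * gamma(m + 2) / a^(m + 2) else 0
  }
  v
}

# evaluate a primitive table (data.frame c0, m, a) as density at radii r
.prim_density <- function(r, prims) {
  if (is.null(prims) || nrow(prims) == 0) return(numeric(length(r)))
  out <- numeric(length(r))
  for (k in seq_len(nrow(prims))) {
    out <- out + prims$c0[k] * r^prims$m[k] * exp(-prims$a[k] * r)
  }
  out
}

# total potential of a primitive table
.prim_table_potential <- function(r, prims) {
  out <- numeric(length(r))
  if (is.null(prims) || nrow(prims) == 0) return(out)
  for (k in seq_len(nrow(prims))) {
    out <- out + .prim_potential(r, prims$c0[k], prims$m[k], prims$a[k])
  }
  out
}

# integral of a primitive table over all space: 4 pi int rho r^2 dr
.prim_table_charge <- function(prims) {
  if (is.null(prims) || nrow(prims) == 0) return(0)
  sum(4 * pi * prims$c0 * gamma(prims$m + 3) / prims$a^(prims$m + 3))
}

# <r^l> moment of the radial function f(r) = c r^m exp(-a r): int f r^(l+2) dr
.prim_rl_moment <- function(c0, m, a, l) {
  c0 * gamma(m + l + 3) / a^(m + l + 3)
}
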